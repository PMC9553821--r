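# Fixtures and fitted models reused across test files, built once per run.
.shared <- new.env(parent = emptyenv())

shared_standard <- function() {
  if (is.null(.shared$standard)) .shared$standard <- generate_fixture("standard")
  .shared$standard
}

shared_standard_fit <- function() {
  if (is.null(.shared$standard_fit)) {
    fx <- shared_standard()
    .shared$standard_fit <- fit_dlnm(fx$weather, fx$counts)
  }
  .shared$standard_fit
}

# A small crossbasis-only fit on the 60-day tiny fixture: response plus
# intercept and cross-basis columns, with the prediction metadata attached
# the same way fit_dlnm does it.
shared_tiny_fit <- function() {
  if (is.null(.shared$tiny_fit)) {
    fx <- generate_fixture("tiny")
    cb <- build_crossbasis(fx$weather$tmean, crossbasis_spec(4, 2, 3))
    keep <- which(cb$complete_row_mask)
    X <- cbind("(Intercept)" = 1, cb$matrix[keep, ])
    fit <- fit_quasipoisson(fx$counts$count[keep], X,
                            labels = list("(Intercept)" = 1L,
                                          crossbasis = 1L + seq_len(ncol(cb$matrix))))
    fit$crossbasis <- cb
    fit$exposure <- fx$weather$tmean
    fit$rows <- keep
    fit$y <- fx$counts$count[keep]
    .shared$tiny_fit <- fit
  }
  .shared$tiny_fit
}
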