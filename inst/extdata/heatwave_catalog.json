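[
  {
    "metric": "tmin",
    "threshold_kind": "percentile",
    "threshold_value": 90,
    "min_duration": 2,
    "id": "tmin_p90_d2"
  },
  {
    "metric": "tmin",
    "threshold_kind": "percentile",
    "threshold_value": 95,
    "min_duration": 2,
    "id": "tmin_p95_d2"
  },
  {
    "metric": "tmin",
    "threshold_kind": "percentile",
    "threshold_value": 99,
    "min_duration": 2,
    "id": "tmin_p99_d2"
  },
  {
    "metric": "tmin",
    "threshold_kind": "absolute",
    "threshold_value": 35,
    "min_duration": 1,
    "id": "tmin_abs35_d1"
  },
  {
    "metric": "tmean",
    "threshold_kind": "percentile",
    "threshold_value": 90,
    "min_duration": 2,
    "id": "tmean_p90_d2"
  },
  {
    "metric": "tmean",
    "threshold_kind": "percentile",
    "threshold_value": 95,
    "min_duration": 2,
    "id": "tmean_p95_d2"
  },
  {
    "metric": "tmean",
    "threshold_kind": "percentile",
    "threshold_value": 99,
    "min_duration": 2,
    "id": "tmean_p99_d2"
  },
  {
    "metric": "tmean",
    "threshold_kind": "absolute",
    "threshold_value": 35,
    "min_duration": 1,
    "id": "tmean_abs35_d1"
  },
  {
    "metric": "tmax",
    "threshold_kind": "percentile",
    "threshold_value": 90,
    "min_duration": 2,
    "id": "tmax_p90_d2"
  },
  {
    "metric": "tmax",
    "threshold_kind": "percentile",
    "threshold_value": 95,
    "min_duration": 2,
    "id": "tmax_p95_d2"
  },
  {
    "metric": "tmax",
    "threshold_kind": "percentile",
    "threshold_value": 99,
    "min_duration": 2,
    "id": "tmax_p99_d2"
  },
  {
    "metric": "tmax",
    "threshold_kind": "absolute",
    "threshold_value": 35,
    "min_duration": 1,
    "id": "tmax_abs35_d1"
  },
  {
    "metric": "apparent",
    "threshold_kind": "percentile",
    "threshold_value": 90,
    "min_duration": 2,
    "id": "apparent_p90_d2"
  },
  {
    "metric": "apparent",
    "threshold_kind": "percentile",
    "threshold_value": 95,
    "min_duration": 2,
    "id": "apparent_p95_d2"
  },
  {
    "metric": "apparent",
    "threshold_kind": "percentile",
    "threshold_value": 99,
    "min_duration": 2,
    "id": "apparent_p99_d2"
  },
  {
    "metric": "apparent",
    "threshold_kind": "absolute",
    "threshold_value": 35,
    "min_duration": 1,
    "id": "apparent_abs35_d1"
  }
]
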