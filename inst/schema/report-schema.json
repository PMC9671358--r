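{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "mrkit pipeline report",
  "type": "object",
  "required": ["package", "version", "seed", "config", "selection",
               "harmonization", "estimates", "heterogeneity", "presso",
               "loo"],
  "properties": {
    "package": {"type": "string"},
    "version": {"type": "string"},
    "seed": {"type": "integer"},
    "config": {"type": "object"},
    "selection": {
      "type": "object",
      "required": ["offered", "after_significance", "after_clumping",
                   "after_f_filter"]
    },
    "harmonization": {
      "type": "object",
      "required": ["offered", "kept", "counts"]
    },
    "estimates": {"type": "array"},
    "heterogeneity": {
      "type": "object",
      "required": ["q", "df", "pval", "i2", "label"]
    },
    "presso": {
      "type": "object",
      "required": ["rss_obs", "global_pval", "outliers"]
    },
    "loo": {"type": "object", "required": ["flag", "beta_range"]},
    "post_outlier": {"type": "object"},
    "confounder_filtered": {"type": "object"},
    "mvmr": {"type": "object"},
    "power": {"type": "object"}
  }
}
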