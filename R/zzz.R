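.datatable.aware <- TRUE

# data.table non-standard evaluation columns
utils::globalVariables(c(
  ".N", "locus_id", "base", "ref", "alt", "eps", "is_nonref", "is_alt",
  "strand", "bq", "mq", "vaf", "depth", "alt_count", "kind"
))
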