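.datatable.aware <- TRUE

# data.table non-standard-evaluation symbols
utils::globalVariables(c(
  ".", "attempt", "t_ms", "x", "y", "level", "raw_length", "participant_id",
  "V1", "sleep", "bin", "grp", "country", "sleep_hours", ".y",
  "gdp_per_capita", "abs_latitude", "weird", "..lev_cols"
))
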