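.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", ".N", ".I", "age", "alive", "age_group", "age_band", "condition",
  "count", "count_p5", "count_p95", "count_weighted", "deaths", "dementia",
  "dementia_and_frailty", "dementia_state", "dependency", "education",
  "entry_year", "frail", "frailty", "group", "group2", "headcount", "id",
  "iadl_limited", "adl_limited", "depression", "srh", "impaired_mobility",
  "informal", "inpatient", "is_both", "is_dementia", "is_frail", "is_mci",
  "iteration", "key", "ltc_care_home", "ltc_home_community", "mc_se", "cell",
  "monthly_cost", "ncond", "outpatient_rx", "p", "p_lower", "p_upper",
  "population", "prevalence", "proportion", "proportion_p5",
  "proportion_p95", "py", "py_adj", "rel_diff", "seed", "sex", "total",
  "value", "value_observed", "value_projected", "year", "flagged",
  "death_age", "death_year", "component"
))
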