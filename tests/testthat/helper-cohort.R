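# Shared small planted cohorts, built once per test run.

.cohort_cache <- new.env(parent = emptyenv())

planted_cohort <- function(n = 600, seed = 11, ...) {
  key <- paste(n, seed, paste(deparse(list(...)), collapse = ""), sep = "|")
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- generate_cohort(cohort_config(n_patients = n,
                                                          seed = seed, ...))
  .cohort_cache[[key]]
}

truth_of <- function(cohort, ids) {
  cohort$truth$subgroup[match(ids, cohort$truth$patient_id)]
}
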