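# Shared fixtures, built once per test run.

# small but fully featured cohort reused by the status/outcome/pipeline tests
shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(cohort_config(n_patients = 8000,
                                              seed = 401L))
    cache
  }
})

# a tiny two-template, clearly separable corpus for classifier sanity tests
toy_separable_corpus <- function(n = 200, seed = 5L) {
  set.seed(seed)
  lab <- sample(c("current", "ex", "never", "unknown"), n, replace = TRUE)
  txt <- c(current = "tupakoi edelleen joka paiva",
           ex = "tupakoinnin lopetus kauan sitten vuosi",
           never = "ei koskaan tupakoinut ikina",
           unknown = "tupakointi taysin epaselva asia")[lab]
  data.frame(text = unname(txt), label = lab, stringsAsFactors = FALSE)
}

# assemble the analysis data frame (status truth via the note-assignment
# rule, CCI from diagnosis codes, outcome flags from events)
analysis_frame <- function(coh) {
  s <- merge(coh$surgeries, coh$patients[, c("patient_id", "sex")],
             by = "patient_id")
  st <- assign_status_all(coh$status_notes, coh$surgeries)
  df <- merge(s, st, by = "surgery_id")
  cut <- tapply(as.numeric(as.Date(df$date)), df$patient_id, min)
  cci <- compute_cci_table(coh$diagnosis_events, unique(df$patient_id), cut)
  df <- merge(df, cci, by = "patient_id")
  merge(df, flag_outcomes(coh$surgeries, coh$diagnosis_events,
                          coh$care_events), by = "surgery_id")
}

adjusted_overall_spec <- function(outcome = "overall")
  model_spec(outcome, continuous = "age_at_surgery",
             categorical = list(status = "never", sex = "female",
                                asa_class = "1", cci_band = "0"))
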