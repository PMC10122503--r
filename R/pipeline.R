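# End-to-end study orchestration: classify -> assign -> score -> analyze.

.adjusted_spec <- function(outcome)
  model_spec(outcome, continuous = "age_at_surgery",
             categorical = list(status = "never", sex = "female",
                                asa_class = "1", cci_band = "0"))

.unadjusted_spec <- function(outcome)
  model_spec(outcome, categorical = list(status = "never"))

.or_row <- function(fit) {
  o <- odds_ratios(fit, "^status")
  rn <- sub("^status", "", rownames(o))
  data.frame(group = rn, or = o[, "or"], ci_low = o[, "ci_low"],
             ci_high = o[, "ci_high"], row.names = NULL,
             stringsAsFactors = FALSE)
}

.fit_pair <- function(df, outcome) {
  unadj <- fit_logistic(df, .unadjusted_spec(outcome))
  adj <- fit_logistic(df, .adjusted_spec(outcome))
  imp <- wald_partial_chisq(adj)
  shap <- shapley_importance(adj)
  imp$mean_abs_shapley <- shap$mean_abs_shapley[match(imp$variable,
                                                      shap$variable)]
  list(unadjusted = unadj, adjusted = adj, importance = imp,
       pseudo_r2 = pseudo_r2(adj))
}

#' Yearly smoking-status ratios of the analysis set
#'
#' @param analysis_set data frame with `date` (or `year`) and `status`.
#' @return data frame with `year`, `status`, `n`, `proportion`; the
#'   proportions within each calendar year sum to 1 and the `n` column
#'   sums to the analysis-set size. Years without surgeries are omitted.
#' @export
yearly_status_ratios <- function(analysis_set) {
  year <- analysis_set$year %||%
    as.integer(format(as.Date(analysis_set$date), "%Y"))
  tab <- as.data.frame(table(year = year, status = analysis_set$status),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  tab$year <- as.integer(tab$year)
  tot <- tapply(tab$n, tab$year, sum)
  tab <- tab[tot[as.character(tab$year)] > 0, , drop = FALSE]
  tab$proportion <- tab$n / tot[as.character(tab$year)]
  tab[order(tab$year, tab$status), ]
}

.baseline_table <- function(df) {
  per_status <- split(df, df$status)
  do.call(rbind, lapply(names(per_status), function(s) {
    d <- per_status[[s]]
    data.frame(status = s, n = nrow(d),
               male = sum(d$sex == "male"),
               age_mean = mean(d$age_at_surgery),
               age_sd = stats::sd(d$age_at_surgery),
               age_median = stats::median(d$age_at_surgery),
               age_q1 = unname(stats::quantile(d$age_at_surgery, 0.25)),
               age_q3 = unname(stats::quantile(d$age_at_surgery, 0.75)),
               asa3_or_higher = mean(d$asa_class >= 3),
               cci_band0 = mean(d$cci_band == "0"),
               stringsAsFactors = FALSE)
  }))
}

#' Run the full study pipeline on a (synthetic or real) registry
#'
#' Stages: (1) obtain timestamped status observations — either directly
#' from the note status column, or by training the sentence classifier on a
#' labelled corpus, tuning its abstention thresholds on a held-out split,
#' and classifying the note text; (2) collapse observations into one
#' preoperative status per surgery and apply the exclusion flow (unknown
#' status, age < 16, missing ASA); (3) compute Charlson comorbidity bands
#' from pre-surgery diagnosis codes; (4) flag 90-day overall and critical
#' complications; (5) fit unadjusted and adjusted logistic models for both
#' composites, plus per-specialty overall models for specialties with more
#' than `min_specialty_n` surgeries, with Wald and Shapley importance and
#' pseudo-R2. Deterministic given the seeds in the configs.
#'
#' @param cohort a `smoking_cohort` (from [generate_cohort()]) or an
#'   equivalent list of registry tables.
#' @param corpus optional labelled sentence corpus; when supplied, status
#'   observations come from the trained classifier applied to the note
#'   text rather than from the notes' status column.
#' @param nlp_cfg classifier configuration used when `corpus` is given.
#' @param min_precision_known precision constraint for threshold tuning.
#' @param definitions outcome definitions
#'   ([default_outcome_definitions()]).
#' @param min_specialty_n per-specialty models require strictly more than
#'   this many surgeries (default 10000).
#' @param output_dir optional directory; report tables are written there as
#'   CSV (atomically, via a temporary file).
#' @return object of class `study_report`.
#' @export
run_study <- function(cohort, corpus = NULL, nlp_cfg = nlp_config(),
                      min_precision_known = 0.95,
                      definitions = default_outcome_definitions(),
                      min_specialty_n = 10000L, output_dir = NULL) {
  surgeries <- merge(cohort$surgeries,
                     cohort$patients[, c("patient_id", "sex")],
                     by = "patient_id", sort = FALSE)

  nlp_eval <- NULL
  if (!is.null(corpus)) {
    sp <- split_corpus(corpus, 0.1, seed = nlp_cfg$seed)
    model <- train_classifier(sp$train, nlp_cfg)
    policy <- tune_thresholds(model, sp$test, min_precision_known)
    probs <- predict(model, sp$test, type = "prob")
    nlp_eval <- evaluate(sp$test$label,
                         apply_threshold_policy(probs, policy))
    notes <- cohort$status_notes
    note_lab <- apply_threshold_policy(
      predict(model, notes$text, type = "prob"), policy)
    obs <- data.frame(patient_id = notes$patient_id, date = notes$date,
                      status = note_lab, stringsAsFactors = FALSE)
    obs <- obs[obs$status != "unknown", , drop = FALSE]
  } else {
    obs <- cohort$status_notes[, c("patient_id", "date", "status")]
  }

  statuses <- assign_status_all(obs, surgeries)
  bas <- build_analysis_set(surgeries, statuses)
  df <- bas$analysis_set

  cutoff <- tapply(as.numeric(as.Date(df$date)), df$patient_id, min)
  cci <- compute_cci_table(cohort$diagnosis_events,
                           patient_ids = unique(df$patient_id),
                           cutoff_dates = cutoff)
  df <- merge(df, cci[, c("patient_id", "cci_count", "cci_band")],
              by = "patient_id", sort = FALSE)
  flags <- flag_outcomes(df, cohort$diagnosis_events, cohort$care_events,
                         definitions)
  df <- merge(df, flags, by = "surgery_id", sort = FALSE)
  df$year <- as.integer(format(as.Date(df$date), "%Y"))
  df <- df[order(df$surgery_id), ]
  rownames(df) <- NULL

  fits <- list(overall = .fit_pair(df, "overall"),
               critical = .fit_pair(df, "critical"))
  spec_counts <- table(df$specialty)
  for (sp_name in names(spec_counts)[spec_counts > min_specialty_n]) {
    fits[[paste0("overall_", sp_name)]] <-
      .fit_pair(df[df$specialty == sp_name, ], "overall")
  }

  or_table <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    rbind(cbind(model = nm, adjustment = "unadjusted",
                .or_row(f$unadjusted)),
          cbind(model = nm, adjustment = "adjusted", .or_row(f$adjusted)))
  }))
  importance <- do.call(rbind, lapply(names(fits), function(nm)
    cbind(model = nm, fits[[nm]]$importance)))

  report <- structure(list(
    flow = bas$flow,
    baseline = .baseline_table(df),
    yearly = yearly_status_ratios(df),
    or_table = or_table,
    importance = importance,
    pseudo_r2 = lapply(fits, `[[`, "pseudo_r2"),
    nlp_evaluation = nlp_eval,
    analysis_set = df,
    fits = fits), class = "study_report")

  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report:", nrow(x$analysis_set), "surgeries in analysis set\n")
  cat("\nExclusion flow:\n"); print(x$flow)
  cat("\nSmoking-status odds ratios:\n")
  print(x$or_table[x$or_table$model %in% c("overall", "critical"), ],
        digits = 3)
  invisible(x)
}
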