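# Synthetic surgical registry generator.
#
# The cohort emulates the structure the downstream analysis assumes: smoking
# status drives age, sex, ASA class and comorbidity distributions (ex-smokers
# oldest and sickest, producing the confounding that inflates unadjusted odds
# ratios above the conditional ones), and complications are drawn from a
# logistic model on (status, age, sex, ASA, CCI band) with configured
# conditional odds ratios. The overall and critical indicators are drawn
# from their own logistic models coupled through one shared uniform per
# surgery, so each marginal model is exact and critical implies overall.

.default_status_mix <- c(never = 90208, ex = 23101, current = 45326) /
  (90208 + 23101 + 45326)

.default_asa_probs <- rbind(
  never   = c(0.218, 0.420, 0.279, 0.077, 0.006),
  ex      = c(0.067, 0.299, 0.429, 0.193, 0.012),
  current = c(0.110, 0.405, 0.344, 0.129, 0.013)
)

# Per-status prevalence of each Charlson category (columns never/ex/current).
# The eight potentially smoking-related categories follow the baseline-table
# percentages; the remaining categories are set to plausible levels that
# reproduce the observed comorbidity-count bands approximately.
.default_comorbidity_probs <- matrix(
  c( # never   ex      current
    0.023, 0.063, 0.035,   # mi
    0.027, 0.077, 0.030,   # chf
    0.044, 0.150, 0.107,   # pvd
    0.063, 0.117, 0.079,   # cevd
    0.010, 0.020, 0.015,   # dementia
    0.054, 0.162, 0.097,   # copd
    0.010, 0.020, 0.015,   # rheumd
    0.005, 0.010, 0.008,   # pud
    0.005, 0.015, 0.012,   # mld
    0.040, 0.080, 0.050,   # diab
    0.010, 0.030, 0.015,   # diabwc
    0.003, 0.004, 0.004,   # hp
    0.010, 0.030, 0.015,   # rend
    0.205, 0.298, 0.168,   # canc
    0.002, 0.006, 0.004,   # msld
    0.014, 0.025, 0.015,   # metacanc
    0.001, 0.001, 0.002    # aids
  ),
  ncol = 3, byrow = TRUE,
  dimnames = list(c("mi", "chf", "pvd", "cevd", "dementia", "copd", "rheumd",
                    "pud", "mld", "diab", "diabwc", "hp", "rend", "canc",
                    "msld", "metacanc", "aids"),
                  c("never", "ex", "current"))
)

.default_specialty_mix <- c(gastro = 0.170, ortho = 0.154, gyn = 0.118,
                            plastics = 0.077, orl = 0.069, vascular = 0.058,
                            urology = 0.061, breast = 0.049,
                            cardiothoracic = 0.050, neuro = 0.050,
                            other = 0.144)

#' Configuration for the synthetic surgical cohort
#'
#' Defaults encode the study conditions of the emulated registry: the
#' status mix and per-status age/sex/ASA/comorbidity distributions follow
#' the baseline table of the cohort being emulated, the conditional odds
#' ratios default to the adjusted estimates (ex 1.09, current 1.17 for the
#' overall composite; ex 1.09, current 1.21 for the critical one), and the
#' never-smoker complication risks default to 31.0% (overall) and 3.3%
#' (critical).
#'
#' @param n_patients number of patients (warning below 100: unstable
#'   marginals).
#' @param status_mix named probability vector over never/ex/current.
#' @param conditional_or_overall,conditional_or_critical named odds ratios
#'   (`ex`, `current`) versus never-smokers, on the conditional (adjusted)
#'   scale; a `never` entry, if present, is ignored.
#' @param age_params list of `c(mean, sd)` per status; ages are truncated
#'   normal on \[16, 100\] years.
#' @param male_prob per-status probability of male sex.
#' @param asa_probs 3 x 5 matrix of per-status ASA class probabilities.
#' @param comorbidity_probs 17 x 3 matrix of per-status Charlson category
#'   prevalences (rows must match the shipped map's categories).
#' @param comorbidity_frailty_sd standard deviation of the per-patient
#'   normal frailty added to every category's log-odds; comorbidities
#'   cluster within patients, which populates the upper comorbidity-count
#'   bands the way registry data do. Per-category intercepts are
#'   recalibrated so the marginal prevalences still match
#'   `comorbidity_probs`.
#' @param baseline_risk,baseline_risk_critical never-smoker marginal risk of
#'   the overall / critical composite, in (0, 1).
#' @param covariate_log_or log odds ratios of the non-smoking covariates in
#'   the outcome model: `age` (per year), `male`, `asa` (length 5, first
#'   element 0) and `cci_band` (length 6, first element 0).
#' @param specialty_mix named probability vector over specialty labels.
#' @param conflict_note_rate fraction of ex-/current-smoker patients who
#'   carry conflicting timestamped status notes (the assignment rule
#'   resolves them back to the true status).
#' @param surgeries_per_patient maximum surgeries per patient (default 1;
#'   repeated-measures correlation is not modelled).
#' @param years calendar years over which surgeries are spread.
#' @param note_noise_rate character-noise rate applied to note text.
#' @param seed integer seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 20000,
                          status_mix = .default_status_mix,
                          conditional_or_overall = c(ex = 1.09,
                                                     current = 1.17),
                          conditional_or_critical = c(ex = 1.09,
                                                      current = 1.21),
                          age_params = list(never = c(56, 18),
                                            ex = c(64, 14),
                                            current = c(53, 16)),
                          male_prob = c(never = 0.357, ex = 0.588,
                                        current = 0.514),
                          asa_probs = .default_asa_probs,
                          comorbidity_probs = .default_comorbidity_probs,
                          comorbidity_frailty_sd = 1.4,
                          baseline_risk = 0.31,
                          baseline_risk_critical = 0.033,
                          covariate_log_or = list(
                            age = log(1.02), male = log(1.1),
                            asa = log(c(1, 1.8, 3.0, 5.0, 8.0)),
                            cci_band = log(c(1, 1.2, 1.45, 1.7, 2.0, 2.4))),
                          specialty_mix = .default_specialty_mix,
                          conflict_note_rate = 0.10,
                          surgeries_per_patient = 1L,
                          years = 2015:2019,
                          note_noise_rate = 0.02,
                          seed = 1L) {
  if (n_patients < 1) stop("n_patients must be positive", call. = FALSE)
  status_mix <- status_mix[c("never", "ex", "current")]
  if (anyNA(status_mix))
    stop("status_mix must be named over never/ex/current", call. = FALSE)
  check_prob_vector(status_mix, "status_mix")
  check_prob_vector(specialty_mix, "specialty_mix")
  norm_or <- function(v, what) {
    v <- v[setdiff(names(v), "never")]
    v <- v[c("ex", "current")]
    if (anyNA(v) || any(v <= 0))
      stop(what, " must be positive odds ratios named ex/current",
           call. = FALSE)
    v
  }
  conditional_or_overall <- norm_or(conditional_or_overall,
                                    "conditional_or_overall")
  conditional_or_critical <- norm_or(conditional_or_critical,
                                     "conditional_or_critical")
  for (r in c(baseline_risk, baseline_risk_critical))
    if (r <= 0 || r >= 1)
      stop("baseline risks must lie in (0, 1)", call. = FALSE)
  asa_probs <- sweep(asa_probs, 1, rowSums(asa_probs), "/")
  if (conflict_note_rate < 0 || conflict_note_rate > 1)
    stop("conflict_note_rate must lie in [0, 1]", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 status_mix = status_mix,
                 conditional_or_overall = conditional_or_overall,
                 conditional_or_critical = conditional_or_critical,
                 age_params = age_params, male_prob = male_prob,
                 asa_probs = asa_probs,
                 comorbidity_probs = comorbidity_probs,
                 comorbidity_frailty_sd = comorbidity_frailty_sd,
                 baseline_risk = baseline_risk,
                 baseline_risk_critical = baseline_risk_critical,
                 covariate_log_or = covariate_log_or,
                 specialty_mix = specialty_mix,
                 conflict_note_rate = conflict_note_rate,
                 surgeries_per_patient = as.integer(surgeries_per_patient),
                 years = years, note_noise_rate = note_noise_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Apply the Charlson hierarchy to a logical flag matrix (patients x cats).
.hierarchy_flags <- function(flags) {
  flags[flags[, "metacanc"], "canc"] <- FALSE
  flags[flags[, "msld"], "mld"] <- FALSE
  flags[flags[, "diabwc"], "diab"] <- FALSE
  flags
}

.calibrate_intercept <- function(lp, target) {
  stats::uniroot(function(a) mean(stats::plogis(a + lp)) - target,
                 lower = -30, upper = 30, tol = 1e-10)$root
}

#' Generate a synthetic surgical registry
#'
#' Returns the five linked tables the pipeline consumes: patients,
#' surgeries, diagnosis events (pre-surgery comorbidity codes, post-surgery
#' complication codes, and noise codes that must be filtered out), care
#' events (death, reoperation, readmission, ICU/ventilation), and
#' timestamped smoking-status notes with rendered Finnish-style sentence
#' text. Fully deterministic given the config seed.
#'
#' @param config a [cohort_config()].
#' @return list of class `smoking_cohort` with elements `patients`,
#'   `surgeries`, `diagnosis_events`, `care_events`, `status_notes`, and
#'   the `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_patients < 100)
    warning("n_patients < 100: empirical marginals will be unstable",
            call. = FALSE)
  map <- charlson_map()
  with_seed(config$seed, {
    n <- config$n_patients
    status <- sample(names(config$status_mix), n, replace = TRUE,
                     prob = config$status_mix)
    si <- match(status, c("never", "ex", "current"))
    sex <- ifelse(stats::runif(n) < config$male_prob[status], "male",
                  "female")
    agep <- do.call(rbind, config$age_params)[status, , drop = FALSE]
    age0 <- rtruncnorm(n, agep[, 1], agep[, 2], 16, 100)
    pid <- sprintf("P%07d", seq_len(n))

    # surgeries (one per patient by default)
    nsurg_per <- if (config$surgeries_per_patient > 1L)
      sample.int(config$surgeries_per_patient, n, replace = TRUE)
    else rep(1L, n)
    srow <- rep(seq_len(n), nsurg_per)
    ns <- length(srow)
    year0 <- as.Date(sprintf("%d-01-01", min(config$years)))
    span <- as.integer(as.Date(sprintf("%d-12-31", max(config$years))) -
                         year0)
    sdate <- year0 + sample.int(span + 1L, ns, replace = TRUE) - 1L
    first_num <- tapply(as.numeric(sdate), srow, min)
    first_by_pat <- as.Date(as.numeric(first_num[as.character(seq_len(n))]),
                            origin = "1970-01-01")
    birth <- first_by_pat - round(age0 * 365.25)
    age_at <- as.numeric(sdate - birth[srow]) / 365.25
    asa <- integer(ns)
    for (k in 1:3) {
      idx <- which(si[srow] == k)
      asa[idx] <- sample.int(5L, length(idx), replace = TRUE,
                             prob = config$asa_probs[k, ])
    }
    specialty <- sample(names(config$specialty_mix), ns, replace = TRUE,
                        prob = config$specialty_mix)

    # comorbidity category flags per patient: per-category Bernoulli with a
    # shared per-patient frailty on the log-odds, intercepts recalibrated so
    # marginal prevalences match the configured per-status values
    cats <- rownames(config$comorbidity_probs)
    frailty <- stats::rnorm(n, 0, config$comorbidity_frailty_sd)
    pr <- matrix(0, n, length(cats), dimnames = list(NULL, cats))
    for (k in 1:3) {
      idx <- which(si == k)
      if (!length(idx)) next
      fsub <- frailty[if (length(idx) > 5000) idx[1:5000] else idx]
      for (cat in cats) {
        p_target <- config$comorbidity_probs[cat,
                                             c("never", "ex", "current")[k]]
        off <- stats::uniroot(function(a)
          mean(stats::plogis(a + fsub)) - p_target,
          lower = -30, upper = 10, tol = 1e-6)$root
        pr[idx, cat] <- stats::plogis(off + frailty[idx])
      }
    }
    flags <- matrix(stats::runif(n * length(cats)) < pr, nrow = n,
                    dimnames = list(NULL, cats))
    eff_flags <- .hierarchy_flags(flags)
    cci_count <- rowSums(eff_flags)
    band <- cci_band(cci_count)

    # outcome models (linear predictors without intercept)
    co <- config$covariate_log_or
    lp_common <- co$age * age_at +
      co$male * (sex[srow] == "male") +
      co$asa[asa] +
      co$cci_band[as.integer(band[srow])]
    b_status_o <- c(never = 0, log(config$conditional_or_overall))
    b_status_c <- c(never = 0, log(config$conditional_or_critical))
    names(b_status_o) <- names(b_status_c) <- c("never", "ex", "current")
    lp_o <- lp_common + b_status_o[status[srow]]
    lp_c <- lp_common + b_status_c[status[srow]]
    nev <- status[srow] == "never"
    a_o <- .calibrate_intercept(lp_o[nev], config$baseline_risk)
    a_c <- .calibrate_intercept(lp_c[nev], config$baseline_risk_critical)
    u <- stats::runif(ns)
    p_o <- stats::plogis(a_o + lp_o)
    p_c <- stats::plogis(a_c + lp_c)
    overall <- u < p_o
    critical <- u < pmin(p_c, p_o)

    surgeries <- data.frame(
      surgery_id = sprintf("S%07d", seq_len(ns)),
      patient_id = pid[srow], date = sdate,
      specialty = specialty, asa_class = asa,
      age_at_surgery = round(age_at, 1), stringsAsFactors = FALSE)

    # diagnosis events: comorbidity codes before surgery
    diag_list <- list()
    for (cat in cats) {
      idx <- which(flags[, cat])
      if (!length(idx)) next
      prefixes <- map$prefix[map$category == cat]
      diag_list[[cat]] <- data.frame(
        patient_id = pid[idx],
        icd10_code = sample(prefixes, length(idx), replace = TRUE),
        date = first_by_pat[idx] - sample(30:1825, length(idx),
                                          replace = TRUE),
        stringsAsFactors = FALSE)
    }

    # complication events in days 1..90 after surgery (care events may fall
    # on day 0); ICD-coded complications use day >= 1 so that a same-day
    # complication code cannot leak into the pre-surgery comorbidity lookback
    defs <- default_outcome_definitions()
    crit_icd <- defs$critical$icd10_prefixes
    over_only_icd <- setdiff(defs$overall$icd10_prefixes, crit_icd)
    care_list <- list()
    death_day <- rep(NA_integer_, ns)

    ci <- which(critical)
    if (length(ci)) {
      mode <- sample(c("icu", "death", "icd"), length(ci), replace = TRUE,
                     prob = c(0.35, 0.15, 0.50))
      day <- sample(0:90, length(ci), replace = TRUE)
      icd_i <- ci[mode == "icd"]
      if (length(icd_i))
        diag_list$crit <- data.frame(
          patient_id = pid[srow[icd_i]],
          icd10_code = sample(crit_icd, length(icd_i), replace = TRUE),
          date = sdate[icd_i] + pmax(1L, day[mode == "icd"]),
          stringsAsFactors = FALSE)
      ev_i <- ci[mode != "icd"]
      if (length(ev_i)) {
        kind <- ifelse(mode[mode != "icd"] == "death", "death",
                       "icu_or_ventilation")
        care_list$crit <- data.frame(
          patient_id = pid[srow[ev_i]], kind = kind,
          date = sdate[ev_i] + day[mode != "icd"], stringsAsFactors = FALSE)
        death_day[ev_i[kind == "death"]] <- day[mode != "icd"][kind == "death"]
      }
    }
    oi <- which(overall & !critical)
    if (length(oi)) {
      mode <- sample(c("readmission", "reoperation", "icd"), length(oi),
                     replace = TRUE, prob = c(0.25, 0.10, 0.65))
      day <- sample(0:90, length(oi), replace = TRUE)
      icd_i <- oi[mode == "icd"]
      if (length(icd_i))
        diag_list$over <- data.frame(
          patient_id = pid[srow[icd_i]],
          icd10_code = sample(over_only_icd, length(icd_i), replace = TRUE),
          date = sdate[icd_i] + pmax(1L, day[mode == "icd"]),
          stringsAsFactors = FALSE)
      ev_i <- oi[mode != "icd"]
      if (length(ev_i))
        care_list$over <- data.frame(
          patient_id = pid[srow[ev_i]], kind = mode[mode != "icd"],
          date = sdate[ev_i] + day[mode != "icd"], stringsAsFactors = FALSE)
    }

    # noise diagnoses: complication-list codes outside the window and
    # unrelated codes inside it, to exercise the window/prefix filters
    noise_out <- which(stats::runif(ns) < 0.15)
    if (length(noise_out))
      diag_list$noise_out <- data.frame(
        patient_id = pid[srow[noise_out]],
        icd10_code = sample(defs$overall$icd10_prefixes, length(noise_out),
                            replace = TRUE),
        date = sdate[noise_out] + sample(91:240, length(noise_out),
                                         replace = TRUE),
        stringsAsFactors = FALSE)
    noise_in <- which(stats::runif(ns) < 0.25)
    if (length(noise_in))
      diag_list$noise_in <- data.frame(
        patient_id = pid[srow[noise_in]],
        icd10_code = sample(c("Z018", "M791", "H522", "L209"),
                            length(noise_in), replace = TRUE),
        date = sdate[noise_in] + sample(1:90, length(noise_in),
                                        replace = TRUE),
        stringsAsFactors = FALSE)

    diagnosis_events <- do.call(rbind, diag_list)
    rownames(diagnosis_events) <- NULL
    care_events <- if (length(care_list)) do.call(rbind, care_list)
    else data.frame(patient_id = character(), kind = character(),
                    date = as.Date(character()))
    rownames(care_events) <- NULL

    # invariant: no events after a patient's death
    dead <- !is.na(death_day)
    if (any(dead)) {
      dd <- stats::setNames(as.numeric(sdate[dead]) + death_day[dead],
                            pid[srow[dead]])
      drop_after_death <- function(ev) {
        lim <- dd[ev$patient_id]
        ev[is.na(lim) | as.numeric(as.Date(ev$date)) <= lim, , drop = FALSE]
      }
      diagnosis_events <- drop_after_death(diagnosis_events)
      care_events <- drop_after_death(care_events)
    }

    # status notes: one note of the true class before the first surgery;
    # conflicting earlier/recent pairs for a fraction of ex/current patients
    note_date <- first_by_pat - sample(7:365, n, replace = TRUE)
    notes <- data.frame(patient_id = pid, date = note_date, status = status,
                        stringsAsFactors = FALSE)
    confl <- which(status %in% c("ex", "current") &
                     stats::runif(n) < config$conflict_note_rate)
    if (length(confl)) {
      earlier <- ifelse(status[confl] == "current",
                        sample(c("ex", "never"), length(confl),
                               replace = TRUE),
                        "current")
      extra <- data.frame(patient_id = pid[confl],
                          date = note_date[confl] -
                            sample(60:1000, length(confl), replace = TRUE),
                          status = earlier, stringsAsFactors = FALSE)
      # for half of the conflicted ex-smokers the most recent note reads
      # "never" (preceded by "current"), exercising the never->ex override
      flip <- confl[status[confl] == "ex" &
                      stats::runif(length(confl)) < 0.5]
      notes$status[flip] <- "never"
      notes <- rbind(notes, extra)
    }
    rend <- .render_sentences(notes$status, config$note_noise_rate)
    notes$text <- rend$text
    notes <- notes[order(notes$patient_id, notes$date), ]
    rownames(notes) <- NULL

    patients <- data.frame(patient_id = pid, sex = sex, birth_date = birth,
                           true_status = status, stringsAsFactors = FALSE)
    structure(list(patients = patients, surgeries = surgeries,
                   diagnosis_events = diagnosis_events,
                   care_events = care_events, status_notes = notes,
                   config = config),
              class = "smoking_cohort")
  })
}

#' @export
print.smoking_cohort <- function(x, ...) {
  cat("Synthetic surgical cohort:\n")
  cat("  patients:        ", nrow(x$patients), "\n")
  cat("  surgeries:       ", nrow(x$surgeries), "\n")
  cat("  diagnosis events:", nrow(x$diagnosis_events), "\n")
  cat("  care events:     ", nrow(x$care_events), "\n")
  cat("  status notes:    ", nrow(x$status_notes), "\n")
  invisible(x)
}
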