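# Charlson comorbidity index from ICD-10 codes.
#
# The mapping ships as an editable CSV (Quan ICD-10 coding with the original
# Charlson weights) so alternative weightings can be swapped in. Matching is
# prefix-based on the normalized code (dot removed, upper case); overlapping
# prefixes are resolved by longest-prefix match, and the hierarchy rules
# (metastatic tumour supersedes localized cancer, moderate/severe liver
# disease supersedes mild, complicated diabetes supersedes uncomplicated)
# remove both flag and weight of the superseded category.

CCI_SMOKING_RELATED <- c("mi", "chf", "pvd", "cevd", "copd", "hp",
                         "canc", "metacanc")

#' Load a Charlson category map
#'
#' @param file CSV with columns `category`, `prefix`, `weight`,
#'   `supersedes`; defaults to the shipped Quan ICD-10 coding with original
#'   Charlson weights.
#' @return data frame of class `charlson_map`.
#' @export
charlson_map <- function(file = system.file("extdata",
                                            "charlson_icd10_quan.csv",
                                            package = "smokesurg")) {
  m <- utils::read.csv(file, stringsAsFactors = FALSE,
                       colClasses = c("character", "character",
                                      "integer", "character"))
  stopifnot(all(c("category", "prefix", "weight", "supersedes") %in%
                  names(m)))
  m$prefix <- toupper(m$prefix)
  if (any(m$weight < 1)) stop("weights must be >= 1", call. = FALSE)
  class(m) <- c("charlson_map", "data.frame")
  m
}

normalize_icd10 <- function(codes) {
  toupper(gsub("[. ]", "", as.character(codes)))
}

icd10_valid <- function(codes) {
  grepl("^[A-Z][0-9]{2}", normalize_icd10(codes))
}

# Map each (unique) code to its Charlson category by longest-prefix match;
# returns NA for unmapped codes.
.map_codes_to_category <- function(codes, map) {
  codes <- normalize_icd10(codes)
  uc <- unique(codes)
  cat_u <- rep(NA_character_, length(uc))
  best <- integer(length(uc))
  for (i in seq_len(nrow(map))) {
    p <- map$prefix[i]
    nl <- nchar(p)
    hit <- startsWith(uc, p) & nl > best
    if (any(hit)) {
      cat_u[hit] <- map$category[i]
      best[hit] <- nl
    }
  }
  cat_u[match(codes, uc)]
}

.apply_hierarchy <- function(categories, map) {
  sup <- unique(map[map$supersedes != "" & !is.na(map$supersedes),
                    c("category", "supersedes")])
  for (i in seq_len(nrow(sup))) {
    if (sup$category[i] %in% categories)
      categories <- setdiff(categories, sup$supersedes[i])
  }
  categories
}

#' Compute the Charlson comorbidity index for one patient
#'
#' A category is flagged iff any (syntactically valid) code starts with one
#' of its prefixes; hierarchy rules then drop superseded categories so they
#' contribute neither flag nor weight. Invalid codes are skipped with a
#' warning. The result is idempotent and independent of code order and
#' duplication.
#'
#' @param codes character vector of ICD-10 codes (dots allowed).
#' @param map a [charlson_map()].
#' @return object of class `cci_result`: list with `flags` (named logical
#'   over all categories), `count` (number of flagged categories), `score`
#'   (sum of weights), and `category_band` (factor with levels
#'   `0,1,2,3,4,>=5` on the count).
#' @examples
#' compute_cci(c("I21.0", "C50", "C78"))
#' @export
compute_cci <- function(codes, map = charlson_map()) {
  codes <- unique(as.character(codes))
  codes <- codes[!is.na(codes) & nzchar(codes)]
  bad <- !icd10_valid(codes)
  if (any(bad)) {
    warning("skipping ", sum(bad), " syntactically invalid ICD-10 code(s): ",
            paste(utils::head(codes[bad], 5), collapse = ", "), call. = FALSE)
    codes <- codes[!bad]
  }
  all_cats <- unique(map$category)
  cats <- unique(stats::na.omit(.map_codes_to_category(codes, map)))
  cats <- .apply_hierarchy(cats, map)
  flags <- stats::setNames(all_cats %in% cats, all_cats)
  wmap <- tapply(map$weight, map$category, function(w) w[1])
  score <- sum(wmap[cats])
  count <- length(cats)
  structure(list(flags = flags, count = count,
                 score = if (count) as.integer(score) else 0L,
                 category_band = cci_band(count)),
            class = "cci_result")
}

#' Band a comorbidity count as used in baseline tables and regression
#'
#' @param count integer vector of comorbidity counts (or weighted scores,
#'   if banding scores instead).
#' @return factor with levels `0`, `1`, `2`, `3`, `4`, `>=5`.
#' @export
cci_band <- function(count) {
  factor(ifelse(count >= 5, ">=5", as.character(count)),
         levels = c("0", "1", "2", "3", "4", ">=5"))
}

#' Flags of potentially smoking-related Charlson categories
#'
#' Restricts a [compute_cci()] result to the fixed subset of categories
#' regarded as potentially smoking-related in the baseline table: acute
#' myocardial infarction, congestive heart failure, peripheral vascular
#' disease, cerebrovascular disease, chronic pulmonary disease,
#' hemiplegia/paraplegia, cancer, and metastatic solid tumour.
#'
#' @param result a `cci_result`.
#' @return named logical vector over the smoking-related categories that
#'   are flagged (possibly empty).
#' @export
smoking_related_flags <- function(result) {
  stopifnot(inherits(result, "cci_result"))
  f <- result$flags[intersect(names(result$flags), CCI_SMOKING_RELATED)]
  f[f]
}

#' Charlson comorbidity per patient from a diagnosis-event table
#'
#' Vectorized companion of [compute_cci()] for registry use: diagnosis
#' events are restricted to dates on or before each patient's surgery date
#' (the lookback window covers all history by default) and collapsed to one
#' count/score/band per patient. Patients without any qualifying code get
#' count 0.
#'
#' @param diagnosis_events data frame with `patient_id`, `icd10_code`, and
#'   optionally `date`.
#' @param patient_ids patients to report (defaults to those present).
#' @param cutoff_dates optional named vector/list of per-patient cutoff
#'   dates (e.g. surgery dates); events after the cutoff are ignored.
#' @param map a [charlson_map()].
#' @return data frame with `patient_id`, `cci_count`, `cci_score`,
#'   `cci_band`.
#' @export
compute_cci_table <- function(diagnosis_events, patient_ids = NULL,
                              cutoff_dates = NULL, map = charlson_map()) {
  ev <- diagnosis_events
  if (!is.null(cutoff_dates) && nrow(ev)) {
    cut <- cutoff_dates[as.character(ev$patient_id)]
    keep <- !is.na(cut) & as.Date(ev$date) <= as.Date(cut,
                                                      origin = "1970-01-01")
    ev <- ev[keep, , drop = FALSE]
  }
  if (is.null(patient_ids)) patient_ids <- unique(ev$patient_id)
  wmap <- tapply(map$weight, map$category, function(w) w[1])
  if (nrow(ev)) {
    ev$category <- .map_codes_to_category(ev$icd10_code, map)
    ev <- ev[!is.na(ev$category), c("patient_id", "category")]
    ev <- unique(ev)
    per <- split(ev$category, ev$patient_id)
    per <- lapply(per, .apply_hierarchy, map = map)
    counts <- vapply(per, length, 1L)
    scores <- vapply(per, function(cc) as.integer(sum(wmap[cc])), 1L)
  } else {
    counts <- scores <- integer(0)
  }
  out <- data.frame(patient_id = patient_ids, stringsAsFactors = FALSE)
  i <- match(as.character(out$patient_id), names(counts))
  out$cci_count <- ifelse(is.na(i), 0L, counts[i])
  out$cci_score <- ifelse(is.na(i), 0L, scores[i])
  out$cci_band <- cci_band(out$cci_count)
  out
}
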