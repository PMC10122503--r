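# Collapse timestamped smoking-status observations into one preoperative
# status per surgery.
#
# Rule: among observations dated on or before the surgery (same-day notes
# count as preoperative), the most recent status wins — unless that status
# is "never" while any earlier preoperative observation is "current" or
# "ex", in which case the assigned status is "ex" (a once-documented smoker
# cannot revert to never-smoker; the conflict is read as having quit). A
# same-day tie between conflicting observations resolves by the precedence
# current > ex > never, conservative toward detecting smoking exposure.

#' Assign the preoperative smoking status for one surgery
#'
#' @param observations data frame with `date` and `status` columns for one
#'   patient; `status` must be one of `current`, `ex`, `never` (unknowns
#'   are filtered upstream). Row order never affects the result.
#' @param surgery_date the surgery date.
#' @return one of `"current"`, `"ex"`, `"never"`, `"unknown"` (`unknown`
#'   iff no preoperative observation exists).
#' @examples
#' obs <- data.frame(date = as.Date(c("2017-05-01", "2019-03-01")),
#'                   status = c("current", "never"))
#' assign_preoperative_status(obs, as.Date("2019-12-01"))  # "ex"
#' @export
assign_preoperative_status <- function(observations, surgery_date) {
  stopifnot(all(observations$status %in% KNOWN_CLASSES))
  d <- as.Date(observations$date)
  keep <- d <= as.Date(surgery_date)
  if (!any(keep)) return("unknown")
  st <- observations$status[keep]
  d <- d[keep]
  prec <- c(current = 1L, ex = 2L, never = 3L)
  o <- order(as.numeric(d), -prec[st], decreasing = TRUE)
  latest <- st[o[1]]
  if (latest == "never" && any(st %in% c("current", "ex"))) "ex"
  else latest
}

#' Assign preoperative statuses for a whole surgery table
#'
#' @param observations data frame with `patient_id`, `date`, `status`.
#' @param surgeries data frame with `surgery_id`, `patient_id`, `date`.
#' @return data frame with `surgery_id` and assigned `status`.
#' @export
assign_status_all <- function(observations, surgeries) {
  prec <- c(current = 1L, ex = 2L, never = 3L)
  j <- merge(
    data.frame(patient_id = as.character(observations$patient_id),
               odate = as.Date(observations$date),
               ostatus = as.character(observations$status),
               stringsAsFactors = FALSE),
    data.frame(patient_id = as.character(surgeries$patient_id),
               surgery_id = as.character(surgeries$surgery_id),
               sdate = as.Date(surgeries$date), stringsAsFactors = FALSE),
    by = "patient_id")
  j <- j[j$odate <= j$sdate, , drop = FALSE]
  status <- stats::setNames(rep("unknown", nrow(surgeries)),
                            as.character(surgeries$surgery_id))
  if (nrow(j)) {
    # ascending date, same-day ties ordered so the highest-precedence
    # status comes last; the last row per surgery is the winning note
    o <- order(j$surgery_id, j$odate, -prec[j$ostatus])
    j <- j[o, , drop = FALSE]
    last <- !duplicated(j$surgery_id, fromLast = TRUE)
    ever_smoked <- tapply(j$ostatus %in% c("current", "ex"),
                          j$surgery_id, any)
    s <- j$ostatus[last]
    ids <- j$surgery_id[last]
    s[s == "never" & ever_smoked[ids]] <- "ex"
    status[ids] <- s
  }
  data.frame(surgery_id = surgeries$surgery_id, status = unname(status),
             stringsAsFactors = FALSE)
}

#' Build the analysis set and the exclusion flow table
#'
#' Drops surgeries with unknown smoking status, age below 16 years, or
#' missing ASA class, and reports a flow-diagram style count table in which
#' retained + excluded reconciles exactly with the input at every step.
#'
#' @param surgeries surgery table including `age_at_surgery` and
#'   `asa_class`.
#' @param statuses result of [assign_status_all()] (or a data frame with
#'   `surgery_id`, `status`).
#' @return list with `analysis_set` (surgeries + `status` column) and
#'   `flow` (data frame of step, excluded and remaining counts).
#' @export
build_analysis_set <- function(surgeries, statuses) {
  x <- merge(surgeries, statuses, by = "surgery_id", all.x = TRUE,
             sort = FALSE)
  x$status[is.na(x$status)] <- "unknown"
  n0 <- nrow(x)
  steps <- list()
  drop_unknown <- x$status == "unknown"
  steps$unknown_smoking_status <- sum(drop_unknown)
  x <- x[!drop_unknown, , drop = FALSE]
  drop_age <- x$age_at_surgery < 16
  steps$age_below_16 <- sum(drop_age)
  x <- x[!drop_age, , drop = FALSE]
  drop_asa <- is.na(x$asa_class)
  steps$unknown_asa_class <- sum(drop_asa)
  x <- x[!drop_asa, , drop = FALSE]
  flow <- data.frame(step = c("input", names(steps), "final"),
                     excluded = c(0L, unlist(steps, use.names = FALSE), 0L),
                     stringsAsFactors = FALSE)
  flow$remaining <- n0 - cumsum(flow$excluded)
  rownames(x) <- NULL
  list(analysis_set = x, flow = flow)
}
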