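# independent re-statement of the assignment rule, used as oracle: take the
# preoperative observations, pick the chronologically last one (same-day
# conflicts resolved current > ex > never), and demote a winning "never" to
# "ex" whenever any preoperative observation shows smoking exposure
oracle_assign <- function(dates, statuses, surgery_date) {
  pre <- dates <= surgery_date
  if (!any(pre)) return("unknown")
  dates <- dates[pre]; statuses <- statuses[pre]
  latest_day <- max(dates)
  on_day <- statuses[dates == latest_day]
  winner <- if ("current" %in% on_day) "current"
  else if ("ex" %in% on_day) "ex" else "never"
  if (winner == "never" && any(statuses != "never")) "ex" else winner
}

test_that("most-recent-unless-never rule handles the canonical cases", {
  obs <- data.frame(date = as.Date(c("2017-06-01", "2019-02-01")),
                    status = c("current", "never"))
  expect_equal(assign_preoperative_status(obs, as.Date("2019-12-01")), "ex")
  expect_equal(assign_preoperative_status(
    data.frame(date = as.Date("2019-02-01"), status = "never"),
    as.Date("2019-12-01")), "never")
  obs2 <- data.frame(date = as.Date(c("2018-03-01", "2019-05-01")),
                     status = c("current", "ex"))
  expect_equal(assign_preoperative_status(obs2, as.Date("2019-12-01")),
               "ex")
  expect_equal(assign_preoperative_status(obs2, as.Date("2018-06-01")),
               "current")
  # no preoperative observation
  expect_equal(assign_preoperative_status(obs2, as.Date("2018-01-01")),
               "unknown")
})

test_that("rule matches brute-force oracle over all small configurations", {
  days <- as.Date(c("2018-01-01", "2018-06-01", "2019-01-01"))
  surgeries <- as.Date(c("2018-06-01", "2019-06-01"))
  statuses <- c("current", "ex", "never")
  for (n_obs in 1:3) {
    combos <- expand.grid(rep(list(seq_along(days)), n_obs))
    labels <- expand.grid(rep(list(statuses), n_obs),
                          stringsAsFactors = FALSE)
    for (i in seq_len(nrow(combos))) {
      d <- days[unlist(combos[i, ])]
      for (j in seq_len(nrow(labels))) {
        st <- unlist(labels[j, ])
        obs <- data.frame(date = d, status = st,
                          stringsAsFactors = FALSE)
        for (sd in surgeries) {
          expect_identical(
            assign_preoperative_status(obs, sd),
            oracle_assign(d, st, as.Date(sd, origin = "1970-01-01")))
        }
      }
    }
  }
})

test_that("result is invariant to observation order and future notes", {
  obs <- data.frame(date = as.Date(c("2017-01-01", "2018-01-01",
                                     "2019-01-01")),
                    status = c("never", "current", "ex"))
  sd <- as.Date("2019-06-01")
  base <- assign_preoperative_status(obs, sd)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1)))
    expect_identical(assign_preoperative_status(obs[perm, ], sd), base)
  # adding an observation after the surgery never changes the result
  later <- rbind(obs, data.frame(date = as.Date("2020-01-01"),
                                 status = "never"))
  expect_identical(assign_preoperative_status(later, sd), base)
})

test_that("the never-to-ex override can only yield ex", {
  # exhaustive over 2-observation histories: whenever the winning status
  # differs from the latest observation, the winner is ex and the latest
  # observation is never
  days <- as.Date(c("2018-01-01", "2019-01-01"))
  sd <- as.Date("2019-06-01")
  for (s1 in c("current", "ex", "never")) for (s2 in c("current", "ex",
                                                       "never")) {
    obs <- data.frame(date = days, status = c(s1, s2))
    got <- assign_preoperative_status(obs, sd)
    if (got != s2) {
      expect_identical(s2, "never")
      expect_identical(got, "ex")
    }
  }
})

test_that("vectorized assignment equals the per-surgery rule", {
  coh <- shared_cohort()
  st <- assign_status_all(coh$status_notes, coh$surgeries)
  idx <- seq(1, nrow(coh$surgeries), by = 37)
  for (i in idx) {
    obs <- coh$status_notes[coh$status_notes$patient_id ==
                              coh$surgeries$patient_id[i], ]
    expect_identical(st$status[i],
                     assign_preoperative_status(obs,
                                                coh$surgeries$date[i]))
  }
})

test_that("analysis-set exclusions reconcile exactly", {
  surg <- data.frame(surgery_id = sprintf("s%02d", 1:10),
                     patient_id = sprintf("p%02d", 1:10),
                     age_at_surgery = c(70, 15, 40, 50, 12, 60, 33, 45, 80,
                                        25),
                     asa_class = c(1, 2, NA, 3, 2, 1, 2, NA, 4, 2))
  statuses <- data.frame(surgery_id = surg$surgery_id,
                         status = c("never", "ex", "current", "unknown",
                                    "never", "ex", "current", "never",
                                    "unknown", "ex"))
  res <- build_analysis_set(surg, statuses)
  expect_equal(res$flow$remaining[1], 10)
  expect_equal(sum(res$flow$excluded), 10 - nrow(res$analysis_set))
  expect_equal(res$flow$remaining[nrow(res$flow)], nrow(res$analysis_set))
  # unknown status removed first (2), then underage (2 remaining), then
  # missing ASA among the rest
  expect_equal(res$flow$excluded[res$flow$step == "unknown_smoking_status"],
               2)
  expect_false(any(res$analysis_set$status == "unknown"))
  expect_true(all(res$analysis_set$age_at_surgery >= 16))
  expect_false(anyNA(res$analysis_set$asa_class))
  # clean input: zero exclusions
  clean <- build_analysis_set(surg[c(1, 4, 6), ],
                              data.frame(surgery_id = surg$surgery_id[c(1,
                                                                        4,
                                                                        6)],
                                         status = "ex"))
  expect_true(all(clean$flow$excluded == 0))
  expect_equal(nrow(clean$analysis_set), 3)
})
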