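test_that("a separable toy corpus is learned perfectly and reproducibly", {
  corp <- toy_separable_corpus(200)
  cfg <- nlp_config(hash_buckets = 2^14, epochs = 5, seed = 3L)
  m1 <- train_classifier(corp, cfg)
  expect_equal(mean(predict(m1, corp, type = "class") == corp$label), 1)
  m2 <- train_classifier(corp, cfg)
  expect_identical(m1$class_weights, m2$class_weights)
  expect_identical(m1$embeddings, m2$embeddings)
  # mean training loss decreases over epochs on this separable problem
  expect_lt(utils::tail(m1$epoch_loss, 1), m1$epoch_loss[1])
})

test_that("training requires all four classes", {
  corp <- toy_separable_corpus(100)
  expect_error(train_classifier(corp[corp$label != "ex", ]),
               "absent from training data")
})

test_that("predictions are proper distributions; empty input is uniform", {
  corp <- toy_separable_corpus(80)
  m <- train_classifier(corp, nlp_config(hash_buckets = 2^14, epochs = 3,
                                         seed = 1L))
  p <- predict(m, c("tupakoi edelleen joka paiva", "", "!!!"))
  expect_equal(unname(rowSums(p)), rep(1, 3), tolerance = 1e-9)
  expect_equal(unname(p[2, ]), rep(0.25, 4))
  expect_equal(unname(p[3, ]), rep(0.25, 4))  # normalizes to empty
  expect_identical(unname(attr(p, "no_features")), c(FALSE, TRUE, TRUE))
  # purity: a duplicated sentence gets an identical distribution
  p2 <- predict(m, rep("tupakoi edelleen joka paiva", 2))
  expect_identical(p2[1, ], p2[2, ])
})

test_that("held-out accuracy on the default synthetic corpus is high", {
  co <- generate_corpus(corpus_config(n_sentences = 10000, seed = 14L))
  sp <- split_corpus(co, 0.1, seed = 14L)
  m <- train_classifier(sp$train, nlp_config(seed = 14L))
  acc <- mean(predict(m, sp$test, type = "class") == sp$test$label)
  expect_gt(acc, 0.85)
})

test_that("threshold policy gates the argmax as specified", {
  pol <- threshold_policy(current = 0.8, ex = 0.5, never = 0.5)
  d1 <- c(current = 0.92, ex = 0.04, never = 0.02, unknown = 0.02)
  expect_equal(apply_threshold_policy(d1, pol), "current")
  d2 <- c(current = 0.60, ex = 0.25, never = 0.10, unknown = 0.05)
  expect_equal(apply_threshold_policy(d2, pol), "unknown")
  # argmax unknown is unknown at any threshold
  d3 <- c(current = 0.1, ex = 0.1, never = 0.1, unknown = 0.7)
  expect_equal(apply_threshold_policy(d3, threshold_policy(0, 0, 0)),
               "unknown")
  expect_error(threshold_policy(current = 1.2), "\\[0, 1\\]")
})

test_that("abstention is monotone in each threshold", {
  set.seed(15)
  probs <- matrix(stats::rexp(400 * 4), ncol = 4)
  probs <- probs / rowSums(probs)
  colnames(probs) <- c("current", "ex", "never", "unknown")
  for (cls in c("current", "ex", "never")) {
    lo <- hi <- list(current = 0.2, ex = 0.2, never = 0.2)
    hi[[cls]] <- 0.6
    lab_lo <- apply_threshold_policy(probs, do.call(threshold_policy, lo))
    lab_hi <- apply_threshold_policy(probs, do.call(threshold_policy, hi))
    expect_lte(sum(lab_hi == cls), sum(lab_lo == cls))
    # retained set at the higher threshold nests inside the lower one
    expect_true(all(which(lab_hi == cls) %in% which(lab_lo == cls)))
  }
})

test_that("threshold tuning equals exhaustive grid search on a toy set", {
  dists <- rbind(
    c(0.90, 0.05, 0.03, 0.02), c(0.70, 0.20, 0.05, 0.05),
    c(0.55, 0.30, 0.10, 0.05), c(0.85, 0.05, 0.05, 0.05),
    c(0.10, 0.80, 0.05, 0.05), c(0.05, 0.60, 0.30, 0.05),
    c(0.20, 0.65, 0.10, 0.05), c(0.05, 0.90, 0.03, 0.02),
    c(0.05, 0.05, 0.85, 0.05), c(0.10, 0.10, 0.75, 0.05),
    c(0.05, 0.15, 0.55, 0.25), c(0.02, 0.03, 0.05, 0.90))
  colnames(dists) <- c("current", "ex", "never", "unknown")
  gold <- c("current", "current", "ex", "current",
            "ex", "never", "ex", "ex",
            "never", "never", "unknown", "unknown")
  min_prec <- 0.75
  step <- 0.05
  pol <- tune_thresholds(dists, gold, min_precision_known = min_prec,
                         grid_step = step)
  # oracle: enumerate the full 3-d grid, maximize retained known-class true
  # positives under the per-class precision constraints, ties -> lower
  # thresholds (lexicographic)
  grid <- seq(0, 1, by = step)
  best <- NULL
  best_obj <- -1
  for (tc in grid) for (te in grid) for (tn in grid) {
    lab <- apply_threshold_policy(dists, threshold_policy(tc, te, tn))
    ok <- TRUE
    tp_tot <- 0
    for (cls in c("current", "ex", "never")) {
      assigned <- lab == cls
      tp <- sum(assigned & gold == cls)
      if (sum(assigned) > 0 && tp / sum(assigned) < min_prec) ok <- FALSE
      tp_tot <- tp_tot + tp
    }
    if (ok && tp_tot > best_obj) {
      best_obj <- tp_tot
      best <- c(tc, te, tn)
    }
  }
  expect_equal(unname(unlist(pol)), best, tolerance = 1e-12)
})

test_that("degenerate tuning constraints behave as specified", {
  dists <- rbind(c(0.9, 0.04, 0.04, 0.02), c(0.04, 0.9, 0.04, 0.02),
                 c(0.04, 0.04, 0.9, 0.02))
  colnames(dists) <- c("current", "ex", "never", "unknown")
  # unconstrained: all thresholds zero
  pol0 <- tune_thresholds(dists, c("current", "ex", "never"),
                          min_precision_known = 0)
  expect_equal(unname(unlist(pol0)), c(0, 0, 0))
  # classifier wrong on every sentence: infeasible, all-abstain + warning
  expect_warning(
    pol1 <- tune_thresholds(dists, c("ex", "never", "current"),
                            min_precision_known = 1),
    "infeasible")
  expect_equal(unname(unlist(pol1)), c(1, 1, 1))
})

test_that("evaluation metrics, CIs, and macro averages are correct", {
  # perfect predictions
  g <- rep(c("current", "ex", "never", "unknown"), times = c(5, 4, 6, 5))
  ev <- evaluate(g, g)
  expect_equal(ev$accuracy, 1)
  expect_true(all(ev$per_class$precision == 1))
  expect_true(all(ev$per_class$recall == 1))
  # closed-form normal-approximation CI: p = 0.9, n = 100
  ci <- evaluate(c(rep("ex", 90), rep("never", 10)),
                 rep("ex", 100))$per_class
  row <- ci[ci$class == "ex", ]
  expect_equal(row$precision, 0.9)
  expect_equal(round(row$precision_lo, 3), 0.841)
  expect_equal(round(row$precision_hi, 3), 0.959)
  # confusion-matrix trace over total equals accuracy
  set.seed(16)
  g2 <- sample(c("current", "ex", "never", "unknown"), 200, replace = TRUE)
  p2 <- sample(c("current", "ex", "never", "unknown"), 200, replace = TRUE)
  ev2 <- evaluate(g2, p2)
  expect_equal(sum(diag(ev2$confusion)) / sum(ev2$confusion), ev2$accuracy)
  expect_equal(as.numeric(rowSums(ev2$confusion)),
               as.numeric(table(factor(g2, c("current", "ex", "never",
                                             "unknown")))))
  # permutation invariance
  perm <- sample(200)
  ev3 <- evaluate(g2[perm], p2[perm])
  expect_identical(ev2$confusion, ev3$confusion)
  expect_equal(ev2$macro_precision_known, ev3$macro_precision_known)
  # a class never predicted has NA precision, never zero
  ev4 <- evaluate(c("current", "ex"), c("current", "current"))
  expect_true(is.na(ev4$per_class$precision[ev4$per_class$class ==
                                              "never"]))
})

test_that("macro averages exclude unknown; both recall weightings differ", {
  # construct predictions with known per-class rates
  g <- c(rep("current", 10), rep("ex", 10), rep("never", 20),
         rep("unknown", 10))
  p <- g
  p[1:5] <- "unknown"    # current recall 0.5
  p[31:34] <- "unknown"  # never recall 0.8
  ev <- evaluate(g, p)
  expect_equal(ev$macro_recall_known, mean(c(0.5, 1, 0.8)))
  expect_equal(ev$weighted_recall_known,
               (10 * 0.5 + 10 * 1 + 20 * 0.8) / 40)
  expect_false(isTRUE(all.equal(ev$macro_recall_known,
                                ev$weighted_recall_known)))
})

test_that("stratified cross-validation partitions the corpus", {
  co <- generate_corpus(corpus_config(n_sentences = 400, seed = 17L))
  cfg <- nlp_config(hash_buckets = 2^14, epochs = 4, seed = 17L)
  cv <- cross_validate(co, k = 5, cfg, seed = 17L)
  expect_length(cv$folds, 400)
  expect_equal(sort(unique(cv$folds)), 1:5)
  expect_true(all(abs(table(cv$folds) - 80) <= 4))
  # folds are stratified: each class roughly balanced across folds
  tab <- table(co$label, cv$folds)
  expect_true(all(abs(tab - rowMeans(tab)) <= 3))
  # pooled confusion equals the sum of fold confusions
  summed <- Reduce(`+`, lapply(cv$fold_reports, `[[`, "confusion"))
  expect_equal(as.numeric(cv$pooled$confusion), as.numeric(summed))
  # determinism of fold assignment
  cv2 <- cross_validate(co, k = 5, cfg, seed = 17L)
  expect_identical(cv$folds, cv2$folds)
})
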