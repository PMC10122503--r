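# Hashed bag-of-n-grams linear softmax classifier with abstention.
#
# Architecture: unigrams + bigrams of the normalized sentence are hashed
# into a fixed number of buckets; the bucket embeddings are averaged and fed
# through a linear layer with softmax over the four smoking classes. Both
# layers are trained jointly by SGD on the cross-entropy, single-threaded,
# with a linearly decaying learning rate. All randomness (initialization,
# shuffling, splits) comes from the config seed, so training is
# deterministic.

#' Classifier training configuration
#'
#' @param hash_buckets number of hash buckets for the n-gram features.
#' @param embedding_dim embedding dimension.
#' @param ngram_order maximum n-gram order (2 = unigrams + bigrams).
#' @param epochs SGD epochs.
#' @param learning_rate initial learning rate (decays linearly to 0).
#' @param seed integer seed.
#' @return object of class `nlp_config`.
#' @export
nlp_config <- function(hash_buckets = 2^18, embedding_dim = 32L,
                       ngram_order = 2L, epochs = 10L, learning_rate = 0.1,
                       seed = 1L) {
  stopifnot(hash_buckets >= 2, embedding_dim >= 1, ngram_order >= 1,
            epochs >= 1, learning_rate > 0)
  structure(list(hash_buckets = as.integer(hash_buckets),
                 embedding_dim = as.integer(embedding_dim),
                 ngram_order = as.integer(ngram_order),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "nlp_config")
}

# Hash each sentence into a vector of 1-based bucket ids.
.featurize <- function(texts, config) {
  texts <- normalize_text(texts)
  toks <- strsplit(texts, " ", fixed = TRUE)
  lapply(toks, function(tk) {
    tk <- tk[nzchar(tk)]
    if (!length(tk)) return(integer(0))
    grams <- tk
    if (config$ngram_order >= 2 && length(tk) >= 2)
      grams <- c(grams, paste(tk[-length(tk)], tk[-1], sep = "_"))
    hash_ngrams_cpp(grams, config$hash_buckets)
  })
}

#' Train the smoking-status sentence classifier
#'
#' @param corpus data frame with `text` and `label` columns; all four
#'   classes (current, ex, never, unknown) must be present.
#' @param config an [nlp_config()].
#' @return object of class `smoke_classifier` holding the embedding and
#'   class-weight matrices, the class order, per-epoch mean training loss,
#'   and the config.
#' @export
train_classifier <- function(corpus, config = nlp_config()) {
  stopifnot(is.data.frame(corpus), all(c("text", "label") %in% names(corpus)))
  missing_labels <- setdiff(SMOKING_CLASSES, unique(corpus$label))
  if (length(missing_labels))
    stop("label(s) absent from training data: ",
         paste(missing_labels, collapse = ", "), call. = FALSE)
  docs <- .featurize(corpus$text, config)
  y <- match(corpus$label, SMOKING_CLASSES)
  n <- length(docs)
  with_seed(config$seed, {
    E0 <- matrix(stats::runif(config$hash_buckets * config$embedding_dim,
                              -1, 1) / config$embedding_dim,
                 nrow = config$hash_buckets)
    W0 <- matrix(0, nrow = 4L, ncol = config$embedding_dim)
    ord <- vapply(seq_len(config$epochs), function(e) sample.int(n),
                  integer(n))
    fit <- sgd_train_cpp(docs, y, E0, W0, config$epochs,
                         config$learning_rate, ord)
  })
  structure(list(embeddings = fit$embeddings,
                 class_weights = fit$class_weights,
                 class_order = SMOKING_CLASSES,
                 epoch_loss = fit$epoch_loss, config = config),
            class = "smoke_classifier")
}

#' @export
print.smoke_classifier <- function(x, ...) {
  cat("Hashed n-gram softmax classifier:",
      x$config$hash_buckets, "buckets, dim", x$config$embedding_dim, "\n")
  cat("Final mean training loss:",
      format(utils::tail(x$epoch_loss, 1), digits = 4), "\n")
  invisible(x)
}

#' Predict class probabilities for sentences
#'
#' @param object a trained `smoke_classifier`.
#' @param newdata character vector of sentences or a data frame with a
#'   `text` column.
#' @param type `"prob"` for an n x 4 probability matrix, `"class"` for
#'   argmax labels (ties broken toward the earlier class in the fixed order
#'   current < ex < never < unknown).
#' @param ... unused.
#' @return probability matrix (rows sum to 1) with attribute
#'   `"no_features"`, a logical vector flagging sentences with zero
#'   in-vocabulary features (those get the uniform distribution); or a
#'   character vector of labels.
#' @export
predict.smoke_classifier <- function(object, newdata, type = c("prob",
                                                               "class"),
                                     ...) {
  type <- match.arg(type)
  txt <- if (is.data.frame(newdata)) newdata$text else newdata
  docs <- .featurize(txt, object$config)
  probs <- softmax_predict_cpp(docs, object$embeddings,
                               object$class_weights)
  colnames(probs) <- object$class_order
  attr(probs, "no_features") <- lengths(docs) == 0L
  if (type == "prob") return(probs)
  object$class_order[apply(probs, 1, which.max)]
}

#' Per-class abstention thresholds
#'
#' @param current,ex,never probability thresholds in `[0, 1]` for the three
#'   known classes.
#' @return object of class `threshold_policy`.
#' @export
threshold_policy <- function(current = 0, ex = 0, never = 0) {
  th <- c(current = unname(current), ex = unname(ex),
          never = unname(never))
  if (any(th < 0 | th > 1))
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  structure(as.list(th), class = "threshold_policy")
}

#' Apply an abstention policy to predicted distributions
#'
#' The argmax label is returned iff the argmax is a known class and its
#' probability reaches that class's threshold; in every other case
#' (including argmax = unknown) the sentence is assigned to `unknown`.
#' Raising a threshold can therefore only shrink the set of sentences
#' assigned to that class.
#'
#' @param dist an n x 4 probability matrix (columns in the fixed class
#'   order) or a single length-4 distribution.
#' @param policy a [threshold_policy()].
#' @return character vector of assigned labels.
#' @export
apply_threshold_policy <- function(dist, policy) {
  stopifnot(inherits(policy, "threshold_policy"))
  if (is.null(dim(dist))) dist <- matrix(dist, nrow = 1,
                                         dimnames = list(NULL,
                                                         SMOKING_CLASSES))
  amax <- apply(dist, 1, which.max)
  lab <- SMOKING_CLASSES[amax]
  pmaxv <- dist[cbind(seq_len(nrow(dist)), amax)]
  th <- unlist(policy)[lab]  # NA where argmax is unknown
  lab[is.na(th) | pmaxv < th] <- "unknown"
  lab
}

#' Stratified train/test split
#'
#' @param corpus labelled corpus.
#' @param test_fraction held-out fraction (default 0.1).
#' @param seed integer seed.
#' @return list with `train` and `test` data frames.
#' @export
split_corpus <- function(corpus, test_fraction = 0.1, seed = 1L) {
  with_seed(seed, {
    test_idx <- unlist(lapply(split(seq_len(nrow(corpus)), corpus$label),
                              function(ix) {
                                k <- max(1L, round(length(ix) *
                                                     test_fraction))
                                sample(ix, k)
                              }), use.names = FALSE)
    list(train = corpus[-test_idx, , drop = FALSE],
         test = corpus[test_idx, , drop = FALSE])
  })
}

#' Tune abstention thresholds for precision
#'
#' Grid search over the three per-class thresholds choosing the policy that
#' maximizes the total number of correctly retained known-class sentences
#' subject to each known class's precision on the validation corpus being
#' at least `min_precision_known`; ties are broken toward lower thresholds.
#' Because a sentence's assignment to class c depends only on that class's
#' threshold, the exhaustive grid decomposes exactly into three per-class
#' scans, which is how it is computed. A class for which the constraint is
#' infeasible at every occupied threshold gets threshold 1 (all-abstain)
#' with a warning.
#'
#' @param model trained classifier, or an n x 4 matrix of predicted class
#'   probabilities (columns in the fixed class order).
#' @param validation labelled validation corpus; when `model` is a
#'   probability matrix, a plain character vector of gold labels.
#' @param min_precision_known required precision per known class
#'   (default 0.95).
#' @param grid_step threshold grid resolution (default 0.05).
#' @return [threshold_policy()] with attribute `"feasible"` (named logical
#'   per known class).
#' @export
tune_thresholds <- function(model, validation, min_precision_known = 0.95,
                            grid_step = 0.05) {
  if (is.matrix(model)) {
    probs <- model
    gold <- as.character(validation)
  } else {
    probs <- predict(model, validation, type = "prob")
    gold <- validation$label
  }
  grid <- seq(0, 1, by = grid_step)
  amax <- apply(probs, 1, which.max)
  lab <- SMOKING_CLASSES[amax]
  pmaxv <- probs[cbind(seq_len(nrow(probs)), amax)]
  chosen <- c(current = 1, ex = 1, never = 1)
  feasible <- c(current = FALSE, ex = FALSE, never = FALSE)
  for (cls in KNOWN_CLASSES) {
    is_c <- lab == cls
    best_tp <- -1L
    best_th <- 1
    for (th in grid) {
      assigned <- is_c & pmaxv >= th
      n_assigned <- sum(assigned)
      tp <- sum(assigned & gold == cls)
      prec_ok <- n_assigned == 0L || tp / n_assigned >= min_precision_known
      if (prec_ok && (tp > best_tp)) {  # ties keep the earlier (lower) th
        best_tp <- tp
        best_th <- th
        feasible[cls] <- n_assigned > 0L
      }
    }
    chosen[cls] <- if (feasible[cls]) best_th else 1
  }
  if (!all(feasible))
    warning("precision constraint infeasible for class(es): ",
            paste(names(feasible)[!feasible], collapse = ", "),
            "; using all-abstain threshold 1", call. = FALSE)
  pol <- threshold_policy(chosen["current"], chosen["ex"], chosen["never"])
  attr(pol, "feasible") <- feasible
  pol
}
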