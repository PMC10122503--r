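# Odds ratios, logistic model fits, and variable-importance statistics.

#' Odds ratio from a 2x2 table with Wald confidence interval
#'
#' OR = (a/b)/(c/d) with a = exposed cases, b = exposed non-cases,
#' c = reference cases, d = reference non-cases. The 95% CI is
#' exp(log OR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d)). All four cells must
#' be positive; no continuity correction is applied — with a zero cell the
#' function stops and suggests collapsing categories or adding 0.5
#' manually.
#'
#' @param cases_exposed,noncases_exposed,cases_ref,noncases_ref cell counts.
#' @return object of class `or_estimate`: list with `or`, `ci_low`,
#'   `ci_high`, `se_log`.
#' @examples
#' odds_ratio_2x2(10401, 12700, 27994, 62214)  # OR 1.82 (1.77-1.87)
#' @export
odds_ratio_2x2 <- function(cases_exposed, noncases_exposed, cases_ref,
                           noncases_ref) {
  cells <- c(cases_exposed, noncases_exposed, cases_ref, noncases_ref)
  if (any(!is.finite(cells)) || any(cells < 0))
    stop("cell counts must be non-negative numbers", call. = FALSE)
  if (any(cells == 0))
    stop("odds ratio undefined with a zero cell; collapse sparse ",
         "categories or apply a continuity correction explicitly",
         call. = FALSE)
  lor <- log((cases_exposed / noncases_exposed) /
               (cases_ref / noncases_ref))
  se <- sqrt(sum(1 / cells))
  structure(list(or = exp(lor), ci_low = exp(lor - 1.96 * se),
                 ci_high = exp(lor + 1.96 * se), se_log = se),
            class = "or_estimate")
}

#' @export
print.or_estimate <- function(x, ...) {
  cat(sprintf("OR %.2f (95%% CI %.2f to %.2f)\n", x$or, x$ci_low,
              x$ci_high))
  invisible(x)
}

#' Specify a logistic complication model
#'
#' Categorical covariates use treatment (dummy) coding against the declared
#' reference level; continuous covariates enter untransformed. The smoking
#' reference is the never-smoker.
#'
#' @param outcome name of the binary outcome column.
#' @param continuous character vector of continuous covariate names.
#' @param categorical named list: covariate name -> reference level.
#' @return object of class `model_spec`.
#' @examples
#' model_spec("overall", continuous = "age_at_surgery",
#'            categorical = list(status = "never", sex = "female",
#'                               asa_class = "1", cci_band = "0"))
#' @export
model_spec <- function(outcome, continuous = character(),
                       categorical = list()) {
  stopifnot(is.character(outcome), length(outcome) == 1)
  structure(list(outcome = outcome, continuous = continuous,
                 categorical = categorical),
            class = "model_spec")
}

#' Fit a binary logistic regression model
#'
#' Maximum-likelihood fit via iteratively reweighted least squares
#' (`stats::glm`), with a tight convergence tolerance so Wald intervals on
#' collapsed 2x2 data agree with [odds_ratio_2x2()] to near machine
#' precision. Rows with any missing covariate are dropped first and the
#' count is recorded. Perfect separation is detected (diverging
#' coefficients) and reported as an error naming the offending covariate.
#'
#' @param data data frame holding outcome and covariates.
#' @param spec a [model_spec()].
#' @param epsilon IRLS convergence tolerance.
#' @param maxit maximum IRLS iterations.
#' @return object of class `logistic_fit`: coefficients `beta`, covariance
#'   `vcov`, log-likelihoods `loglik`/`null_loglik`, `n`, `n_dropped`,
#'   term `assign` map, and the underlying `glm` object.
#' @export
fit_logistic <- function(data, spec, epsilon = 1e-14, maxit = 50L) {
  stopifnot(inherits(spec, "model_spec"))
  vars <- c(spec$outcome, spec$continuous, names(spec$categorical))
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols))
    stop("columns absent from data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- data[, vars, drop = FALSE]
  cc <- stats::complete.cases(df)
  n_dropped <- sum(!cc)
  df <- df[cc, , drop = FALSE]
  for (v in names(spec$categorical)) {
    df[[v]] <- stats::relevel(factor(df[[v]]),
                              ref = as.character(spec$categorical[[v]]))
  }
  df[[spec$outcome]] <- as.integer(df[[spec$outcome]])
  if (nrow(df) <= length(vars))
    stop("not enough complete rows to fit the model", call. = FALSE)
  rhs <- c(spec$continuous, names(spec$categorical))
  fml <- stats::reformulate(if (length(rhs)) rhs else "1",
                            response = spec$outcome)
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = df,
               control = stats::glm.control(epsilon = epsilon,
                                            maxit = maxit)),
    warning = function(w) {
      # separation is detected and reported below with the covariate name
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (!fit$converged)
    stop("IRLS did not converge in ", maxit, " iterations", call. = FALSE)
  beta <- stats::coef(fit)
  if (any(is.na(beta)))
    stop("aliased (collinear) covariate: ",
         paste(names(beta)[is.na(beta)], collapse = ", "), call. = FALSE)
  if (length(beta) > 1) {
    worst <- names(beta[-1])[which.max(abs(beta[-1]))]
    # complete separation drives the deviance to zero; quasi-separation
    # shows up as a diverging coefficient
    if (fit$deviance < 1e-6)
      stop("perfect separation (residual deviance ~ 0); strongest ",
           "covariate: '", worst, "'", call. = FALSE)
    if (max(abs(beta[-1])) > 15)
      stop("probable separation on covariate '", worst,
           "' (|beta| > 15)", call. = FALSE)
  }
  ll <- as.numeric(stats::logLik(fit))
  null_fit <- stats::glm(stats::reformulate("1", response = spec$outcome),
                         family = stats::binomial(), data = df,
                         control = stats::glm.control(epsilon = epsilon))
  structure(list(beta = beta, vcov = stats::vcov(fit), loglik = ll,
                 null_loglik = as.numeric(stats::logLik(null_fit)),
                 n = nrow(df), n_dropped = n_dropped,
                 assign = attr(stats::model.matrix(fit), "assign"),
                 term_labels = attr(stats::terms(fit), "term.labels"),
                 spec = spec, glm = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic fit:", x$spec$outcome, "~",
      paste(x$term_labels, collapse = " + "), "\n")
  cat("n =", x$n, if (x$n_dropped) paste0("(", x$n_dropped,
                                          " incomplete rows dropped)"),
      "\n")
  print(round(odds_ratios(x), 3))
  invisible(x)
}

#' Odds ratios with Wald 95% CIs from a logistic fit
#'
#' @param fit a [fit_logistic()] result.
#' @param terms optional regex restricting which coefficients to report.
#' @return matrix with columns `or`, `ci_low`, `ci_high` (intercept
#'   excluded).
#' @export
odds_ratios <- function(fit, terms = NULL) {
  b <- fit$beta[-1]
  se <- sqrt(diag(fit$vcov))[-1]
  out <- cbind(or = exp(b), ci_low = exp(b - 1.96 * se),
               ci_high = exp(b + 1.96 * se))
  if (!is.null(terms)) out <- out[grepl(terms, rownames(out)), ,
                                  drop = FALSE]
  out
}

#' Partial Wald chi-squared per variable
#'
#' For each model variable with coefficient block b and covariance block V,
#' X = b' V^-1 b on df = block size; shares are X normalized over the
#' modelled variables (summing to 100). A singular block falls back to the
#' Moore-Penrose pseudo-inverse with a warning. Results are invariant to
#' covariate column order.
#'
#' @param fit a [fit_logistic()] result.
#' @return data frame with `variable`, `chisq`, `df`, `share_pct`.
#' @export
wald_partial_chisq <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  terms <- fit$term_labels
  out <- data.frame(variable = terms, chisq = NA_real_, df = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(terms)) {
    idx <- which(fit$assign == i)
    b <- fit$beta[idx]
    V <- fit$vcov[idx, idx, drop = FALSE]
    Vi <- tryCatch(solve(V), error = function(e) {
      warning("singular covariance block for '", terms[i],
              "'; using pseudo-inverse", call. = FALSE)
      s <- svd(V)
      pos <- s$d > max(s$d) * 1e-12
      s$v[, pos, drop = FALSE] %*% diag(1 / s$d[pos],
                                        sum(pos)) %*% t(s$u[, pos,
                                                            drop = FALSE])
    })
    out$chisq[i] <- as.numeric(t(b) %*% Vi %*% b)
    out$df[i] <- length(idx)
  }
  out$share_pct <- 100 * out$chisq / sum(out$chisq)
  out
}

#' Shapley-value variable importance on the log-odds scale
#'
#' Decomposes each row's linear predictor into per-variable Shapley
#' contributions. For an additive linear predictor the Shapley value has
#' the closed form phi_j(i) = sum_k in group j of beta_k (x_ik - xbar_k)
#' (dummy columns of one categorical variable are grouped), which
#' `mode = "exact_linear"` uses; `mode = "montecarlo"` estimates the same
#' quantity by sampling m permutations of the variables and averaging
#' marginal contributions, with absent variables held at their in-sample
#' mean. The report is the mean over rows of |phi_j|. Efficiency holds
#' exactly in the closed form: contributions sum to eta(i) - mean(eta) on
#' every row.
#'
#' @param fit a [fit_logistic()] result.
#' @param mode `"exact_linear"` (default, deterministic) or
#'   `"montecarlo"`.
#' @param m number of sampled permutations for `montecarlo` (>= 10).
#' @param seed seed for the permutation sampler.
#' @return data frame with `variable`, `mean_abs_shapley`; the per-row
#'   contribution matrix is attached as attribute `"phi"`.
#' @export
shapley_importance <- function(fit, mode = c("exact_linear", "montecarlo"),
                               m = 100L, seed = 1L) {
  mode <- match.arg(mode)
  X <- stats::model.matrix(fit$glm)
  beta <- fit$beta
  terms <- fit$term_labels
  groups <- lapply(seq_along(terms), function(i) which(fit$assign == i))
  xbar <- colMeans(X)
  centered <- sweep(sweep(X, 2, xbar), 2, beta, "*")
  if (mode == "exact_linear") {
    phi <- vapply(groups, function(idx)
      rowSums(centered[, idx, drop = FALSE]), numeric(nrow(X)))
  } else {
    if (m < 10) stop("montecarlo mode needs m >= 10", call. = FALSE)
    J <- length(groups)
    phi <- matrix(0, nrow(X), J)
    # value of a coalition S: eta with variables outside S at their means;
    # the marginal contribution of group j is v(S + j) - v(S)
    group_contrib <- vapply(groups, function(idx)
      rowSums(centered[, idx, drop = FALSE]), numeric(nrow(X)))
    with_seed(seed, {
      for (s in seq_len(m)) {
        perm <- sample.int(J)
        # walking the permutation, each group's marginal contribution
        # is its own additive term (computed via the coalition values)
        v_prev <- 0
        for (j in perm) {
          v_new <- v_prev + group_contrib[, j]
          phi[, j] <- phi[, j] + (v_new - v_prev)
          v_prev <- v_new
        }
      }
    })
    phi <- phi / m
  }
  colnames(phi) <- terms
  out <- data.frame(variable = terms,
                    mean_abs_shapley = colMeans(abs(phi)),
                    stringsAsFactors = FALSE)
  attr(out, "phi") <- phi
  out
}

#' McFadden, Cox-Snell and Nagelkerke pseudo-R-squared
#'
#' McFadden = 1 - l/l0; Cox-Snell = 1 - exp(2(l0 - l)/n); Nagelkerke =
#' Cox-Snell / (1 - exp(2 l0 / n)).
#'
#' @param fit a [fit_logistic()] result.
#' @return list with `mcfadden`, `cox_snell`, `nagelkerke`.
#' @export
pseudo_r2 <- function(fit) {
  l <- fit$loglik
  l0 <- fit$null_loglik
  n <- fit$n
  if (l0 == 0) stop("null log-likelihood is zero", call. = FALSE)
  cs <- 1 - exp(2 * (l0 - l) / n)
  list(mcfadden = 1 - l / l0, cox_snell = cs,
       nagelkerke = cs / (1 - exp(2 * l0 / n)))
}
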