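# Univariate associations, nested logistic outcome models, likelihood-ratio
# tests and rank-based AUC. Fitting delegates to stats::glm (binomial IRLS,
# tolerance 1e-8, at most 100 iterations); the nested-model comparison and
# the tie-corrected AUC are computed here.

#' Z-score normalisation across patients
#'
#' Centres and scales a feature to mean 0, sd 1 (denominator n - 1) over the
#' non-missing values of the analysed (sub)group; missing values stay
#' missing. Radiomics features are normalised this way before entering any
#' model, and re-normalised within each analysed subgroup.
#'
#' @param x numeric vector (may contain `NA`).
#' @param name feature name used in error messages.
#' @return numeric vector of the same length.
#' @export
zscore_normalise <- function(x, name = deparse(substitute(x))) {
  ok <- !is.na(x)
  if (sum(ok) < 2L)
    stop("cannot normalise '", name, "': fewer than 2 non-missing values",
         call. = FALSE)
  s <- stats::sd(x[ok])
  if (!is.finite(s) || s == 0)
    stop("cannot normalise '", name, "': zero variance across patients",
         call. = FALSE)
  x[ok] <- (x[ok] - mean(x[ok])) / s
  x
}

#' Fit a logistic outcome model
#'
#' Maximum-likelihood logistic regression of a binary toxicity endpoint on a
#' set of predictors, via iteratively reweighted least squares (relative
#' tolerance 1e-8, max 100 iterations). Perfect separation is flagged (fit
#' returned at the iteration-budget boundary so the log-likelihood remains
#' usable for likelihood-ratio tests).
#'
#' @param data data.frame containing `outcome` and `predictors`; no missing
#'   cells allowed (drop listwise beforehand).
#' @param outcome name of the 0/1 outcome column; both classes must occur.
#' @param predictors character vector of predictor columns (may be empty for
#'   an intercept-only model).
#' @return An object of class `logistic_fit`: `coefficients`, `se`, `p_wald`,
#'   `log_lik`, `deviance`, `converged`, `separation`, `n`, `n_events`,
#'   `outcome`, `predictors`, and the underlying `glm` object.
#' @export
fit_logistic <- function(data, outcome, predictors = character(0)) {
  cols <- c(outcome, predictors)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- data[, cols, drop = FALSE]
  if (anyNA(df))
    stop("missing cells in model data; drop incomplete patients first",
         call. = FALSE)
  y <- df[[outcome]]
  if (length(unique(y)) < 2L)
    stop("outcome '", outcome, "' has a single class", call. = FALSE)
  form <- if (length(predictors)) stats::reformulate(predictors, outcome)
          else stats::reformulate("1", outcome)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  cf <- stats::coef(fit)
  se <- p <- rep(NA_real_, length(cf))
  names(se) <- names(p) <- names(cf)
  se[rownames(sm)] <- sm[, "Std. Error"]
  p[rownames(sm)] <- sm[, "Pr(>|z|)"]
  structure(list(coefficients = cf, se = se, p_wald = p,
                 log_lik = as.numeric(stats::logLik(fit)),
                 deviance = fit$deviance,
                 converged = fit$converged, separation = separation,
                 n = nrow(df), n_events = sum(y), outcome = outcome,
                 predictors = predictors, glm = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> %s ~ %s  (n = %d, events = %d)\n",
              x$outcome,
              if (length(x$predictors)) paste(x$predictors, collapse = " + ")
              else "1",
              x$n, x$n_events))
  print(round(cbind(coef = x$coefficients, se = x$se, p = x$p_wald), 4))
  if (x$separation) cat("warning: possible perfect separation\n")
  invisible(x)
}

#' Univariate association of a feature with an endpoint
#'
#' Wald p-value of the feature's coefficient in a single-predictor logistic
#' model -- the glm-based univariate test. Features should be z-score
#' normalised first.
#'
#' @param data data.frame.
#' @param feature predictor column name.
#' @param endpoint 0/1 outcome column name.
#' @return list with `p` (Wald p-value), `coefficient`, `se`, `n`, `fit`.
#' @export
univariate_association <- function(data, feature, endpoint) {
  if (stats::var(data[[feature]]) == 0)
    stop("feature '", feature, "' is identical for all patients",
         call. = FALSE)
  fit <- fit_logistic(data, endpoint, feature)
  list(p = unname(fit$p_wald[feature]),
       coefficient = unname(fit$coefficients[feature]),
       se = unname(fit$se[feature]),
       n = fit$n, fit = fit)
}

#' Likelihood-ratio test between nested logistic models
#'
#' `statistic = 2 * (loglik_extended - loglik_reference)`, referred to the
#' chi-square upper tail with degrees of freedom equal to the difference in
#' (estimable) parameter count -- the test of whether a radiomics feature
#' adds to a reference model of mean dose and baseline toxicity.
#'
#' @param reference a `logistic_fit`; its predictor set must be a strict
#'   subset of `extended`'s, fitted to the same patients.
#' @param extended a `logistic_fit`.
#' @return An object of class `lrt_result`: `statistic`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(reference, extended) {
  stopifnot(inherits(reference, "logistic_fit"),
            inherits(extended, "logistic_fit"))
  if (reference$n != extended$n || reference$outcome != extended$outcome)
    stop("models must be fitted to the same patients and outcome",
         call. = FALSE)
  if (length(setdiff(reference$predictors, extended$predictors)) > 0L ||
      length(extended$predictors) <= length(reference$predictors))
    stop("models are not strictly nested", call. = FALSE)
  df <- sum(!is.na(extended$coefficients)) -
        sum(!is.na(reference$coefficients))
  statistic <- max(0, 2 * (extended$log_lik - reference$log_lik))
  p <- if (df > 0) stats::pchisq(statistic, df, lower.tail = FALSE) else 1
  structure(list(statistic = statistic, df = df, p = p),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("<lrt_result> chi2 = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p))
  invisible(x)
}

#' Rank-based AUC
#'
#' Mann-Whitney formulation with midranks for ties: the probability that a
#' randomly chosen case outscores a randomly chosen control, ties counting
#' one half. Invariant under strictly increasing score transforms;
#' `auc(s, y) + auc(-s, y) = 1`. Evaluated on the data supplied (apparent
#' performance; no resampling).
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 (or logical) outcome labels; both classes required.
#' @return An object of class `roc_result`: `auc`, `n_cases`, `n_controls`.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels))
    stop("scores and labels must be complete and of equal length",
         call. = FALSE)
  n1 <- as.numeric(sum(labels))   # double: rank sums overflow int at large n
  n0 <- as.numeric(sum(!labels))
  if (n1 == 0 || n0 == 0)
    stop("both outcome classes must be present", call. = FALSE)
  r <- rank(scores)          # midranks
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(list(auc = auc, n_cases = as.integer(n1),
                 n_controls = as.integer(n0)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d cases / %d controls)\n",
              x$auc, x$n_cases, x$n_controls))
  invisible(x)
}
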