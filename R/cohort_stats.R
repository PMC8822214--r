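#' Shapiro-Wilk normality test
#'
#' Thin, validating wrapper around [stats::shapiro.test()], the dispatcher
#' for every downstream choice between parametric and rank-based methods.
#' Constant input is degenerate (W undefined) and raises an error.
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @return List with `W` and `p_value`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L) stop("Shapiro-Wilk requires at least 3 observations, got ", n)
  if (n > 5000L) stop("Shapiro-Wilk supports at most 5000 observations")
  if (stats::sd(values) == 0)
    stop("Shapiro-Wilk is undefined for constant input")
  ht <- stats::shapiro.test(values)
  list(W = unname(ht$statistic), p_value = ht$p.value)
}

#' Normality-dispatched two-group comparison
#'
#' Follows the classical decision tree: if both groups pass Shapiro-Wilk
#' at `alpha_normality` and Levene's test finds homogeneous variances, a
#' pooled independent-sample t-test is used; if both are normal but the
#' variances differ, the corrected (Welch) t-test; otherwise the two-sided
#' Wilcoxon rank-sum (Mann-Whitney) test.
#'
#' @param x,y numeric vectors, each with n >= 3.
#' @param alpha_normality level for the Shapiro-Wilk and Levene pretests
#'   (default 0.05).
#' @return Object of class `group_comparison`: list with `test_used`
#'   (`"t_test"`, `"welch_t"` or `"rank_sum"`), `statistic`, `p_value`,
#'   pretest p-values (`shapiro_p_x`, `shapiro_p_y`, `levene_p`), and a
#'   `summaries` data frame (n, mean, sd, median, IQR per group).
#' @export
compare_groups <- function(x, y, alpha_normality = 0.05) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3L || length(y) < 3L)
    stop("each group needs at least 3 observations")
  sw <- function(v) tryCatch(shapiro_wilk(v)$p_value, error = function(e) 0)
  px <- sw(x); py <- sw(y)
  normal <- px > alpha_normality && py > alpha_normality
  lev_p <- NA_real_
  if (normal) {
    lev <- car::leveneTest(c(x, y),
                           factor(rep(c("x", "y"), c(length(x), length(y)))))
    lev_p <- lev[1, "Pr(>F)"]
  }
  if (normal && lev_p > alpha_normality) {
    ht <- stats::t.test(x, y, var.equal = TRUE)
    used <- "t_test"
  } else if (normal) {
    ht <- stats::t.test(x, y, var.equal = FALSE)
    used <- "welch_t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    used <- "rank_sum"
  }
  summaries <- data.frame(
    group = c("x", "y"), n = c(length(x), length(y)),
    mean = c(mean(x), mean(y)), sd = c(stats::sd(x), stats::sd(y)),
    median = c(stats::median(x), stats::median(y)),
    iqr = c(stats::IQR(x), stats::IQR(y)))
  structure(
    list(test_used = used, statistic = unname(ht$statistic),
         p_value = ht$p.value, shapiro_p_x = px, shapiro_p_y = py,
         levene_p = lev_p, summaries = summaries),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Two-group comparison: %s, statistic = %.4g, p = %.4g\n",
              x$test_used, x$statistic, x$p_value))
  print(x$summaries, row.names = FALSE)
  invisible(x)
}

#' Normality-dispatched correlation
#'
#' Pearson's r when both variables pass Shapiro-Wilk at 0.05, Spearman's
#' rho otherwise — the convention used to relate measured RBC area to the
#' CBC indices (MCV, MCH, MCHC, RDW).
#'
#' @param x,y paired numeric vectors, n >= 4, no missing pairs.
#' @param alpha_normality pretest level (default 0.05).
#' @return List with `method` (`"pearson"` or `"spearman"`), `r` and
#'   `p_value`.
#' @export
correlate <- function(x, y, alpha_normality = 0.05) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("need at least 4 complete pairs")
  sw <- function(v) tryCatch(shapiro_wilk(v)$p_value, error = function(e) 0)
  method <- if (sw(x) > alpha_normality && sw(y) > alpha_normality)
    "pearson" else "spearman"
  ht <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  list(method = method, r = unname(ht$estimate), p_value = ht$p.value)
}

#' ROC curve area by the rank (Mann-Whitney) method
#'
#' AUC is the probability that a randomly chosen case scores above a
#' randomly chosen control, computed from midranks (ties get half
#' credit). The orientation is raw — higher score taken as evidence for
#' the case class — so an inversely related marker yields AUC below 0.5
#' rather than being silently flipped. The p-value tests H0: AUC = 0.5 by
#' the tie-corrected normal approximation to the Mann-Whitney U statistic.
#'
#' @param scores numeric marker values.
#' @param labels vector with exactly two kinds of values; `case_level`
#'   names the positive class.
#' @param case_level the label value treated as "case" (default
#'   `"case"`; for logical labels, `TRUE`).
#' @param marker optional marker name carried in the result.
#' @return Object of class `roc_result`: list with `marker`, `auc`,
#'   `p_value`, `n_cases`, `n_controls`.
#' @export
roc_auc <- function(scores, labels, case_level = if (is.logical(labels)) TRUE else "case",
                    marker = "score") {
  if (length(scores) != length(labels)) stop("scores and labels lengths differ")
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  is_case <- labels == case_level
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present (", n1, " cases, ", n0, " controls)")
  r <- rank(scores)
  u <- sum(r[is_case]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n0)
  n <- n1 + n0
  tie_sizes <- table(scores)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (n * (n - 1))
  sigma <- sqrt(n1 * n0 / 12 * ((n + 1) - tie_term))
  p <- if (sigma > 0) 2 * stats::pnorm(-abs(u - n1 * n0 / 2) / sigma) else 1
  structure(
    list(marker = marker, auc = auc, p_value = p,
         n_cases = n1, n_controls = n0),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC [%s]: AUC = %.3f (p = %.4g; %d cases vs %d controls)\n",
              x$marker, x$auc, x$p_value, x$n_cases, x$n_controls))
  invisible(x)
}

#' Combined two-marker predicted probability
#'
#' Fits a binomial logistic regression of case status on RBC area and MCV
#' and returns the fitted case probabilities — the "predicted
#' probability" marker whose ROC curve summarizes the joint diagnostic
#' value of the two indices. Perfect separation is flagged (the fitted
#' probabilities still rank the subjects correctly, but the coefficients
#' are not interpretable).
#'
#' @param area,mcv paired numeric marker vectors.
#' @param labels case/control labels (see [roc_auc()]).
#' @param case_level label value treated as case.
#' @return List with `scores` (fitted probabilities), `model` (the glm
#'   fit) and `separation` (logical flag).
#' @export
combined_predictor <- function(area, mcv, labels,
                               case_level = if (is.logical(labels)) TRUE else "case") {
  if (length(area) != length(mcv) || length(area) != length(labels))
    stop("area, mcv and labels must have equal length")
  y <- as.integer(labels == case_level)
  if (length(unique(y)) < 2L)
    stop("both classes must be present to fit the combined predictor")
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ area + mcv, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  # perfect separation can also converge silently with deviance ~ 0
  if (fit$deviance < 1e-6) separation <- TRUE
  list(scores = unname(stats::fitted(fit)), model = fit,
       separation = separation)
}
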