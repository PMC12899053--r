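#' Wilcoxon signed-rank test on paired samples
#'
#' Two-sided signed-rank test of the paired differences `x - y`. Zero
#' differences are discarded (Wilcoxon's original method) and tied absolute
#' differences receive midranks. The exact null distribution is used when at
#' most 25 nonzero differences remain and there are no ties; otherwise the
#' normal approximation with continuity and tie corrections is applied.
#'
#' @param x,y paired numeric vectors of equal length.
#' @return A list of class `wilcoxon_result`: `statistic` (positive-rank
#'   sum), `p_value`, `n_pairs` (nonzero differences used), `method`
#'   (`"exact"`, `"approx"` or `"degenerate"`) and `degenerate`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  d <- x - y
  d <- d[d != 0]
  if (!length(d)) {
    return(structure(list(statistic = 0, p_value = 1, n_pairs = 0L,
                          method = "degenerate", degenerate = TRUE),
                     class = "wilcoxon_result"))
  }
  n <- length(d)
  ties <- any(duplicated(abs(d)))
  exact <- n <= 25 && !ties
  res <- suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = TRUE))
  structure(list(statistic = unname(res$statistic),
                 p_value = res$p.value, n_pairs = n,
                 method = if (exact) "exact" else "approx",
                 degenerate = FALSE),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: V = %g, n = %d, p = %.4g (%s)\n",
              x$statistic, x$n_pairs, x$p_value, x$method))
  invisible(x)
}

#' Compare postures by paired Wilcoxon tests
#'
#' For every muscle x Minkowski order x normalization cell, tests whether the
#' spectral distances differ between the SP and NT postures. At the intra
#' level the pairing unit is the participant and each unit's value is its
#' mean repetition distance (`aggregation = "mean"`) or every repetition
#' distance paired by participant and repetition (`"pooled"`). At the inter
#' level the pairing unit is the participant pair. Units missing one posture
#' are dropped with a warning.
#'
#' @param tbl a tidy distance table: columns `muscle`, `posture`, `norm`,
#'   `order`, `distance`, plus `participant` and `repetition` (intra level)
#'   or `pair` (inter level).
#' @param level `"intra"` or `"inter"`.
#' @param aggregation intra-level pairing value, `"mean"` or `"pooled"`.
#' @return Data frame with one row per cell: `muscle`, `order`, `norm`,
#'   `level`, `n_pairs`, `statistic`, `p_value`, `method`.
#' @export
compare_postures <- function(tbl, level = c("intra", "inter"),
                             aggregation = c("mean", "pooled")) {
  level <- match.arg(level)
  aggregation <- match.arg(aggregation)
  if (level == "intra") {
    unit_cols <- if (aggregation == "mean") "participant"
                 else c("participant", "repetition")
    if (aggregation == "mean") {
      tbl <- stats::aggregate(
        distance ~ participant + muscle + posture + norm + order,
        data = tbl, FUN = mean)
    }
  } else unit_cols <- "pair"
  tbl$unit <- do.call(paste, c(tbl[unit_cols], sep = "|"))

  cells <- unique(tbl[c("muscle", "order", "norm")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- tbl[tbl$muscle == cells$muscle[i] & tbl$order == cells$order[i] &
                 tbl$norm == cells$norm[i], ]
    sp <- sub[sub$posture == "SP", ]
    nt <- sub[sub$posture == "NT", ]
    units <- intersect(sp$unit, nt$unit)
    if (length(units) < max(nrow(sp), nrow(nt)))
      warning("dropping units missing one posture in ",
              cells$muscle[i], "/", cells$order[i], "/", cells$norm[i])
    x <- sp$distance[match(units, sp$unit)]
    y <- nt$distance[match(units, nt$unit)]
    w <- wilcoxon_signed_rank(x, y)
    data.frame(muscle = cells$muscle[i], order = cells$order[i],
               norm = cells$norm[i], level = level,
               n_pairs = w$n_pairs, statistic = w$statistic,
               p_value = w$p_value, method = w$method)
  })
  do.call(rbind, out)
}

#' Fit a distribution family by maximum likelihood
#'
#' Closed-form maximum-likelihood estimates: normal `(mean, sd_MLE)`; Laplace
#' `(median, mean absolute deviation from the median)`; Maxwell-Boltzmann
#' scale `a = sqrt(mean(x^2) / 3)` (requires a nonnegative sample).
#'
#' @param x numeric sample.
#' @param family `"normal"`, `"laplace"` or `"maxwell"`.
#' @return Object of class `emg_fit` with `family`, `params`, `n`, and empty
#'   goodness-of-fit slots to be completed by [chi_square_gof()].
#' @export
fit_distribution <- function(x, family = c("normal", "laplace", "maxwell")) {
  family <- match.arg(family)
  params <- switch(family,
    normal = c(mean = mean(x), sd = sqrt(mean((x - mean(x))^2))),
    laplace = {
      mu <- stats::median(x)
      c(mu = mu, b = mean(abs(x - mu)))
    },
    maxwell = {
      if (any(x < 0)) stop("maxwell fit requires nonnegative values")
      c(a = sqrt(mean(x^2) / 3))
    })
  structure(list(family = family, params = params, n = length(x),
                 chi2 = NA_real_, df = NA_integer_, p_value = NA_real_,
                 n_bins = NA_integer_),
            class = "emg_fit")
}

# Quantile function of a fitted emg_fit.
fit_quantile <- function(fit, p) {
  switch(fit$family,
         normal = stats::qnorm(p, fit$params[["mean"]], fit$params[["sd"]]),
         laplace = qlaplace(p, fit$params[["mu"]], fit$params[["b"]]),
         maxwell = qmaxwell(p, fit$params[["a"]]))
}

#' Chi-square goodness-of-fit test with equal-probability bins
#'
#' Bins the sample into `n_bins` equal-probability classes under the fitted
#' model, with `n_bins = min(max(5, floor(n/10)), floor(n/5))` so every class
#' has an expected count of at least five. The statistic is
#' `sum((obs - exp)^2 / exp)` on `n_bins - 1 - n_params` degrees of freedom
#' (penalized for the estimated parameters), with the p-value from the upper
#' tail. Fits with `p >= 0.05` are conventionally considered statistically
#' consistent with the sample.
#'
#' @param x the numeric sample the parameters were estimated from.
#' @param fit an [fit_distribution()] result.
#' @return The completed `emg_fit` (fields `chi2`, `df`, `p_value`, `n_bins`).
#' @export
chi_square_gof <- function(x, fit) {
  n <- length(x)
  n_params <- length(fit$params)
  n_bins <- min(max(5, floor(n / 10)), floor(n / 5))
  if (n_bins < n_params + 2)
    stop("sample too small for a chi-square test with >= 5 expected per bin")
  inner <- fit_quantile(fit, seq_len(n_bins - 1) / n_bins)
  obs <- tabulate(findInterval(x, inner) + 1L, nbins = n_bins)
  expd <- n / n_bins
  fit$chi2 <- sum((obs - expd)^2 / expd)
  fit$df <- as.integer(n_bins - 1 - n_params)
  fit$p_value <- stats::pchisq(fit$chi2, fit$df, lower.tail = FALSE)
  fit$n_bins <- as.integer(n_bins)
  fit
}

#' @export
print.emg_fit <- function(x, ...) {
  cat(sprintf("<emg_fit> %s(%s), n = %d",
              x$family,
              paste(sprintf("%s = %.4g", names(x$params), x$params),
                    collapse = ", "),
              x$n))
  if (!is.na(x$chi2))
    cat(sprintf("; chi2 = %.3f, df = %d, p = %.4g", x$chi2, x$df, x$p_value))
  cat("\n")
  invisible(x)
}
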