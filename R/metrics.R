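# ---------------------------------------------------------------------------
# Benchmark statistics: Kendall tau-b, MUE/RMSE, percentile bootstrap CIs,
# Mann-Whitney U with Holm correction.
# ---------------------------------------------------------------------------

#' Tie-corrected Kendall rank correlation (tau-b)
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return tau-b in \[-1, 1\]; `NA` (with a warning) when either input is
#'   entirely tied, where tau is undefined.
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least two observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    warning("all-tied input: Kendall tau undefined")
    return(NA_real_)
  }
  unname(cor(x, y, method = "kendall"))
}

#' Mean unsigned error and root-mean-square error
#'
#' @param pred,exp numeric vectors of equal length (kcal/mol).
#' @return list `mue`, `rmse`; RMSE >= MUE always.
#' @export
error_metrics <- function(pred, exp) {
  if (length(pred) != length(exp)) stop("pred and exp must have equal length")
  if (!length(pred)) stop("empty input")
  r <- pred - exp
  list(mue = mean(abs(r)), rmse = sqrt(mean(r^2)))
}

#' Percentile bootstrap confidence interval for a paired statistic
#'
#' Resamples (pred, exp) pairs with replacement `n_resamples` times
#' (default 1000) and reports the percentile interval of the statistic.
#'
#' @param statistic function of (pred, exp) returning one number.
#' @param pred,exp paired data vectors, length >= 2.
#' @param n_resamples bootstrap resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed (resampling is reproducible for a fixed seed
#'   and leaves the caller's RNG untouched).
#' @return object of class `metric_result`: `value` (on the observed
#'   sample), `ci_low`, `ci_high`, `n_resamples`, `seed`. Resamples where
#'   the statistic is degenerate (NA/NaN) are dropped; if more than half
#'   are degenerate a warning is issued and the interval uses the valid
#'   ones.
#' @export
bootstrap_ci <- function(statistic, pred, exp, n_resamples = 1000,
                         level = 0.95, seed = 1) {
  if (length(pred) != length(exp)) stop("pred and exp must have equal length")
  n <- length(pred)
  if (n < 2L) stop("need at least two pairs")
  value <- statistic(pred, exp)
  stats <- with_preserved_rng({
    set.seed(as.integer(seed))
    vapply(seq_len(n_resamples), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      as.numeric(suppressWarnings(statistic(pred[idx], exp[idx])))
    }, numeric(1))
  })
  bad <- !is.finite(stats)
  if (mean(bad) > 0.5)
    warning("statistic degenerate on most resamples; CI from valid resamples only")
  stats <- stats[!bad]
  alpha <- (1 - level) / 2
  ci <- quantile(stats, c(alpha, 1 - alpha), names = FALSE, type = 7)
  structure(list(value = value, ci_low = ci[1], ci_high = ci[2],
                 n_resamples = n_resamples, level = level, seed = seed),
            class = "metric_result")
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("<metric_result> %.4g [%.4g, %.4g] (%g%% CI, %d resamples, seed %d)\n",
              x$value, x$ci_low, x$ci_high, 100 * x$level, x$n_resamples,
              x$seed))
  invisible(x)
}

#' Directional Mann-Whitney U tests with Holm correction
#'
#' For each named comparison (a pair of samples, typically absolute errors
#' of two methods) both one-sided Mann-Whitney U tests are run (exact for
#' small samples without ties, normal approximation with tie correction
#' otherwise, via [stats::wilcox.test()]). The better-supported direction
#' is reported per comparison and its one-sided p enters the Holm
#' step-down adjustment across all comparisons.
#'
#' @param comparisons named list; each element a list of two numeric
#'   samples `list(a, b)`.
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame: `comparison`, `U`, `p_raw`, `p_adjusted`,
#'   `significant`, `direction` (`"a_greater"` / `"b_greater"`: which
#'   sample is stochastically larger). Comparisons with fewer than 2
#'   observations on either side are skipped with a warning.
#' @export
mannwhitney_holm <- function(comparisons, alpha = 0.05) {
  stopifnot(length(comparisons) >= 1)
  if (is.null(names(comparisons)))
    names(comparisons) <- paste0("cmp", seq_along(comparisons))
  rows <- lapply(names(comparisons), function(nm) {
    ab <- comparisons[[nm]]
    a <- as.numeric(ab[[1]]); b <- as.numeric(ab[[2]])
    if (length(a) < 2L || length(b) < 2L) {
      warning(sprintf("comparison '%s' skipped: fewer than 2 observations", nm))
      return(NULL)
    }
    gt <- suppressWarnings(wilcox.test(a, b, alternative = "greater"))
    lt <- suppressWarnings(wilcox.test(a, b, alternative = "less"))
    if (gt$p.value <= lt$p.value)
      data.frame(comparison = nm, U = unname(gt$statistic),
                 p_raw = gt$p.value, direction = "a_greater")
    else
      data.frame(comparison = nm, U = unname(lt$statistic),
                 p_raw = lt$p.value, direction = "b_greater")
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(rows) || !nrow(rows)) stop("no testable comparisons")
  rows$p_adjusted <- p.adjust(rows$p_raw, method = "holm")
  rows$significant <- rows$p_adjusted < alpha
  rows[, c("comparison", "U", "p_raw", "p_adjusted", "significant", "direction")]
}

#' Benchmark summary for one target
#'
#' Computes Kendall tau-b and MUE with percentile-bootstrap CIs for a set
#' of predicted vs experimental values, mirroring a benchmark-table row.
#'
#' @param pred,exp paired numeric vectors (kcal/mol).
#' @param n_resamples bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return data.frame with one row per metric (`tau`, `mue`): `value`,
#'   `ci_low`, `ci_high`, `n`.
#' @export
benchmark_metrics <- function(pred, exp, n_resamples = 1000, seed = 1) {
  tau <- bootstrap_ci(function(p, e) kendall_tau(p, e), pred, exp,
                      n_resamples, seed = seed)
  mue <- bootstrap_ci(function(p, e) error_metrics(p, e)$mue, pred, exp,
                      n_resamples, seed = seed + 1L)
  data.frame(metric = c("tau", "mue"),
             value = c(tau$value, mue$value),
             ci_low = c(tau$ci_low, mue$ci_low),
             ci_high = c(tau$ci_high, mue$ci_high),
             n = length(pred))
}
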