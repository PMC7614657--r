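# Cell gating, normalization, robust fits, bootstrap statistics.

#' Derive a percentile gate from a reference population
#'
#' The threshold is the stated percentile of a reference population of known
#' phase (cells identified as G1 or S from live imaging); by convention the
#' 99th (sometimes 95th) percentile.
#'
#' @param reference_values marker values of the reference cells (>= 50).
#' @param percentile percentile in (0, 100).
#' @param direction `"above_is_positive"` or `"below_is_positive"`.
#' @return list of class `"gate_threshold"`: `value`, `percentile`,
#'   `direction`, `n_reference`.
#' @export
derive_gate <- function(reference_values, percentile = 99,
                        direction = c("above_is_positive",
                                      "below_is_positive")) {
  direction <- match.arg(direction)
  if (length(reference_values) < 50)
    stopf("need >= 50 reference cells of known phase")
  structure(list(value = as.numeric(stats::quantile(reference_values,
                                                    percentile / 100)),
                 percentile = percentile, direction = direction,
                 n_reference = length(reference_values)),
            class = "gate_threshold")
}

#' Apply a gate to marker values
#'
#' @param values marker values.
#' @param gate a `"gate_threshold"`.
#' @return logical vector: positive per the gate's direction.
#' @export
apply_gate <- function(values, gate) {
  if (gate$direction == "above_is_positive") values > gate$value
  else values < gate$value
}

#' Robust zero-intercept line by bisquare IRLS
#'
#' Iteratively reweighted least squares through the origin with Tukey
#' bisquare weights `w = (1 - (r / (t s))^2)^2` for `|r| < t s` (else 0),
#' where `s` is a MAD-based robust residual scale and `t` the tuning
#' constant. Converges when the slope changes by < 1e-8 or after 100
#' iterations.
#'
#' @param x,y data (>= 3 points; not all `x` zero).
#' @param tuning bisquare tuning constant.
#' @return fitted slope.
#' @export
robust_line_through_origin <- function(x, y, tuning = 2) {
  if (length(x) < 3 || length(x) != length(y)) stopf("need >= 3 (x, y) pairs")
  if (all(x == 0)) stopf("all x are zero; slope undefined")
  slope <- sum(x * y) / sum(x * x)
  for (it in 1:100) {
    r <- y - slope * x
    s <- stats::median(abs(r - stats::median(r))) / 0.6745
    if (s < 1e-12) break
    u <- r / (tuning * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (all(w * x^2 == 0)) stopf("all bisquare weights zero")
    new_slope <- sum(w * x * y) / sum(w * x^2)
    if (abs(new_slope - slope) < 1e-8) { slope <- new_slope; break }
    slope <- new_slope
  }
  slope
}

#' Percentile bootstrap confidence interval
#'
#' @param values data vector (>= 2 values).
#' @param statistic function of a numeric vector.
#' @param n_boot number of with-replacement resamples (>= 1000).
#' @param level confidence level.
#' @param seed integer seed (resampling is deterministic given it).
#' @return numeric `c(lo, hi)`.
#' @export
bootstrap_ci <- function(values, statistic = mean, n_boot = 1000L,
                         level = 0.95, seed = 1L) {
  if (length(values) < 2) stopf("need >= 2 values")
  if (n_boot < 1000) stopf("n_boot must be >= 1000")
  stats_boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i)
      statistic(sample(values, length(values), replace = TRUE)), 0)
  })
  alpha <- (1 - level) / 2
  out <- as.numeric(stats::quantile(stats_boot, c(alpha, 1 - alpha)))
  names(out) <- c("lo", "hi")
  out
}

#' Time-binned summaries with bootstrap confidence intervals
#'
#' Bins values by time since an event and reports a per-bin statistic with a
#' percentile-bootstrap confidence interval; bins with fewer than
#' `min_per_bin` cells are omitted.
#'
#' @param times time since event (minutes).
#' @param values measurements (same length).
#' @param bin_width_min bin width (minutes).
#' @param statistic `"median"`, `"mean"`, or `"fraction_below_gate"`.
#' @param gate threshold used by `"fraction_below_gate"`.
#' @param min_per_bin minimum cells per reported bin.
#' @param n_boot,level,seed bootstrap settings (see [bootstrap_ci()]).
#' @return data frame: `bin_mid_min`, `n`, `estimate`, `lo`, `hi`.
#' @export
binned_summary <- function(times, values, bin_width_min,
                           statistic = c("median", "mean",
                                         "fraction_below_gate"),
                           gate = NULL, min_per_bin = 36L,
                           n_boot = 1000L, level = 0.95, seed = 1L) {
  statistic <- match.arg(statistic)
  stat_fn <- switch(statistic,
    median = stats::median,
    mean = mean,
    fraction_below_gate = function(v) mean(v < gate))
  if (statistic == "fraction_below_gate" && is.null(gate))
    stopf("fraction_below_gate requires a gate")
  keep <- is.finite(times) & is.finite(values)
  times <- times[keep]; values <- values[keep]
  if (length(times) == 0)
    return(data.frame(bin_mid_min = numeric(), n = integer(),
                      estimate = numeric(), lo = numeric(), hi = numeric()))
  bin <- floor(times / bin_width_min)
  out <- lapply(sort(unique(bin)), function(b) {
    v <- values[bin == b]
    if (length(v) < min_per_bin) return(NULL)
    ci <- bootstrap_ci(v, stat_fn, n_boot = n_boot, level = level,
                       seed = seed + b)
    data.frame(bin_mid_min = (b + 0.5) * bin_width_min, n = length(v),
               estimate = stat_fn(v), lo = ci[["lo"]], hi = ci[["hi"]])
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(bin_mid_min = numeric(), n = integer(),
                      estimate = numeric(), lo = numeric(), hi = numeric())
  out
}

#' Baseline-subtract and normalize stain values
#'
#' `(values - g1_baseline) / reference`: a baseline computed from G1 levels
#' of the stain is subtracted for a true zero, then values are divided by a
#' reference-group statistic.
#'
#' @param values stain values (a.u.).
#' @param g1_baseline baseline from G1 cells (a.u.).
#' @param reference reference-group statistic (> 0).
#' @return normalized values.
#' @export
normalize_values <- function(values, g1_baseline, reference) {
  if (reference <= 0) stopf("reference must be > 0")
  (values - g1_baseline) / reference
}

#' Trim outlier values
#'
#' Drops the top `upper_frac` fraction (or both tails when `symmetric`).
#'
#' @param values data vector.
#' @param upper_frac fraction to trim from the top, in (0, 0.5).
#' @param symmetric also trim the same fraction from the bottom.
#' @return filtered values.
#' @export
trim_outliers <- function(values, upper_frac = 0.01, symmetric = FALSE) {
  if (!(upper_frac > 0 && upper_frac < 0.5))
    stopf("upper_frac must lie in (0, 0.5)")
  hi <- stats::quantile(values, 1 - upper_frac)
  keep <- values <= hi
  if (symmetric) keep <- keep & values >= stats::quantile(values, upper_frac)
  values[keep]
}

#' Randomly subsample groups to a common size
#'
#' Downsamples every group, without replacement, to the smallest group's
#' size.
#'
#' @param groups named list of vectors (each nonempty).
#' @param seed integer seed.
#' @return named list of equally sized vectors.
#' @export
subsample_equal <- function(groups, seed = 1L) {
  if (any(vapply(groups, length, 0L) == 0)) stopf("all groups must be nonempty")
  n_min <- min(vapply(groups, length, 0L))
  with_seed(seed, lapply(groups, function(g)
    g[sample(length(g), n_min, replace = FALSE)]))
}

#' t tests used for condition comparisons
#'
#' Two-sample (Welch), paired, or one-sample t statistics with two-sided p
#' values; thin wrapper around [stats::t.test()] with the pipeline's
#' conventions.
#'
#' @param a,b sample vectors (`b = NULL` for one-sample).
#' @param mode `"two_sample"`, `"paired"`, or `"one_sample"`.
#' @param mu0 null value for the one-sample mode.
#' @return list `t`, `p`, `df`.
#' @export
t_test <- function(a, b = NULL, mode = c("two_sample", "paired", "one_sample"),
                   mu0 = 0) {
  mode <- match.arg(mode)
  degenerate <- switch(mode,
    two_sample = stats::sd(a) == 0 && stats::sd(b) == 0,
    paired = stats::sd(a - b) == 0,
    one_sample = stats::sd(a) == 0)
  if (degenerate) stopf("zero variance: t statistic undefined")
  res <- switch(mode,
    two_sample = stats::t.test(a, b),
    paired = stats::t.test(a, b, paired = TRUE),
    one_sample = stats::t.test(a, mu = mu0))
  list(t = unname(res$statistic), p = res$p.value,
       df = unname(res$parameter))
}
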