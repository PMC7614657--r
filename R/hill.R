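# Single-cell EdU dose-response: Hill-equation fitting by Levenberg-Marquardt
# with the stated initialization, plus derived quantities and stratified fits.

#' Fit a Hill dose-response to single-cell EdU vs inhibitor data
#'
#' Minimizes squared residuals of
#' \deqn{EdU(x) = EdU_{max} - \frac{EdU_{max}-EdU_{min}}{1 + (IC_{50}/x)^n}}
#' over the free parameters using the Levenberg-Marquardt algorithm.
#' `EdU_max` is fixed from cells without the inhibitor (supplied directly or
#' as the mean EdU of rows with `ndcdt1 == 0`). Initialization: `EdU_min` at
#' the 5th percentile of the EdU signal, `IC50` at the median inhibitor
#' level, `n` at 1. On non-convergence a small restart grid around the
#' initial values is tried before failing.
#'
#' @param ndcdt1 per-cell inhibitor (ND-CDT1) levels (a.u.); rows with value
#'   0 are treated as the negative population and excluded from the fit.
#' @param edu per-cell EdU incorporation, background-subtracted (a.u.).
#' @param edu_max fixed EdU ceiling; default: mean EdU of `ndcdt1 == 0` rows.
#' @param fix_edu_min fix `EdU_min` at this value instead of fitting it.
#' @param min_cells minimum number of expressing cells required.
#' @return object of class `"hill_fit"`: list with `params` (named vector
#'   `edu_max`, `edu_min`, `ic50`, `n_hill`), `fitted_flags`, `vcov` (of the
#'   fitted parameters), `n_cells`, `deviance`, `data`.
#' @examples
#' d <- sample_dose_response(hill_params(22, 1, 10.2, 4.2), 500, 0,
#'                           c(0.5, 40), seed = 1)
#' fit <- fit_hill(d$ndcdt1, d$edu, edu_max = 22)
#' coef(fit)
#' @export
fit_hill <- function(ndcdt1, edu, edu_max = NULL, fix_edu_min = NULL,
                     min_cells = 100L) {
  stopifnot(length(ndcdt1) == length(edu))
  neg <- ndcdt1 == 0
  if (is.null(edu_max)) {
    if (!any(neg)) stopf("edu_max not given and no ndcdt1 == 0 cells present")
    edu_max <- mean(edu[neg])
  }
  x <- ndcdt1[!neg]; y <- edu[!neg]
  ok <- is.finite(x) & is.finite(y) & x > 0
  x <- x[ok]; y <- y[ok]
  if (length(x) < min_cells)
    stopf("need >= %d cells with positive inhibitor levels", min_cells)
  if (diff(range(log10(x))) < 1)
    warning("inhibitor levels span less than one decade; fit may be unstable")
  if (stats::sd(y) < 1e-12 || min(y) > 0.95 * edu_max)
    stopf("degenerate data: no inhibition observed, edu_min unidentifiable")

  init <- c(edu_min = as.numeric(stats::quantile(y, 0.05)),
            ic50 = stats::median(x), n_hill = 1)
  model <- function(par, x) {
    em <- if (is.null(fix_edu_min)) par[["edu_min"]] else fix_edu_min
    edu_max - (edu_max - em) / (1 + (par[["ic50"]] / x)^par[["n_hill"]])
  }
  run_fit <- function(start) {
    free <- if (is.null(fix_edu_min)) c("edu_min", "ic50", "n_hill")
            else c("ic50", "n_hill")
    lower <- c(edu_min = -Inf, ic50 = 1e-9, n_hill = 1e-3)[free]
    minpack.lm::nls.lm(
      par = start[free],
      fn = function(par) y - model(par, x),
      lower = lower,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                           ptol = 1e-12)
    )
  }
  fit <- run_fit(init)
  converged <- fit$info %in% 1:4
  if (!converged) {
    for (f_ic in c(0.3, 1, 3)) for (f_n in c(0.5, 1, 2)) {
      start <- init
      start[["ic50"]] <- init[["ic50"]] * f_ic
      start[["n_hill"]] <- init[["n_hill"]] * f_n
      alt <- run_fit(start)
      if (alt$info %in% 1:4 && alt$deviance < fit$deviance) {
        fit <- alt; converged <- TRUE
      }
    }
  }
  if (!converged)
    stopf("Hill fit did not converge (nls.lm info %d: %s)",
          fit$info, fit$message)
  par <- fit$par
  params <- c(edu_max = edu_max,
              edu_min = if (is.null(fix_edu_min)) par[["edu_min"]]
                        else fix_edu_min,
              ic50 = par[["ic50"]], n_hill = par[["n_hill"]])
  vc <- tryCatch({
    covm <- solve(fit$hessian) * 2 * fit$deviance / (length(x) - length(par))
    dimnames(covm) <- list(names(par), names(par))
    covm
  }, error = function(e) NULL)
  structure(list(params = params,
                 fitted_flags = c(edu_max = FALSE,
                                  edu_min = is.null(fix_edu_min),
                                  ic50 = TRUE, n_hill = TRUE),
                 vcov = vc, n_cells = length(x),
                 deviance = fit$deviance,
                 data = data.frame(ndcdt1 = x, edu = y)),
            class = "hill_fit")
}

#' @export
coef.hill_fit <- function(object, ...) object$params

#' @export
vcov.hill_fit <- function(object, ...) object$vcov

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$ndcdt1
       else if (is.data.frame(newdata)) newdata$ndcdt1 else newdata
  hill_response(x, object)
}

#' @export
residuals.hill_fit <- function(object, ...) {
  object$data$edu - predict(object)
}

#' @export
print.hill_fit <- function(x, ...) {
  p <- x$params
  cat("Hill dose-response fit (Levenberg-Marquardt)\n")
  cat(sprintf("  EdU_max %.4g%s  EdU_min %.4g%s  IC50 %.4g  n %.4g\n",
              p[["edu_max"]], if (x$fitted_flags[["edu_max"]]) "" else " (fixed)",
              p[["edu_min"]], if (x$fitted_flags[["edu_min"]]) "" else " (fixed)",
              p[["ic50"]], p[["n_hill"]]))
  cat(sprintf("  %d cells, residual SS %.4g, max inhibition %.3g-fold\n",
              x$n_cells, x$deviance, fold_inhibition(x)))
  invisible(x)
}

#' @export
summary.hill_fit <- function(object, ...) {
  se <- if (!is.null(object$vcov)) sqrt(diag(object$vcov)) else NULL
  structure(list(fit = object, se = se), class = "summary.hill_fit")
}

#' @export
print.summary.hill_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$se)) {
    cat("  standard errors (fitted parameters):\n")
    print(round(x$se, 5))
  }
  invisible(x)
}

#' @export
plot.hill_fit <- function(x, n_points = 200, ...) {
  d <- x$data
  graphics::plot(d$ndcdt1, d$edu, log = "x", pch = 16, cex = 0.3,
                 col = grDevices::adjustcolor("grey30", 0.4),
                 xlab = "ND-CDT1 (a.u.)", ylab = "EdU (a.u.)", ...)
  xs <- exp(seq(log(min(d$ndcdt1)), log(max(d$ndcdt1)), length.out = n_points))
  graphics::lines(xs, hill_response(xs, x), col = "firebrick", lwd = 2)
  invisible(x)
}

#' Maximum fold-inhibition of a Hill fit
#'
#' The ratio of the fitted curve's maximum to its minimum over the dose
#' range, `EdU_max / EdU_min`.
#'
#' @param fit a `"hill_fit"` object (or [hill_params()] set).
#' @return fold inhibition (unitless).
#' @export
fold_inhibition <- function(fit) {
  p <- as_hill_params(fit)
  if (p$edu_min <= 0)
    stopf("fold inhibition undefined for edu_min <= 0")
  p$edu_max / p$edu_min
}

#' Dose-response fits stratified by a second marker
#'
#' Bins records into equal-count strata of `strat_values` (e.g. geminin
#' expression), fits a Hill dose-response in each stratum, and regresses the
#' per-stratum IC50 on the stratum median by ordinary least squares.
#'
#' @param ndcdt1,edu per-cell data as in [fit_hill()].
#' @param strat_values per-cell stratification marker.
#' @param n_bins number of equal-count strata.
#' @param edu_max fixed EdU ceiling passed to each fit.
#' @param min_cells_per_bin strata below this size are skipped with a
#'   warning.
#' @param ... further arguments to [fit_hill()].
#' @return list: `fits` (per-stratum `"hill_fit"`), `table` (stratum median,
#'   `ic50`, `n_cells`), `trend` (`slope`, `intercept` of IC50 vs stratum
#'   median).
#' @export
stratified_dose_response <- function(ndcdt1, edu, strat_values, n_bins,
                                     edu_max, min_cells_per_bin = 200L, ...) {
  if (n_bins < 2) stopf("need >= 2 strata for a trend")
  qs <- stats::quantile(strat_values, probs = seq(0, 1, length.out = n_bins + 1))
  bins <- cut(strat_values, breaks = unique(qs), include.lowest = TRUE)
  fits <- list(); rows <- list()
  for (b in levels(bins)) {
    sel <- which(bins == b)
    if (length(sel) < min_cells_per_bin) {
      warning(sprintf("stratum %s has %d cells (< %d); skipped",
                      b, length(sel), min_cells_per_bin))
      next
    }
    f <- fit_hill(ndcdt1[sel], edu[sel], edu_max = edu_max, ...)
    fits[[b]] <- f
    rows[[b]] <- data.frame(stratum = b,
                            strat_median = stats::median(strat_values[sel]),
                            ic50 = coef(f)[["ic50"]],
                            n_hill = coef(f)[["n_hill"]],
                            n_cells = f$n_cells)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) < 2)
    stopf("fewer than 2 populated strata; trend undefined")
  lm_fit <- stats::lm(ic50 ~ strat_median, data = tab)
  list(fits = fits, table = tab,
       trend = c(slope = unname(stats::coef(lm_fit)[2]),
                 intercept = unname(stats::coef(lm_fit)[1])))
}
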