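# Quantification math for the wet-lab side of regulon characterization:
# four-parameter logistic titration fits with fixed asymptotes (EMSA EC50s
# for protein and effector titrations), empirical growth-curve AUC, and the
# affinity-expression correlation.

#' Construct a titration curve
#'
#' @param x Strictly increasing, strictly positive concentrations (nM for
#'   protein titrations, mM for effector titrations).
#' @param y Response fraction in `[0, 1]` (fraction of probe shifted, or
#'   shift ratio with/without effector).
#' @return Object of class `titration_curve`.
#' @export
titration_curve <- function(x, y) {
  if (length(x) < 4L) stop("need at least 4 points", call. = FALSE)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (any(x <= 0)) stop("concentrations must be strictly positive",
                        call. = FALSE)
  if (any(diff(x) <= 0)) stop("x must be strictly increasing", call. = FALSE)
  if (any(y < 0 | y > 1)) stop("responses must lie in [0, 1]", call. = FALSE)
  structure(list(x = as.numeric(x), y = as.numeric(y)),
            class = "titration_curve")
}

#' Fit a four-parameter logistic with fixed asymptotes
#'
#' Least-squares fit of \deqn{y = c + \frac{d - c}{1 + (x/e)^b}} with the
#' lower limit fixed at `c = 0` and the upper limit at `d = 1`. `e` is the
#' EC50 (same units as `x`); the sign of the slope `b` encodes orientation
#' (negative for responses increasing with concentration, as in protein
#' titrations; positive for decreasing effector-disruption curves).
#' Optimization is over `(b, log e)` with `e` initialized at the `x` whose
#' response is nearest 0.5 and `|b| = 1`, falling back to a restart grid of
#' slopes on non-convergence. The 95% CI on `e` comes from the linearized
#' covariance of `log e`.
#'
#' @param curve A [titration_curve()] (or list with `x`, `y`).
#' @return Object of class `fourpl`: coefficients `b`, `e` (plus fixed
#'   `c = 0`, `d = 1`), `sse`, `ci` (95% on `e`), the data, and the
#'   underlying `nls` fit.
#' @export
fit_4pl <- function(curve) {
  if (!inherits(curve, "titration_curve")) curve <- titration_curve(curve$x,
                                                                    curve$y)
  x <- curve$x; y <- curve$y
  if (all(y == 0) || all(y == 1))
    stop("degenerate data: all responses at one asymptote", call. = FALSE)
  e0 <- x[which.min(abs(y - 0.5))]
  # orientation from the response trend against log x
  b0 <- if (stats::cor(log(x), y) >= 0) -1 else 1
  dat <- data.frame(x = x, y = y)
  one_fit <- function(b_init, loge_init) {
    tryCatch(
      minpack.lm::nlsLM(y ~ 1 / (1 + exp(b * (log(x) - loge))),
                        data = dat,
                        start = list(b = b_init, loge = loge_init),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(err) NULL)
  }
  fit <- one_fit(b0, log(e0))
  if (is.null(fit)) {
    for (b_try in c(b0 * c(0.5, 2, 4), -b0 * c(0.5, 1, 2, 4))) {
      fit <- one_fit(b_try, log(stats::median(x)))
      if (!is.null(fit)) break
    }
  }
  if (is.null(fit))
    stop("4PL fit failed to converge (tried restart grid); n = ",
         length(x), ", response range ", paste(range(y), collapse = ".."),
         call. = FALSE)
  cf <- stats::coef(fit)
  se_loge <- tryCatch(sqrt(stats::vcov(fit)["loge", "loge"]),
                      error = function(err) NA_real_)
  ci <- exp(cf[["loge"]] + c(-1, 1) * 1.96 * se_loge)
  structure(list(
    b = cf[["b"]], e = exp(cf[["loge"]]), c = 0, d = 1,
    sse = sum(stats::residuals(fit)^2),
    ci = stats::setNames(ci, c("lower", "upper")),
    data = dat, fit = fit), class = "fourpl")
}

#' @export
print.fourpl <- function(x, digits = 4, ...) {
  cat(sprintf(
    "<fourpl> EC50 = %s (95%% CI %s..%s), slope b = %s, SSE = %s\n",
    format(x$e, digits = digits), format(x$ci[1], digits = digits),
    format(x$ci[2], digits = digits), format(x$b, digits = digits),
    format(x$sse, digits = digits)))
  invisible(x)
}

#' @export
coef.fourpl <- function(object, ...) {
  c(b = object$b, c = object$c, d = object$d, e = object$e)
}

#' @export
predict.fourpl <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else
    if (is.list(newdata)) newdata$x else newdata
  object$c + (object$d - object$c) / (1 + (x / object$e)^object$b)
}

#' @export
residuals.fourpl <- function(object, ...) {
  object$data$y - predict(object)
}

#' @export
summary.fourpl <- function(object, ...) {
  out <- list(coefficients = coef(object), ec50 = object$e, ci = object$ci,
              sse = object$sse, n = nrow(object$data))
  class(out) <- "summary.fourpl"
  out
}

#' @export
print.summary.fourpl <- function(x, ...) {
  cat("Four-parameter logistic fit (asymptotes fixed at 0 and 1)\n")
  cat(sprintf("  n = %d, SSE = %.4g\n", x$n, x$sse))
  cat(sprintf("  EC50 = %.4g  [%.4g, %.4g]\n", x$ec50, x$ci[1], x$ci[2]))
  cat(sprintf("  slope b = %.4g\n", x$coefficients[["b"]]))
  invisible(x)
}

#' @export
plot.fourpl <- function(x, n_grid = 200, ...) {
  xg <- exp(seq(log(min(x$data$x)), log(max(x$data$x)), length.out = n_grid))
  plot(x$data$x, x$data$y, log = "x", xlab = "concentration",
       ylab = "response fraction", ...)
  graphics::lines(xg, predict(x, xg))
  graphics::abline(v = x$e, lty = 2)
  invisible(x)
}

#' Empirical area under a growth curve
#'
#' Trapezoidal integral of OD over time, no baseline subtraction.
#'
#' @param t Strictly increasing time points (h).
#' @param od Non-negative OD600 readings.
#' @return AUC in OD·h.
#' @export
empirical_auc <- function(t, od) {
  if (length(t) < 2L) stop("need at least 2 points", call. = FALSE)
  if (length(t) != length(od)) stop("t and od lengths differ", call. = FALSE)
  if (any(diff(t) <= 0)) stop("t must be strictly increasing", call. = FALSE)
  if (any(od < 0)) stop("od must be non-negative", call. = FALSE)
  pracma::trapz(t, od)
}

#' Correlation between operator affinity and gene expression response
#'
#' Pearson correlation (with two-sided t-test p-value) between probe EC50s
#' and expression fold changes of the cognate genes, as in
#' knockout-versus-wild-type comparisons. Log transforms are off by
#' default; flags expose log10(EC50) and log2(FC).
#'
#' @param ec50 Positive EC50 values (nM).
#' @param fc Expression fold changes.
#' @param log_ec50 Correlate log10(EC50) instead.
#' @param log2_fc Correlate log2(FC) instead (requires positive FCs).
#' @return List: `r`, `p`, `n`, `method`.
#' @export
affinity_expression_correlation <- function(ec50, fc, log_ec50 = FALSE,
                                            log2_fc = FALSE) {
  if (length(ec50) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (length(ec50) != length(fc)) stop("lengths differ", call. = FALSE)
  if (any(ec50 <= 0)) stop("EC50 values must be positive", call. = FALSE)
  xx <- if (log_ec50) log10(ec50) else ec50
  yy <- if (log2_fc) log2(fc) else fc
  if (stats::sd(xx) == 0 || stats::sd(yy) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  ct <- stats::cor.test(xx, yy, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(xx),
       method = sprintf("pearson%s%s", if (log_ec50) " log10(ec50)" else "",
                        if (log2_fc) " log2(fc)" else ""))
}
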