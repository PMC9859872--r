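#' Four-parameter logistic (4PL) response function
#'
#' `y = A2 + (A1 - A2) / (1 + (x/x0)^p)`. For `p > 0` the value at
#' `x = 0` is the upper asymptote `A1`, the value at `x = x0` is the
#' midpoint `(A1 + A2)/2` (so `x0` is the EC50), and the curve decreases
#' monotonically towards `A2` whenever `A1 > A2`.
#'
#' @param x concentration(s), >= 0.
#' @param A1 upper asymptote (response at zero concentration).
#' @param A2 lower asymptote (response at saturation).
#' @param x0 inflection concentration (EC50), > 0.
#' @param p slope exponent, > 0 for a decreasing inhibition curve.
#' @return Numeric vector of responses.
#' @examples
#' fourpl(c(0, 50, 1e6), 1, 0.1, 50, 1.2)
#' @export
fourpl <- function(x, A1, A2, x0, p) {
  A2 + (A1 - A2) / (1 + (x / x0)^p)
}

# gradient of fourpl wrt (A1, A2, x0, p); rows follow x
fourpl_gradient <- function(x, par) {
  A1 <- par[["A1"]]; A2 <- par[["A2"]]; x0 <- par[["x0"]]; p <- par[["p"]]
  u <- (x / x0)^p
  D <- 1 + u
  dA1 <- 1 / D
  dA2 <- 1 - 1 / D
  dx0 <- (A1 - A2) * u * p / (x0 * D^2)
  lg <- ifelse(x > 0, log(x / x0), 0)      # u * log term vanishes at x = 0
  dp <- -(A1 - A2) * u * lg / D^2
  cbind(A1 = dA1, A2 = dA2, x0 = dx0, p = dp)
}

#' Normalize calibration signals to the zero-concentration blank
#'
#' Divides every signal by the mean signal of the zero-concentration
#' (blank) entries, so the blank's normalized mean is exactly 1. This is
#' the normalization that makes replicate calibrations from different
#' strip batches comparable.
#'
#' @param points data frame with columns `concentration` and the signal
#'   column named by `value`.
#' @param value name of the signal column (default `"signal"`; use
#'   `"ratio"` for test/control ratios).
#' @return The input data frame with an added column `normalized`.
#' @export
normalize_signals <- function(points, value = "signal") {
  stopifnot(is.data.frame(points), "concentration" %in% names(points),
            value %in% names(points))
  blank <- points[[value]][points$concentration == 0]
  if (length(blank) == 0L)
    stop("normalization error: no zero-concentration entry")
  b <- mean(blank)
  if (!is.finite(b) || b <= 0)
    stop("degenerate blank: zero-concentration mean signal must be > 0")
  points$normalized <- points[[value]] / b
  points
}

#' Fit a four-parameter logistic calibration curve
#'
#' Least-squares fit of [fourpl()] to (concentration, signal) points via
#' Levenberg-Marquardt ([minpack.lm::nlsLM]), with the parameter
#' covariance taken from the Jacobian at the optimum
#' (`sigma^2 (J'J)^{-1}`). Concentrations are fitted on the raw scale;
#' the zero-concentration point is handled through the model's own limit
#' `y(0) = A1` (valid for `p > 0`, which is enforced by a bound).
#'
#' @param points data frame with columns `concentration` and the response
#'   column named by `value`; at least 5 distinct concentrations.
#' @param value response column name (default `"normalized"`).
#' @param weights optional per-point weights for weighted least squares
#'   (e.g. `1/SD^2`); default unweighted.
#' @param start optional named list/vector of start values
#'   `(A1, A2, x0, p)`; a data-driven heuristic is used otherwise.
#' @return Object of class `four_pl_fit`: `par` (named estimates), `cov`
#'   (4 x 4 covariance), `sigma2` (residual variance), `df` (n - 4), `n`,
#'   `fitted`, `residuals`, `data`.
#' @examples
#' x <- c(0, 1, 10, 30, 100, 300, 1000, 10000)
#' d <- data.frame(concentration = x,
#'                 normalized = fourpl(x, 1, 0.1, 50, 1.2))
#' coef(fit_4pl(d))
#' @export
fit_4pl <- function(points, value = "normalized", weights = NULL,
                    start = NULL) {
  stopifnot(is.data.frame(points), "concentration" %in% names(points),
            value %in% names(points))
  x <- points$concentration
  y <- points[[value]]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 5L)
    stop("fit error: need >= 5 distinct concentrations")
  if (!any(x == 0))
    warning("no zero-concentration point; A1 is extrapolated")

  if (is.null(start)) {
    a1 <- mean(y[x == min(x)]); a2 <- mean(y[x == max(x)])
    mid <- (a1 + a2) / 2
    xpos <- x[x > 0]
    x0s <- xpos[which.min(abs(y[x > 0] - mid))]
    if (length(x0s) == 0L || x0s <= 0) x0s <- exp(mean(log(xpos)))
    start <- list(A1 = a1, A2 = a2, x0 = x0s, p = 1)
  }
  d <- data.frame(x = x, y = y)
  args <- list(
    y ~ A2 + (A1 - A2) / (1 + (x / x0)^p),
    data = d, start = start,
    lower = c(A1 = -Inf, A2 = -Inf, x0 = 1e-9, p = 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15)
  )
  if (!is.null(weights)) args$weights <- weights
  fit <- tryCatch(
    do.call(minpack.lm::nlsLM, args),
    error = function(e)
      stop("fit error: 4PL fit did not converge (", conditionMessage(e), ")")
  )
  par <- stats::coef(fit)
  if (par[["A1"]] < par[["A2"]])
    warning("orientation warning: fitted A1 < A2 (increasing curve)")
  n <- length(y)
  dfree <- n - 4L
  rss <- stats::deviance(fit)
  sigma2 <- if (dfree > 0) rss / dfree else 0
  J <- fourpl_gradient(x, par)
  if (!is.null(weights)) J <- J * sqrt(weights)
  JtJ <- crossprod(J)
  cov <- tryCatch(sigma2 * chol2inv(chol(JtJ)), error = function(e) NULL)
  if (!is.null(cov)) dimnames(cov) <- list(names(par), names(par))
  structure(list(
    par = par, cov = cov, sigma2 = sigma2, df = dfree, n = n,
    fitted = fourpl(x, par[["A1"]], par[["A2"]], par[["x0"]], par[["p"]]),
    residuals = y - fourpl(x, par[["A1"]], par[["A2"]], par[["x0"]],
                           par[["p"]]),
    data = d
  ), class = "four_pl_fit")
}

#' @export
coef.four_pl_fit <- function(object, ...) object$par

#' @export
predict.four_pl_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else
    if (is.data.frame(newdata)) newdata$x else newdata
  p <- object$par
  fourpl(x, p[["A1"]], p[["A2"]], p[["x0"]], p[["p"]])
}

#' @export
print.four_pl_fit <- function(x, ...) {
  cat("Four-parameter logistic fit\n")
  se <- if (!is.null(x$cov)) sqrt(diag(x$cov)) else rep(NA_real_, 4)
  for (nm in names(x$par))
    cat(sprintf("  %-3s = %10.5g  (SE %.3g)\n", nm, x$par[[nm]], se[[nm]]))
  cat(sprintf("  residual SD %.4g on %d df (n = %d)\n",
              sqrt(x$sigma2), x$df, x$n))
  invisible(x)
}

#' Pointwise confidence band of a fitted 4PL curve
#'
#' Delta-method band: `yhat(x) +/- t(level, df) * SE(yhat(x))` with
#' `SE^2 = g(x)' V g(x)`, `g` the parameter gradient of the curve and `V`
#' the parameter covariance. A parametric-bootstrap band (refitting
#' Gaussian resamples of the fitted curve and taking pointwise quantiles)
#' is available as an independent cross-check.
#'
#' @param fit a [fit_4pl()] object with a valid covariance.
#' @param x concentration grid.
#' @param level confidence level (default 0.95; 0 collapses the band onto
#'   the curve).
#' @param method `"delta"` (default) or `"bootstrap"`.
#' @param n_boot bootstrap draws (method = "bootstrap").
#' @param seed seed for the bootstrap.
#' @return Data frame `x`, `fit`, `se`, `lower`, `upper`.
#' @export
confidence_band <- function(fit, x, level = 0.95,
                            method = c("delta", "bootstrap"),
                            n_boot = 2000L, seed = 0L) {
  stopifnot(inherits(fit, "four_pl_fit"))
  method <- match.arg(method)
  yhat <- predict(fit, x)
  if (method == "delta") {
    if (is.null(fit$cov))
      stop("band error: singular covariance, no confidence band")
    G <- fourpl_gradient(x, fit$par)
    se <- sqrt(pmax(rowSums((G %*% fit$cov) * G), 0))
    tq <- stats::qt((1 + level) / 2, df = fit$df)
    data.frame(x = x, fit = yhat, se = se,
               lower = yhat - tq * se, upper = yhat + tq * se)
  } else {
    mu <- predict(fit)
    sd <- sqrt(fit$sigma2)
    curves <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        yb <- mu + stats::rnorm(fit$n, 0, sd)
        fb <- tryCatch(
          fit_4pl(data.frame(concentration = fit$data$x, normalized = yb),
                  start = as.list(fit$par)),
          error = function(e) NULL)
        if (is.null(fb)) rep(NA_real_, length(x)) else predict(fb, x)
      }, numeric(length(x)))
    })
    curves <- curves[, colSums(is.na(curves)) == 0, drop = FALSE]
    alpha <- (1 - level) / 2
    data.frame(
      x = x, fit = yhat,
      se = apply(curves, 1L, stats::sd),
      lower = apply(curves, 1L, stats::quantile, probs = alpha),
      upper = apply(curves, 1L, stats::quantile, probs = 1 - alpha)
    )
  }
}

# bisection on the log-concentration scale to relative tolerance
bisect_log <- function(f, lo, hi, rel_tol = 1e-6) {
  flo <- f(lo); fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi) || sign(flo) == sign(fhi))
    stop("limit beyond calibrated range: no sign change in bracket [",
         format(lo), ", ", format(hi), "]")
  while (hi / lo - 1 > rel_tol) {
    mid <- sqrt(lo * hi)
    if (sign(f(mid)) == sign(flo)) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' Confidence-band-derived detection limits (MDC and RDL)
#'
#' For a decreasing inhibition curve, the critical response is the lower
#' limit of the confidence band evaluated at zero concentration. The
#' minimum detectable concentration (MDC) is the concentration at which
#' the fitted calibration curve crosses that critical response, and the
#' reliable detection limit (RDL) is where the upper band limit crosses
#' it. Both are located by bracketing bisection on a log-concentration
#' scale. Since the upper band lies above the curve, `MDC <= RDL` always.
#'
#' The sentence defining these limits admits a second reading, exposed
#' via `rule = "lower-upper"`: MDC from the crossing of the lower band
#' limit (instead of the curve) with the critical response.
#'
#' @param fit a [fit_4pl()] object (requires `A1 > A2`).
#' @param level confidence level of the band (default 0.95).
#' @param rule `"curve-upper"` (default: MDC on the curve, RDL on the
#'   upper band) or `"lower-upper"` (MDC on the lower band).
#' @param bracket search interval in ug/l.
#' @param rel_tol relative bisection tolerance.
#' @return List of class `detection_limits`: `MDC`, `RDL`, `EC50`,
#'   `level`, `y_crit`.
#' @export
detection_limits <- function(fit, level = 0.95,
                             rule = c("curve-upper", "lower-upper"),
                             bracket = c(1e-3, 1e5), rel_tol = 1e-6) {
  stopifnot(inherits(fit, "four_pl_fit"))
  rule <- match.arg(rule)
  if (fit$par[["A1"]] <= fit$par[["A2"]])
    stop("detection limits require a decreasing curve (A1 > A2)")
  band0 <- confidence_band(fit, 0, level = level)
  y_crit <- band0$lower
  tq <- stats::qt((1 + level) / 2, df = fit$df)
  curve_f <- function(x) predict(fit, x) - y_crit
  upper_f <- function(x) {
    b <- confidence_band(fit, x, level = level)
    b$fit + tq * b$se - y_crit
  }
  lower_f <- function(x) {
    b <- confidence_band(fit, x, level = level)
    b$fit - tq * b$se - y_crit
  }
  solve_limit <- function(f) {
    # f is positive near 0 and negative past the crossing; a collapsed
    # band puts the crossing below the bracket, i.e. effectively at 0
    if (f(bracket[1L]) <= 0) return(bracket[1L])
    bisect_log(f, bracket[1L], bracket[2L], rel_tol)
  }
  mdc_f <- if (rule == "curve-upper") curve_f else lower_f
  mdc <- solve_limit(mdc_f)
  rdl <- solve_limit(upper_f)
  structure(list(MDC = mdc, RDL = rdl, EC50 = unname(fit$par[["x0"]]),
                 level = level, y_crit = y_crit, rule = rule),
            class = "detection_limits")
}

#' @export
print.detection_limits <- function(x, ...) {
  cat(sprintf("MDC = %.4g ug/l, RDL = %.4g ug/l, EC50 = %.4g ug/l (%d%% band)\n",
              x$MDC, x$RDL, x$EC50, round(100 * x$level)))
  invisible(x)
}

#' Compare calibrations of different conjugates
#'
#' Aggregates fitted calibrations (e.g. triplicate batches per conjugate)
#' into a ranking table of EC50 (mean and standard error), MDC and RDL
#' per conjugate label.
#'
#' @param fits list of [fit_4pl()] objects.
#' @param limits list of [detection_limits()] objects, parallel to `fits`.
#' @param labels character vector of conjugate labels, parallel to `fits`;
#'   repeated labels are aggregated as replicate batches.
#' @return Data frame with one row per label: `label`, `n_batches`,
#'   `EC50`, `EC50_se`, `MDC`, `MDC_se`, `RDL`, `RDL_se`.
#' @export
compare_conjugates <- function(fits, limits, labels) {
  if (length(fits) < 2L)
    stop("need >= 2 calibrations to compare")
  stopifnot(length(fits) == length(limits), length(fits) == length(labels))
  grids <- lapply(fits, function(f) sort(unique(f$data$x)))
  if (length(unique(vapply(grids, paste, "", collapse = ","))) > 1L)
    warning("comparability warning: calibrations use different concentration grids")
  agg <- function(v) c(mean = mean(v),
                       se = if (length(v) > 1L) stats::sd(v) / sqrt(length(v))
                            else 0)
  out <- do.call(rbind, lapply(unique(labels), function(lb) {
    i <- which(labels == lb)
    ec <- agg(vapply(fits[i], function(f) unname(f$par[["x0"]]), 0))
    md <- agg(vapply(limits[i], function(l) l$MDC, 0))
    rd <- agg(vapply(limits[i], function(l) l$RDL, 0))
    data.frame(label = lb, n_batches = length(i),
               EC50 = ec[["mean"]], EC50_se = ec[["se"]],
               MDC = md[["mean"]], MDC_se = md[["se"]],
               RDL = rd[["mean"]], RDL_se = rd[["se"]])
  }))
  rownames(out) <- NULL
  out[order(out$MDC), ]
}
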