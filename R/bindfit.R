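# Sigmoid fitting for binding and stability assays. A single 4-parameter
# Hill kernel backs both the titration K_D fit and the thermal-melt Tm fit.

#' Four-parameter Hill sigmoid
#'
#' `y = base + (amplitude - base) * x^n / (k^n + x^n)`. For titrations `k`
#' is read as the dissociation constant K_D; for melts (x = temperature) it
#' is the transition midpoint Tm and `n` absorbs the transition steepness.
#'
#' @param x abscissa (concentration in µM, or temperature in °C).
#' @param base,amplitude low- and high-x plateaus (signal units).
#' @param k half-transition abscissa.
#' @param n Hill coefficient (steepness).
#' @return predicted signal.
#' @export
hill_curve <- function(x, base, amplitude, k, n)
  base + (amplitude - base) * x^n / (k^n + x^n)

# Shared nonlinear LS driver. Initialisation: plateaus from the signal
# extremes, k from the x nearest half-signal, n = 1 (titration) or a slope
# guess (melt). port algorithm with positivity bounds on k and n.
.fit_hill_kernel <- function(x, y, n_start = 1, fix_n = NULL) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  base0 <- y[1]; amp0 <- y[length(y)]
  k0 <- x[which.min(abs(y - (base0 + amp0) / 2))]
  if (k0 <= min(x)) k0 <- stats::median(x)
  ctrl <- stats::nls.control(maxiter = 10000, tol = 1e-10, minFactor = 1e-12,
                             warnOnly = FALSE)
  fit <- tryCatch({
    if (is.null(fix_n)) {
      stats::nls(y ~ hill_curve(x, base, amplitude, k, n),
                 start = list(base = base0, amplitude = amp0, k = k0,
                              n = n_start),
                 lower = c(base = -Inf, amplitude = -Inf, k = min(x) * 1e-3,
                           n = 0.05),
                 upper = c(Inf, Inf, max(x) * 1e3, 50),
                 algorithm = "port", control = ctrl)
    } else {
      n <- fix_n
      stats::nls(y ~ hill_curve(x, base, amplitude, k, n),
                 start = list(base = base0, amplitude = amp0, k = k0),
                 lower = c(-Inf, -Inf, min(x) * 1e-3),
                 upper = c(Inf, Inf, max(x) * 1e3),
                 algorithm = "port", control = ctrl)
    }
  }, error = function(e) NULL)
  if (is.null(fit)) return(list(converged = FALSE))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  list(converged = TRUE, base = unname(cf["base"]),
       amplitude = unname(cf["amplitude"]), k = unname(cf["k"]),
       n = if (is.null(fix_n)) unname(cf["n"]) else fix_n,
       se = se, residual_sd = stats::sigma(fit), fit = fit)
}

#' Hill fit of a fluorescence-polarisation titration
#'
#' Least-squares fit of [hill_curve()] to polarization vs. concentration;
#' `k` is returned as the dissociation constant K_D in the concentration
#' units of the input (µM in the standard assay design, a 0.02-12.5 µM
#' serial dilution). With `fix_n = 1` the fit reduces to a simple binding
#' isotherm; by default `n` is free.
#'
#' @param curve data.frame with columns `concentration` (> 0, at least 5
#'   distinct values) and `signal`.
#' @param fix_n optional fixed Hill coefficient.
#' @return list of class `hill_fit`: `kd`, `n`, `base`, `amplitude`, `se`
#'   (named standard errors), `converged`. On non-convergence only
#'   `converged = FALSE` is returned — no estimates.
#' @export
fit_hill <- function(curve, fix_n = NULL) {
  stopifnot(all(curve$concentration > 0),
            length(unique(curve$concentration)) >= 5)
  res <- .fit_hill_kernel(curve$concentration, curve$signal, fix_n = fix_n)
  if (!res$converged) return(structure(list(converged = FALSE),
                                       class = "hill_fit"))
  structure(list(kd = res$k, n = res$n, base = res$base,
                 amplitude = res$amplitude, se = res$se,
                 residual_sd = res$residual_sd, converged = TRUE),
            class = "hill_fit")
}

#' Sigmoid fit of a thermal melt
#'
#' Fits the same Hill kernel with temperature as abscissa; the midpoint `k`
#' is reported as the melting temperature Tm (°C). Non-sigmoid data is
#' flagged as non-converged. The steepness parameter doubles as the
#' transition slope; pre/post plateaus come from `base` and `amplitude`.
#'
#' @param curve data.frame with columns `temperature` and `signal`.
#' @return list of class `melt_fit`: `tm`, `slope_n`, `base`, `amplitude`,
#'   `se`, `converged`.
#' @export
fit_melt <- function(curve) {
  res <- .fit_hill_kernel(curve$temperature, curve$signal, n_start = 30)
  if (!res$converged) return(structure(list(converged = FALSE),
                                       class = "melt_fit"))
  tm <- res$k
  # a genuine melt is a sigmoid: require the fit to explain the variance
  # and the midpoint to fall inside the scanned range
  pred <- hill_curve(curve$temperature, res$base, res$amplitude, tm, res$n)
  r2 <- 1 - sum((curve$signal - pred)^2) /
    max(sum((curve$signal - mean(curve$signal))^2), 1e-300)
  ok <- r2 >= 0.8 && tm >= min(curve$temperature) &&
    tm <= max(curve$temperature)
  structure(list(tm = tm, slope_n = res$n, base = res$base,
                 amplitude = res$amplitude, se = res$se,
                 converged = ok), class = "melt_fit")
}

#' Inflection temperature from a first-derivative scan
#'
#' Smooths the signal (e.g. the 350/330 nm intrinsic-fluorescence ratio)
#' with a centered moving average, differentiates numerically, and reports
#' Ti as the temperature of the extremal |derivative|. All local extrema of
#' the derivative magnitude above 20% of the global one are also listed, so
#' double transitions are visible rather than hidden.
#'
#' @param curve data.frame with `temperature` (>= 20 points) and `signal`.
#' @param smoothing_window centered moving-average width, points (default 5).
#' @return list of class `derivative_result`: `ti` (°C), `extrema`
#'   (data.frame temperature/derivative at the reported local extrema),
#'   `derivative` (data.frame over the full scan).
#' @export
first_derivative_ti <- function(curve, smoothing_window = 5L) {
  x <- curve$temperature; y <- curve$signal
  stopifnot(length(x) >= 20)
  ord <- order(x); x <- x[ord]; y <- y[ord]
  k <- max(1L, as.integer(smoothing_window))
  sm <- stats::filter(y, rep(1 / k, k), sides = 2)
  sm <- as.numeric(sm)
  pad <- which(!is.na(sm))
  xs <- x[pad]; ys <- sm[pad]
  d <- diff(ys) / diff(xs)
  xm <- (xs[-1] + xs[-length(xs)]) / 2
  if (max(abs(d)) < 1e-12 * max(1, diff(range(y))) || diff(range(y)) == 0)
    stop("flat signal: no inflection")
  # guard against genuinely featureless (linear) scans
  if (stats::sd(d) < 1e-8 * max(abs(d)))
    stop("linear signal: no inflection")
  a <- abs(d)
  loc <- which(diff(sign(diff(a))) < 0) + 1L
  loc <- loc[a[loc] >= 0.2 * max(a)]
  if (!length(loc)) loc <- which.max(a)
  structure(list(ti = xm[which.max(a)],
                 extrema = data.frame(temperature = xm[loc],
                                      derivative = d[loc]),
                 derivative = data.frame(temperature = xm, derivative = d)),
            class = "derivative_result")
}

#' Welch (unequal-variance) unpaired t-test
#'
#' Closed-form Welch statistic: `t = (mean_a - mean_b) / sqrt(va/na + vb/nb)`
#' with Welch-Satterthwaite degrees of freedom and two-sided p; significance
#' at alpha = 0.05. Two groups with zero variance and equal means give
#' t = 0, p = 1.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param alpha significance level (default 0.05).
#' @return list of class `ttest_result`: `t`, `df`, `p`, `significant`.
#' @export
unpaired_ttest <- function(group_a, group_b, alpha = 0.05) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  na <- length(group_a); nb <- length(group_b)
  va <- stats::var(group_a); vb <- stats::var(group_b)
  sed2 <- va / na + vb / nb
  if (sed2 == 0) {
    t_stat <- 0; df <- na + nb - 2; p <- 1
  } else {
    t_stat <- (mean(group_a) - mean(group_b)) / sqrt(sed2)
    df <- sed2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  structure(list(t = t_stat, df = df, p = p, significant = p < alpha),
            class = "ttest_result")
}
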