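# Langmuir-monolayer analysis: peptide adsorption kinetics at the
# air-water interface and extrapolation of the critical insertion
# pressure pi_c, the monolayer packing density above which the peptide
# can no longer insert.  A pi_c well above ~30 mN/m (the lateral pressure
# of a natural plasma membrane) indicates high avidity for the lipid.

#' Fit peptide insertion kinetics
#'
#' Fits the surface-pressure increase to a mono-exponential approach to
#' saturation, `dpi(t) = dpi_max * (1 - exp(-k t))`, by nonlinear least
#' squares, and reports the initial insertion velocity `v0 = k * dpi_max`
#' (the slope at t = 0).  If the fit does not converge the finite
#' difference slope over the first two points is returned as `v0` with
#' `fallback = TRUE`.
#'
#' @param time time points (min), strictly increasing, at least 4.
#' @param dpi surface-pressure increase at each time (mN/m), non-negative.
#' @return `list(dpi_max, k, v0, fallback, flat)`; an all-zero trace
#'   gives `(0, 0, 0)` with `flat = TRUE`.
#' @examples
#' t <- seq(0, 30, by = 2)
#' fitInsertionKinetics(t, 15 * (1 - exp(-0.2 * t)))
#' @export
fitInsertionKinetics <- function(time, dpi) {
  time <- as.numeric(time); dpi <- as.numeric(dpi)
  if (length(time) != length(dpi)) stop("time and dpi lengths differ")
  if (length(time) < 4L) stop("kinetic fit needs at least 4 points")
  if (is.unsorted(time, strictly = TRUE)) stop("time must be strictly increasing")
  if (any(dpi < 0)) stop("dpi must be non-negative")
  if (all(dpi == 0))
    return(list(dpi_max = 0, k = 0, v0 = 0, fallback = FALSE, flat = TRUE))
  k0 <- {
    # crude rate guess from the time to half-saturation
    half <- max(dpi) / 2
    th <- time[which(dpi >= half)[1L]]
    if (is.na(th) || th <= 0) 1 else log(2) / th
  }
  fit <- tryCatch(
    stats::nls(dpi ~ dmax * (1 - exp(-k * time)),
               start = list(dmax = max(dpi), k = k0),
               # scaleOffset makes the convergence test valid on noiseless data
               control = stats::nls.control(maxiter = 200, scaleOffset = 1)),
    error = function(e) NULL)
  if (is.null(fit)) {
    dt <- time[2L] - time[1L]
    slope <- (dpi[2L] - dpi[1L]) / dt
    return(list(dpi_max = max(dpi), k = NA_real_, v0 = slope,
                fallback = TRUE, flat = FALSE))
  }
  cf <- stats::coef(fit)
  list(dpi_max = unname(cf[["dmax"]]), k = unname(cf[["k"]]),
       v0 = unname(cf[["dmax"]] * cf[["k"]]), fallback = FALSE, flat = FALSE)
}

#' Estimate the critical insertion pressure
#'
#' Ordinary least-squares line through the insertion isotherm
#' `dpi_max = a + b * pi0`; the critical pressure of insertion is the
#' x-intercept `pi_c = -a / b`, the initial pressure at which the
#' peptide-induced pressure increase extrapolates to zero.  Requires a
#' negative slope (insertion must decrease with monolayer density).
#'
#' @param pi0 initial surface pressures (mN/m), at least 2 distinct
#'   values (3 or more recommended for a meaningful residual).
#' @param dpi_max maximal pressure increases at each `pi0` (mN/m).
#' @return `list(pi_c, slope, intercept, sigma)` where `sigma` is the
#'   residual standard error (`NA` for an exact two-point line).
#' @examples
#' pi0 <- c(10, 15, 20, 25, 30, 35)
#' estimatePiC(pi0, 21.25 - 0.5 * pi0)$pi_c  # 42.5
#' @export
estimatePiC <- function(pi0, dpi_max) {
  pi0 <- as.numeric(pi0); dpi_max <- as.numeric(dpi_max)
  if (length(pi0) != length(dpi_max)) stop("pi0 and dpi_max lengths differ")
  if (length(pi0) < 2L || length(unique(pi0)) < 2L)
    stop("pi_c estimation needs at least 2 points at distinct pi0 values")
  if (length(pi0) < 3L)
    message("fewer than 3 isotherm points: line is exact, no residual estimate")
  if (any(dpi_max < 0))
    warning("negative dpi_max value(s) in the isotherm")
  fit <- stats::lm(dpi_max ~ pi0)
  a <- unname(stats::coef(fit)[1L]); b <- unname(stats::coef(fit)[2L])
  if (!is.finite(b) || b >= 0)
    stop("isotherm slope is not negative: no extrapolable pi_c")
  sigma <- if (length(pi0) > 2L)
    sqrt(sum(stats::residuals(fit)^2) / stats::df.residual(fit))
  else NA_real_
  list(pi_c = -a / b, slope = b, intercept = a, sigma = sigma)
}
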