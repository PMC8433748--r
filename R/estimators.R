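# Initial-guess machinery and the classical empirical cmc estimators kept for
# comparison with the concentration-model fits: two-line intersection,
# smoothed-derivative extrema and the Boltzmann sigmoid midpoint. For
# properties that are nonlinear in the species concentrations these
# estimators are biased by construction (the extremum of a property
# derivative is generally not at the cmc); the model fits are not.

# local-quadratic (Savitzky-Golay-type) smoothed derivatives on a possibly
# non-uniform grid; window is a fraction of the points, at least 5
.smooth_deriv <- function(x, y, window_frac = 0.2) {
  n <- length(x)
  w <- max(5L, ceiling(window_frac * n))
  half <- w %/% 2L
  d1 <- d2 <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    if (hi - lo + 1L < 3L) { lo <- max(1L, hi - 2L); hi <- min(n, lo + 2L) }
    t <- x[lo:hi] - x[i]
    co <- stats::lm.fit(cbind(1, t, t^2), y[lo:hi])$coefficients
    d1[i] <- co[2]
    d2[i] <- 2 * co[3]
  }
  list(d1 = d1, d2 = d2)
}

# least-squares line through a segment; returns c(intercept, slope)
.seg_line <- function(x, y) stats::lm.fit(cbind(1, x), y)$coefficients

#' Initial parameter specifications for a curve
#'
#' Heuristic starting values for [fit_curve()]: the critical concentration
#' from the extremum of the magnitude of a local-quadratic smoothed second
#' derivative (window 20% of the points, at least 5), clipped to the interior
#' 10-90% of the concentration range; r starts at 0.1; slopes of linear
#' properties from least-squares lines on the lowest and highest 25% of the
#' points; sigmoid plateau limits from the mean of the first/last 3 values.
#'
#' @param curve a [titration_curve].
#' @param model_kind model the specs are for (default: the curve's kind).
#' @return List of [param_spec] objects covering the model's parameters.
#' @export
initial_guess <- function(curve, model_kind = NULL) {
  stopifnot(inherits(curve, "titration_curve"))
  kind <- if (is.null(model_kind)) curve$kind else model_kind
  model <- .get_model(kind)
  x <- curve$x; y <- curve$y; n <- length(x)
  if (n < 6L) stop("need at least 6 points for initial guesses", call. = FALSE)

  sd2 <- .smooth_deriv(x, y, 0.2)$d2
  i0 <- which.max(abs(sd2))
  xr <- range(x)
  cmc0 <- min(max(x[i0], xr[1] + 0.1 * diff(xr)), xr[1] + 0.9 * diff(xr))
  cmc0 <- max(cmc0, 1e-12)

  n_seg <- max(3L, floor(0.25 * n))
  low <- .seg_line(x[1:n_seg], y[1:n_seg])
  high <- .seg_line(x[(n - n_seg + 1):n], y[(n - n_seg + 1):n])
  y_lo <- mean(y[1:3]); y_hi <- mean(y[(n - 2):n])

  ps <- function(name, init, fixed = FALSE) param_spec(name, init, fixed = fixed)
  specs <- switch(kind,
    conductivity = list(
      ps("cmc", cmc0), ps("r", 0.1),
      ps("a", max(low[2], 1e-8)), ps("b", high[2]), ps("kappa_s", low[1])),
    molar_conductivity = list(
      ps("cmc", cmc0), ps("r", 0.1), ps("a", y_lo), ps("b", y_hi)),
    carpena = list(
      ps("cmc", cmc0), ps("delta", 0.0625 * cmc0),
      ps("a", max(low[2], 1e-8)), ps("b", high[2]), ps("kappa_s", low[1])),
    surface_tension = list(
      ps("cmc", cmc0), ps("r", 0.1), ps("gamma0", max(y)),
      ps("st_coeff", max((max(y) - min(y)) / log(11), 1e-8)),
      ps("k_ad", 10 / cmc0)),
    nmr = list(
      ps("cmc", cmc0), ps("r", 0.1),
      ps("delta_free", y_lo), ps("delta_mic", y_hi)),
    fluorescence = list(
      ps("cmc", cmc0), ps("r", 0.1), ps("k", 2 / cmc0),
      ps("f_free", y_lo), ps("f_bound", y_hi)),
    pyrene_ratio = list(
      ps("cmc", cmc0), ps("r", 0.1), ps("c", 2 / cmc0),
      ps("sr_free", y_lo), ps("sr_bound", y_hi)),
    absorbance = list(
      ps("cmc", cmc0), ps("r", 0.1),
      ps("eps_free", low[2]), ps("eps_mic", high[2]),
      ps("path", 1, fixed = TRUE)),
    absorbance_ratio = list(
      ps("cmc", cmc0), ps("r", 0.1),
      ps("q1", y_lo), ps("qm", y_hi), ps("qa", 1)),
    fcs_diffusion = list(
      ps("cmc", cmc0), ps("r", 0.1), ps("k", 2 / cmc0),
      ps("d_free", y_lo), ps("d_bound", max(y_hi, 1e-3 * y_lo))),
    aggregation = list(ps("cac", cmc0), ps("r", 0.3)),
    boltzmann = list(
      ps("x0", cmc0), ps("dx", 0.05 * cmc0), ps("a1", y_lo), ps("a2", y_hi)),
    stop("no initial-guess rule for kind '", kind, "'", call. = FALSE)
  )
  specs
}

#' Two-line intersection estimate of the cmc
#'
#' The classical graphical estimator: least-squares lines through the low and
#' high concentration branches; the abscissa of their intersection is
#' returned. Exact for piecewise-linear data; biased for sigmoid properties,
#' where the result depends on intrinsic parameters such as the dye binding
#' constant even though the true cmc is unchanged.
#'
#' @param curve a [titration_curve].
#' @param low_frac,high_frac fractions of the points used for the low and
#'   high segments (each at least 3 points; segments must not overlap).
#' @return Estimated critical concentration.
#' @export
two_line_intersection_cmc <- function(curve, low_frac = 0.25,
                                      high_frac = 0.25) {
  stopifnot(inherits(curve, "titration_curve"))
  x <- curve$x; y <- curve$y; n <- length(x)
  n_lo <- max(3L, floor(low_frac * n))
  n_hi <- max(3L, floor(high_frac * n))
  if (n_lo + n_hi > n) stop("segments overlap; reduce fractions", call. = FALSE)
  lo <- .seg_line(x[1:n_lo], y[1:n_lo])
  hi <- .seg_line(x[(n - n_hi + 1):n], y[(n - n_hi + 1):n])
  if (abs(lo[2] - hi[2]) < 1e-12 * max(abs(lo[2]), abs(hi[2]), 1e-300)) {
    stop("branch lines are parallel; no intersection", call. = FALSE)
  }
  unname((hi[1] - lo[1]) / (lo[2] - hi[2]))
}

#' Derivative-extremum estimate of the cmc
#'
#' Classical estimator from the extremum of a smoothed numerical derivative
#' of the measured property: order 1 uses the extremum of the first
#' derivative, order 2 the extremum of the magnitude of the second
#' derivative. The discrete extremum is refined by quadratic interpolation
#' through the three surrounding grid points; exact ties resolve to the
#' smallest concentration. For properties nonlinear in the species
#' concentrations the result is systematically offset from the cmc.
#'
#' @param curve a [titration_curve].
#' @param order derivative order, 1 or 2.
#' @param window_frac smoothing window as a fraction of the points.
#' @return Estimated critical concentration.
#' @export
derivative_cmc <- function(curve, order = 2L, window_frac = 0.2) {
  stopifnot(inherits(curve, "titration_curve"), order %in% c(1L, 2L))
  x <- curve$x
  sd <- .smooth_deriv(x, curve$y, window_frac)
  v <- abs(if (order == 1L) sd$d1 else sd$d2)
  if (diff(range(v)) <= 1e-10 * max(v, 1e-300)) {
    stop("derivative is flat; no extremum to locate", call. = FALSE)
  }
  i <- which(v == max(v))[1]  # first occurrence = smallest concentration
  if (i == 1L || i == length(x)) return(x[i])
  # quadratic through the three points around the extremum
  xs <- x[(i - 1):(i + 1)]; vs <- v[(i - 1):(i + 1)]
  co <- stats::lm.fit(cbind(1, xs, xs^2), vs)$coefficients
  if (!is.finite(co[3]) || co[3] >= 0) return(x[i])
  vertex <- -co[2] / (2 * co[3])
  if (vertex < xs[1] || vertex > xs[3]) x[i] else unname(vertex)
}

#' Boltzmann sigmoid fit (comparison estimator)
#'
#' Fits the empirical sigmoid `y = a2 + (a1 - a2)/(1 + exp((x - x0)/dx))`
#' with dx > 0 enforced by parameterization. The midpoint `x0` is a popular
#' cmc surrogate for sigmoid data but does not coincide with any fixed
#' characteristic point of the concentration model; it is provided for
#' comparison only.
#'
#' @param curve a [titration_curve] of sigmoid shape.
#' @return A `cmc_fit` with parameters `x0`, `dx`, `a1`, `a2`.
#' @export
boltzmann_sigmoid_fit <- function(curve) {
  fit_curve(curve, model_kind = "boltzmann")
}

#' Compare the concentration model with the Boltzmann conductivity model
#'
#' Fits both the concentration model and the integrated Boltzmann (Carpena)
#' expression to the same conductivity data and reports the two cmc values,
#' the two reduced chi-squared values and the width ratio
#' sigma/delta = (r_hat * cmc_hat)/delta_hat. In practice the two cmc values
#' are nearly identical and the width ratio falls between about 1.5 and 1.8.
#'
#' @param curve a conductivity [titration_curve].
#' @return Object of class `carpena_comparison`.
#' @export
compare_carpena <- function(curve) {
  stopifnot(inherits(curve, "titration_curve"))
  if (curve$kind != "conductivity") {
    stop("comparison is defined for conductivity curves", call. = FALSE)
  }
  fm <- fit_curve(curve)
  fc <- fit_curve(curve, model_kind = "carpena")
  structure(list(
    model_fit = fm, carpena_fit = fc,
    cmc_model = unname(fm$estimates["cmc"]),
    cmc_carpena = unname(fc$estimates["cmc"]),
    red_chi2_model = fm$red_chi2, red_chi2_carpena = fc$red_chi2,
    sigma_delta_ratio = unname(fm$estimates["r"] * fm$estimates["cmc"] /
                                 fc$estimates["delta"])
  ), class = "carpena_comparison")
}

#' @export
print.carpena_comparison <- function(x, ...) {
  cat("Concentration model vs Boltzmann conductivity model\n")
  cat(sprintf("  cmc (model):    %#.6g\n", x$cmc_model))
  cat(sprintf("  cmc (Boltzmann):%#.6g\n", x$cmc_carpena))
  cat(sprintf("  reduced chi^2:  %.4g vs %.4g\n",
              x$red_chi2_model, x$red_chi2_carpena))
  cat(sprintf("  sigma/delta:    %.3f\n", x$sigma_delta_ratio))
  invisible(x)
}

#' Sparse-data fitting protocol
#'
#' Subsamples a curve to `k` points and fits the concentration model with the
#' relative transition width either free or fixed. With sparse data the width
#' is poorly defined, but fixing it (e.g. at 0.1, or at 0.001 where the model
#' collapses to two intersecting straight lines) still determines the cmc,
#' within errors, at the full-curve value.
#'
#' @param curve a [titration_curve].
#' @param k number of points to keep (>= 6 for conductivity-type models).
#' @param r_fixed fixed value for `r`, or `NULL` to leave it free.
#' @param strategy subsampling strategy, see [subsample()].
#' @param seed seed for the `"random"` strategy.
#' @return A `cmc_fit` with element `subsample_indices` recording the kept
#'   points.
#' @export
sparse_fit_protocol <- function(curve, k, r_fixed = NULL,
                                strategy = "endpoints_spread", seed = NULL) {
  stopifnot(inherits(curve, "titration_curve"))
  if (k < 6L) stop("'k' must be at least 6", call. = FALSE)
  sub <- subsample(curve, k, strategy = strategy, seed = seed)
  specs <- initial_guess(sub)
  if (!is.null(r_fixed)) {
    for (i in seq_along(specs)) {
      if (specs[[i]]$name == "r") {
        specs[[i]] <- param_spec("r", r_fixed, fixed = TRUE)
      }
    }
  }
  fit <- fit_curve(sub, specs = specs)
  fit$subsample_indices <- attr(sub, "indices")
  fit
}
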