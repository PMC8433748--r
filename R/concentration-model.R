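#' cmcfit: cmc and transition-width determination from titration data
#'
#' A surfactant concentration model gives the monomer concentration \[S1\] as a
#' closed-form function of the total concentration \[S\]0, parameterized by the
#' critical micelle concentration (cmc) and the relative transition width r.
#' Property models (conductivity, surface tension, NMR shift, fluorescence,
#' absorbance, diffusion, aggregation fraction) are built on it and fitted to
#' titration data by damped nonlinear least squares.
#'
#' @keywords internal
"_PACKAGE"

# error function; erf(x) = 2*Phi(x*sqrt(2)) - 1
erf <- function(x) 2 * stats::pnorm(sqrt(2) * x) - 1

# relative widths below this are evaluated with the piecewise-linear limit
# [S1] = min(s0, cmc) to avoid 0 * Inf in the closed form
.R_LINEAR_LIMIT <- 1e-6

#' Micellization parameters
#'
#' Bundle of the two concentration-model parameters, the critical micelle
#' concentration `cmc` and the relative transition width `r = sigma/cmc`,
#' optionally with the mean aggregation number `n` (needed only to form the
#' micelle concentration \[M\] = \[Sm\]/n). Units of `cmc` are whatever the
#' caller uses consistently (mM, mol/kg, nM, ...): the model is scale
#' invariant in (cmc, sigma).
#'
#' @param cmc critical micelle concentration, > 0.
#' @param r relative transition width (sigma/cmc), > 0.
#' @param n mean aggregation number, >= 1, or `NULL`.
#' @return An object of class `micellization_params`.
#' @examples
#' micellization_params(cmc = 8.099, r = 0.112)
#' @export
micellization_params <- function(cmc, r, n = NULL) {
  stopifnot(is.numeric(cmc), length(cmc) == 1L, is.finite(cmc),
            is.numeric(r), length(r) == 1L, is.finite(r))
  if (cmc <= 0) stop("'cmc' must be > 0", call. = FALSE)
  if (r <= 0) stop("'r' must be > 0", call. = FALSE)
  if (!is.null(n)) {
    stopifnot(is.numeric(n), length(n) == 1L, is.finite(n))
    if (n < 1) stop("aggregation number 'n' must be >= 1", call. = FALSE)
  }
  structure(list(cmc = cmc, r = r, n = n), class = "micellization_params")
}

#' @export
print.micellization_params <- function(x, ...) {
  cat("Micellization parameters: cmc =", format(x$cmc),
      " r =", format(x$r), " sigma =", format(x$r * x$cmc))
  if (!is.null(x$n)) cat("  n =", format(x$n))
  cat("\n")
  invisible(x)
}

#' Transition width from the relative width
#'
#' `sigma = r * cmc` (or `r * cac` for aggregating non-surfactant systems).
#'
#' @param cmc critical micelle (or aggregation) concentration, > 0.
#' @param r relative transition width, >= 0.
#' @return The absolute transition width sigma in the units of `cmc`.
#' @examples
#' sigma_from_relative_width(90, 0.36) # cac 90 nM -> sigma 32.4 nM
#' @export
sigma_from_relative_width <- function(cmc, r) {
  if (any(cmc <= 0)) stop("'cmc' must be > 0", call. = FALSE)
  if (any(r < 0)) stop("'r' must be >= 0", call. = FALSE)
  r * cmc
}

#' Amplitude of the concentration model
#'
#' Normalization constant A(r) of the Gaussian second derivative of the
#' monomer concentration. It is exactly the constant that makes the monomer
#' concentration vanish at zero total concentration:
#' `A = 2 / (1 + sqrt(2/pi) r exp(-1/(2 r^2)) + erf(1/(sqrt(2) r)))`.
#' For r < 0.4, A is 1 to within 0.1%. A is always derived from r, never a
#' free fit parameter. For very small r the exponential underflows to exact
#' zero and erf saturates, so A -> 1 silently.
#'
#' @param r relative transition width, > 0 (vectorized).
#' @return Dimensionless amplitude in (0, 1].
#' @examples
#' amplitude(0.4)  # ~ 1.00
#' amplitude(1.0)  # ~ 0.9231
#' @export
amplitude <- function(r) {
  if (any(!is.finite(r)) || any(r <= 0)) stop("'r' must be > 0", call. = FALSE)
  2 / (1 + sqrt(2 / pi) * r * exp(-1 / (2 * r^2)) + erf(1 / (sqrt(2) * r)))
}

#' Monomer concentration
#'
#' Closed-form monomer concentration \[S1\] as a function of total surfactant
#' concentration \[S\]0: the double integral of a Gaussian centred at the cmc
#' with width sigma = r*cmc, normalized so that \[S1\](0) = 0 and
#' \[S1\] -> cmc as \[S\]0 -> Inf. For `r` below 1e-6 the piecewise-linear
#' limit `min(s0, cmc)` is returned.
#'
#' @param s0 total concentration(s), >= 0.
#' @param params a [micellization_params] object.
#' @return Monomer concentration(s), same unit as `s0`.
#' @examples
#' p <- micellization_params(cmc = 1, r = 0.1)
#' monomer_concentration(c(0, 1, 100), p)
#' @export
monomer_concentration <- function(s0, params) {
  stopifnot(inherits(params, "micellization_params"))
  if (any(!is.finite(s0)) || any(s0 < 0)) {
    stop("'s0' must be finite and >= 0", call. = FALSE)
  }
  cmc <- params$cmc
  r <- params$r
  if (r < .R_LINEAR_LIMIT) return(pmin(s0, cmc))
  sigma <- r * cmc
  A <- amplitude(r)
  z <- (s0 - cmc) / (sqrt(2) * sigma)
  # erf(z) - 1 underflows to 0 for z >> 1, giving the plateau [S1] = cmc
  cmc - (A / 2) * (sqrt(2 / pi) * sigma * exp(-z^2) + (s0 - cmc) * (erf(z) - 1))
}

#' Species concentration profile
#'
#' Evaluates the concentration model on a grid: monomer \[S1\], micellized
#' surfactant \[Sm\] = \[S\]0 - \[S1\] and, when an aggregation number is
#' given, the micelle concentration \[M\] = \[Sm\]/n.
#'
#' @param s0_grid ascending grid of total concentrations, >= 0.
#' @param params a [micellization_params] object.
#' @return An object of class `species_profile`: list with `s0`, `s1`, `sm`,
#'   `m` (or `NULL`), `amplitude` and `params`.
#' @examples
#' p <- micellization_params(1, 0.1, n = 100)
#' sp <- species_profile(seq(0, 3, 0.1), p)
#' all.equal(sp$s1 + sp$sm, sp$s0)
#' @export
species_profile <- function(s0_grid, params) {
  stopifnot(inherits(params, "micellization_params"))
  if (is.unsorted(s0_grid, strictly = FALSE)) {
    stop("'s0_grid' must be ascending", call. = FALSE)
  }
  s1 <- monomer_concentration(s0_grid, params)
  sm <- s0_grid - s1
  m <- if (!is.null(params$n)) sm / params$n else NULL
  structure(
    list(s0 = s0_grid, s1 = s1, sm = sm, m = m,
         amplitude = if (params$r < .R_LINEAR_LIMIT) 1 else amplitude(params$r),
         params = params),
    class = "species_profile"
  )
}

#' @export
print.species_profile <- function(x, ...) {
  cat("Species profile:", length(x$s0), "points over [",
      format(min(x$s0)), ",", format(max(x$s0)), "]\n")
  print(x$params)
  invisible(x)
}

#' First derivative of the monomer concentration
#'
#' `d[S1]/d[S]0 = (A/2) (1 - erf((s0 - cmc)/(sqrt(2) sigma)))`, a falling
#' sigmoid centred at the cmc with values in (0, A\].
#'
#' @inheritParams monomer_concentration
#' @return Dimensionless derivative(s).
#' @export
first_derivative <- function(s0, params) {
  stopifnot(inherits(params, "micellization_params"))
  if (any(!is.finite(s0)) || any(s0 < 0)) {
    stop("'s0' must be finite and >= 0", call. = FALSE)
  }
  if (params$r < .R_LINEAR_LIMIT) return(as.numeric(s0 < params$cmc))
  sigma <- params$r * params$cmc
  (amplitude(params$r) / 2) * (1 - erf((s0 - params$cmc) / (sqrt(2) * sigma)))
}

#' Second derivative of the monomer concentration
#'
#' The Gaussian `-(A/(sqrt(2 pi) sigma)) exp(-(s0 - cmc)^2/(2 sigma^2))`,
#' negative by the sign convention of the curvature of \[S1\]; its magnitude
#' peaks at the cmc.
#'
#' @inheritParams monomer_concentration
#' @return Derivative(s) with unit 1/concentration.
#' @export
second_derivative <- function(s0, params) {
  stopifnot(inherits(params, "micellization_params"))
  if (any(!is.finite(s0)) || any(s0 < 0)) {
    stop("'s0' must be finite and >= 0", call. = FALSE)
  }
  sigma <- params$r * params$cmc
  -(amplitude(params$r) / (sqrt(2 * pi) * sigma)) *
    exp(-(s0 - params$cmc)^2 / (2 * sigma^2))
}

#' Derivative profile of the concentration model
#'
#' First and second derivatives of \[S1\] with respect to \[S\]0 on a grid,
#' together with the differential degree of micellization
#' `gamma = 1 - d[S1]/d[S]0`.
#'
#' @inheritParams species_profile
#' @return List of class `derivative_profile` with `s0`, `first`, `second`,
#'   `gamma`.
#' @export
derivative_profile <- function(s0_grid, params) {
  if (is.unsorted(s0_grid)) stop("'s0_grid' must be ascending", call. = FALSE)
  first <- first_derivative(s0_grid, params)
  structure(
    list(s0 = s0_grid, first = first,
         second = second_derivative(s0_grid, params), gamma = 1 - first),
    class = "derivative_profile"
  )
}

#' Degree of micellization
#'
#' Differential form `gamma = d[Sm]/d[S]0 = 1 - d[S1]/d[S]0`, or fractional
#' form `alpha_m = [Sm]/[S]0`. At the cmc the fractional degree is
#' `(A/2) sqrt(2/pi) r`, about 0.4*r: for a typical r = 0.1 only ~4% of the
#' surfactant is micellized at the cmc.
#'
#' @inheritParams monomer_concentration
#' @param mode `"differential"` or `"fractional"`.
#' @return Dimensionless degree(s) of micellization.
#' @examples
#' p <- micellization_params(1, 0.1)
#' degree_of_micellization(1, p, "fractional") # ~ 0.04
#' @export
degree_of_micellization <- function(s0, params,
                                    mode = c("differential", "fractional")) {
  mode <- match.arg(mode)
  if (mode == "differential") {
    1 - first_derivative(s0, params)
  } else {
    if (any(s0 <= 0)) {
      stop("fractional degree of micellization requires s0 > 0", call. = FALSE)
    }
    1 - monomer_concentration(s0, params) / s0
  }
}
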