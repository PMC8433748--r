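# Seeded generators of synthetic titration curves with the statistical
# structure the fitting layer assumes: the forward model plus independent
# Gaussian noise, homoscedastic (absolute) or proportional (relative).

# run fn with a private RNG state so generators never disturb the caller's
.with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Noise specification
#'
#' Gaussian measurement noise, independent across points: `"absolute"` adds
#' `N(0, sd^2)`; `"relative"` adds `N(0, (sd*|y|)^2)` (heteroscedastic).
#' Identical seeds give identical curves.
#'
#' @param mode `"absolute"` or `"relative"`.
#' @param sd positive noise magnitude (property units, or a fraction of the
#'   signal in relative mode).
#' @param seed integer seed.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(mode = c("absolute", "relative"), sd, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(sd), length(sd) == 1L, is.finite(sd))
  if (sd <= 0) stop("'sd' must be > 0", call. = FALSE)
  structure(list(mode = mode, sd = sd, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Simulate a titration curve
#'
#' Evaluates a forward model on a linear or logarithmic concentration grid
#' and optionally adds seeded Gaussian noise; the nominal noise level is
#' stored as the curve's `y_err`. Conductivity-type titrations typically use
#' linear grids; fluorescence titrations logarithmic ones.
#'
#' @param kind one of [model_kinds()].
#' @param params named numeric vector of model parameters (see
#'   [model_parameters()]).
#' @param grid list with `type` ("linear" or "log"), `min`, `max`, `n >= 4`.
#' @param noise a [noise_spec], or `NULL` for a noiseless curve.
#' @param meta metadata list passed to [titration_curve()].
#' @return A [titration_curve].
#' @examples
#' simulate_curve("conductivity",
#'   c(cmc = 8.099, r = 0.112, a = 66.74, b = 26.43, kappa_s = 0),
#'   grid = list(type = "linear", min = 0.1, max = 16.2, n = 30),
#'   noise = noise_spec("relative", 0.005, seed = 7))
#' @export
simulate_curve <- function(kind, params, grid, noise = NULL, meta = list()) {
  stopifnot(is.list(grid), !is.null(grid$min), !is.null(grid$max),
            !is.null(grid$n))
  type <- if (is.null(grid$type)) "linear" else
    match.arg(grid$type, c("linear", "log"))
  if (grid$n < 4L) stop("grid needs at least 4 points", call. = FALSE)
  if (grid$min < 0 || grid$max <= grid$min) {
    stop("invalid grid range", call. = FALSE)
  }
  x <- if (type == "log") {
    if (grid$min <= 0) stop("log grid requires min > 0", call. = FALSE)
    exp(seq(log(grid$min), log(grid$max), length.out = grid$n))
  } else {
    seq(grid$min, grid$max, length.out = grid$n)
  }
  y0 <- forward_model(kind, x, params)
  if (is.null(noise)) {
    return(titration_curve(x, y0, kind = kind, meta = meta))
  }
  stopifnot(inherits(noise, "noise_spec"))
  sds <- if (noise$mode == "absolute") rep(noise$sd, length(x)) else
    noise$sd * abs(y0)
  if (any(sds <= 0)) {
    stop("relative noise is undefined where the signal is zero", call. = FALSE)
  }
  y <- .with_seed(noise$seed, function() y0 + stats::rnorm(length(x), 0, sds))
  titration_curve(x, y, kind = kind, y_err = sds, meta = meta)
}

#' Subsample a titration curve
#'
#' `"endpoints_spread"` keeps the first and last point and spreads the rest
#' approximately evenly along the index range; `"random"` draws a seeded
#' random subset. The kept indices are recorded in the `"indices"` attribute.
#'
#' @param curve a [titration_curve].
#' @param k number of points to keep, 4 <= k <= n.
#' @param strategy `"endpoints_spread"` or `"random"`.
#' @param seed seed for the random strategy.
#' @return A [titration_curve] of `k` points.
#' @export
subsample <- function(curve, k, strategy = c("endpoints_spread", "random"),
                      seed = NULL) {
  stopifnot(inherits(curve, "titration_curve"))
  strategy <- match.arg(strategy)
  n <- length(curve$x)
  if (k > n) stop("'k' exceeds the number of points", call. = FALSE)
  if (k < 4L) stop("'k' must be at least 4", call. = FALSE)
  idx <- if (strategy == "endpoints_spread") {
    unique(round(seq(1L, n, length.out = k)))
  } else {
    .with_seed(seed, function() sort(sample.int(n, k)))
  }
  out <- titration_curve(curve$x[idx], curve$y[idx], kind = curve$kind,
                         y_err = curve$y_err[idx], meta = curve$meta)
  attr(out, "indices") <- idx
  out
}

#' Simulate a conductivity temperature series
#'
#' One conductivity curve per temperature, emulating a titration series of a
#' surface-active compound: cmc(T) follows a second-order polynomial, the
#' relative transition width r is temperature independent, and the limiting
#' slopes a(T) and b(T) are linear in temperature (a falling, b rising is the
#' typical pattern, so the ratio b/a grows with T).
#'
#' @param temperatures strictly increasing temperature values (K).
#' @param cmc_poly coefficients `c(c0, c1, c2)` of cmc(T) = c0 + c1*T + c2*T^2.
#' @param r common relative transition width.
#' @param a_lin,b_lin coefficients `c(intercept, slope)` of a(T) and b(T).
#' @param kappa_s residual solvent conductivity.
#' @param grid grid specification as in [simulate_curve()].
#' @param noise a [noise_spec] or `NULL`; the seed is advanced by one per
#'   curve so replicate curves are independent but reproducible.
#' @return List of [titration_curve] objects with `meta$temperature` set.
#' @export
simulate_temperature_series <- function(temperatures, cmc_poly, r,
                                        a_lin, b_lin, kappa_s = 0,
                                        grid, noise = NULL) {
  if (is.unsorted(temperatures, strictly = TRUE)) {
    stop("'temperatures' must be strictly increasing", call. = FALSE)
  }
  stopifnot(length(cmc_poly) == 3L, length(a_lin) == 2L, length(b_lin) == 2L)
  lapply(seq_along(temperatures), function(i) {
    tt <- temperatures[i]
    cmc_t <- cmc_poly[1] + cmc_poly[2] * tt + cmc_poly[3] * tt^2
    if (cmc_t <= 0) stop("cmc(T) must stay positive", call. = FALSE)
    p <- c(cmc = cmc_t, r = r, a = a_lin[1] + a_lin[2] * tt,
           b = b_lin[1] + b_lin[2] * tt, kappa_s = kappa_s)
    ns <- noise
    if (!is.null(ns)) ns$seed <- ns$seed + i - 1L
    simulate_curve("conductivity", p, grid, noise = ns,
                   meta = list(temperature = tt))
  })
}
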