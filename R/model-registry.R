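# Flat parameter-vector forward models used by the fitting and simulation
# layers. Each model kind maps a named numeric vector to predicted property
# values; the typed constructors in property-models.R are the user-facing
# mirror. Binding constants are the composite per-micellized-surfactant form
# (K/n), keeping (K, n) out of a jointly unidentifiable fit.

.mic <- function(p) micellization_params(cmc = p[["cmc"]], r = p[["r"]])

.model_registry <- list(
  conductivity = list(
    pnames = c("cmc", "r", "a", "b", "kappa_s"),
    positive = c("cmc", "r"),
    forward = function(x, p) {
      s1 <- monomer_concentration(x, .mic(p))
      p[["a"]] * s1 + p[["b"]] * (x - s1) + p[["kappa_s"]]
    }
  ),
  molar_conductivity = list(
    pnames = c("cmc", "r", "a", "b"),
    positive = c("cmc", "r"),
    forward = function(x, p) {
      if (any(x <= 0)) stop("molar conductivity requires x > 0", call. = FALSE)
      s1 <- monomer_concentration(x, .mic(p))
      p[["a"]] * s1 / x + p[["b"]] * (x - s1) / x
    }
  ),
  carpena = list(
    pnames = c("cmc", "delta", "a", "b", "kappa_s"),
    positive = c("cmc", "delta"),
    forward = function(x, p) {
      p[["kappa_s"]] + p[["a"]] * x + p[["delta"]] * (p[["b"]] - p[["a"]]) *
        (.log1pexp((x - p[["cmc"]]) / p[["delta"]]) -
           .log1pexp(-p[["cmc"]] / p[["delta"]]))
    }
  ),
  surface_tension = list(
    pnames = c("cmc", "r", "gamma0", "st_coeff", "k_ad"),
    positive = c("cmc", "r", "st_coeff", "k_ad"),
    forward = function(x, p) {
      s1 <- monomer_concentration(x, .mic(p))
      p[["gamma0"]] - p[["st_coeff"]] * log(1 + p[["k_ad"]] * s1)
    }
  ),
  nmr = list(
    pnames = c("cmc", "r", "delta_free", "delta_mic"),
    positive = c("cmc", "r"),
    forward = function(x, p) {
      if (any(x <= 0)) stop("NMR shift requires x > 0", call. = FALSE)
      s1 <- monomer_concentration(x, .mic(p))
      (p[["delta_free"]] - p[["delta_mic"]]) * s1 / x + p[["delta_mic"]]
    }
  ),
  fluorescence = list(
    pnames = c("cmc", "r", "k", "f_free", "f_bound"),
    positive = c("cmc", "r", "k"),
    forward = function(x, p) {
      km <- p[["k"]] * (x - monomer_concentration(x, .mic(p)))
      (p[["f_free"]] + p[["f_bound"]] * km) / (1 + km)
    }
  ),
  pyrene_ratio = list(
    pnames = c("cmc", "r", "c", "sr_free", "sr_bound"),
    positive = c("cmc", "r", "c"),
    forward = function(x, p) {
      cm <- p[["c"]] * (x - monomer_concentration(x, .mic(p)))
      (p[["sr_free"]] + p[["sr_bound"]] * cm) / (1 + cm)
    }
  ),
  absorbance = list(
    pnames = c("cmc", "r", "eps_free", "eps_mic", "path"),
    positive = c("cmc", "r", "path"),
    default_fixed = "path",
    forward = function(x, p) {
      s1 <- monomer_concentration(x, .mic(p))
      (s1 * p[["eps_free"]] + (x - s1) * p[["eps_mic"]]) * p[["path"]]
    }
  ),
  absorbance_ratio = list(
    pnames = c("cmc", "r", "q1", "qm", "qa"),
    positive = c("cmc", "r", "qa"),
    forward = function(x, p) {
      if (any(x <= 0)) stop("absorbance ratio requires x > 0", call. = FALSE)
      s1 <- monomer_concentration(x, .mic(p))
      sm <- x - s1
      (s1 * p[["q1"]] + sm * p[["qm"]] * p[["qa"]]) / (s1 + sm * p[["qa"]])
    }
  ),
  fcs_diffusion = list(
    pnames = c("cmc", "r", "k", "d_free", "d_bound"),
    positive = c("cmc", "r", "k"),
    forward = function(x, p) {
      km <- p[["k"]] * (x - monomer_concentration(x, .mic(p)))
      (p[["d_free"]] + p[["d_bound"]] * km) / (1 + km)
    }
  ),
  aggregation = list(
    pnames = c("cac", "r"),
    positive = c("cac", "r"),
    forward = function(x, p) {
      if (any(x <= 0)) stop("aggregated fraction requires x > 0", call. = FALSE)
      1 - monomer_concentration(x, micellization_params(p[["cac"]], p[["r"]])) / x
    }
  ),
  # generic empirical sigmoid, used only as a comparison estimator: its
  # midpoint x0 is NOT the cmc of the concentration model
  boltzmann = list(
    pnames = c("x0", "dx", "a1", "a2"),
    positive = c("x0", "dx"),
    forward = function(x, p) {
      p[["a2"]] + (p[["a1"]] - p[["a2"]]) / (1 + exp((x - p[["x0"]]) / p[["dx"]]))
    }
  )
)

#' Model kinds available for fitting
#'
#' All [curve_kinds()] plus `"carpena"`, the integrated Boltzmann-sigmoid
#' conductivity model.
#'
#' @return Character vector of model-kind names.
#' @export
model_kinds <- function() names(.model_registry)

.get_model <- function(kind) {
  m <- .model_registry[[kind]]
  if (is.null(m)) {
    stop("unknown model kind '", kind, "'; see model_kinds()", call. = FALSE)
  }
  m
}

#' Evaluate a forward model from a flat parameter vector
#'
#' Evaluates the property model of the given kind at concentrations `x` with
#' parameters supplied as a named numeric vector (the parameterization used
#' by [fit_curve()] and [simulate_curve()]; see [model_parameters()]).
#'
#' @param kind one of [model_kinds()].
#' @param x concentration vector.
#' @param params named numeric vector covering the model's parameters.
#' @return Predicted property values.
#' @examples
#' forward_model("conductivity", c(1, 5, 10),
#'               c(cmc = 8.1, r = 0.11, a = 66.7, b = 26.4, kappa_s = 0))
#' @export
forward_model <- function(kind, x, params) {
  m <- .get_model(kind)
  missing <- setdiff(m$pnames, names(params))
  if (length(missing)) {
    stop("missing parameter(s) for '", kind, "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m$forward(x, params)
}

#' Parameter names of a model kind
#'
#' @param kind one of [model_kinds()].
#' @return Character vector of the flat parameter names, in canonical order.
#' @export
model_parameters <- function(kind) .get_model(kind)$pnames
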