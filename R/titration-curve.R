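#' Property kinds understood by the package
#'
#' @return Character vector of valid titration-curve kinds.
#' @export
curve_kinds <- function() {
  c("conductivity", "molar_conductivity", "surface_tension", "nmr",
    "fluorescence", "pyrene_ratio", "absorbance", "absorbance_ratio",
    "fcs_diffusion", "aggregation")
}

#' Titration curve
#'
#' Container for one property-concentration series: concentrations `x`
#' (ascending), property values `y`, optional per-point uncertainties `y_err`
#' and free-text metadata (label, units, temperature...). Unsorted input is
#' sorted with a warning.
#'
#' @param x concentrations, finite, >= 0, length >= 4.
#' @param y property values, same length as `x`.
#' @param kind one of [curve_kinds()].
#' @param y_err optional positive per-point uncertainties, same length.
#' @param meta named list of metadata.
#' @return Object of class `titration_curve` (a list with `x`, `y`, `y_err`,
#'   `kind`, `meta`).
#' @export
titration_curve <- function(x, y, kind, y_err = NULL, meta = list()) {
  kind <- match.arg(kind, curve_kinds())
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    stop("'x' and 'y' must be numeric vectors of equal length", call. = FALSE)
  }
  if (length(x) < 4L) stop("a titration curve needs >= 4 points", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("'x' and 'y' must be finite", call. = FALSE)
  }
  if (any(x < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (!is.null(y_err)) {
    if (length(y_err) != length(x) || any(!is.finite(y_err)) || any(y_err <= 0)) {
      stop("'y_err' must be positive, finite and match 'x' in length",
           call. = FALSE)
    }
  }
  if (is.unsorted(x)) {
    warning("concentrations were not ascending; curve reordered")
    o <- order(x)
    x <- x[o]; y <- y[o]
    if (!is.null(y_err)) y_err <- y_err[o]
  }
  structure(list(x = x, y = y, y_err = y_err, kind = kind, meta = meta),
            class = "titration_curve")
}

#' @export
print.titration_curve <- function(x, ...) {
  cat("Titration curve (", x$kind, "): ", length(x$x), " points over [",
      format(min(x$x)), ", ", format(max(x$x)), "]",
      if (!is.null(x$y_err)) ", with uncertainties" else "", "\n", sep = "")
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.titration_curve <- function(x, ...) {
  d <- data.frame(concentration = x$x, value = x$y)
  if (!is.null(x$y_err)) d$error <- x$y_err
  d
}

#' Parameter specification for fitting
#'
#' Describes one model parameter for [fit_curve()] / [global_fit()]: initial
#' value, optional box bounds, whether it is held fixed, and an optional
#' share-group label for global fits (all parameters carrying the same
#' `share_group` across curves occupy a single free slot).
#'
#' @param name parameter name (must match the model's parameter set).
#' @param init initial value (within bounds).
#' @param lower,upper box bounds (default unbounded).
#' @param fixed if `TRUE` the parameter is held at `init`.
#' @param share_group optional identifier for global-fit sharing.
#' @return Object of class `param_spec`.
#' @export
param_spec <- function(name, init, lower = -Inf, upper = Inf, fixed = FALSE,
                       share_group = NULL) {
  stopifnot(is.character(name), length(name) == 1L, is.numeric(init),
            length(init) == 1L, is.finite(init))
  if (init < lower || init > upper) {
    stop("initial value of '", name, "' outside its bounds", call. = FALSE)
  }
  structure(list(name = name, init = init, lower = lower, upper = upper,
                 fixed = isTRUE(fixed), share_group = share_group),
            class = "param_spec")
}
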