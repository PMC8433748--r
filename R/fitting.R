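# Nonlinear least-squares core. Damped (Levenberg-Marquardt) minimization via
# minpack.lm::nls.lm; positivity of critical concentrations, widths and
# equilibrium constants is enforced by fitting them on the log scale, with
# delta-method back-transformed standard errors.
#
# Error convention: unweighted fits scale the covariance by the reduced
# chi-squared (the convention behind typical published +- values); weighted
# fits (weights 1/y_err^2) report it unscaled.

.LM_CONTROL <- function() {
  minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10, gtol = 1e-8,
                             maxiter = 500)
}

# transform table for one model kind: log scale for positive-by-contract
# parameters, identity otherwise
.transforms <- function(model) {
  tr <- rep("identity", length(model$pnames))
  names(tr) <- model$pnames
  tr[model$positive] <- "log"
  tr
}

.to_internal <- function(value, tr) if (tr == "log") log(value) else value
.from_internal <- function(theta, tr) if (tr == "log") exp(theta) else theta
# d(natural)/d(internal), for delta-method SEs
.jac_internal <- function(value, tr) if (tr == "log") value else 1

# central-difference Jacobian of the residual vector
.num_jacobian <- function(fn, theta) {
  r0 <- fn(theta)
  J <- matrix(NA_real_, length(r0), length(theta))
  for (j in seq_along(theta)) {
    h <- 1e-6 * max(abs(theta[j]), 1)
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    J[, j] <- (fn(tp) - fn(tm)) / (2 * h)
  }
  J
}

# Core least-squares driver over a list of residual "blocks".
# slots: data.frame with columns name, init, lower, upper, transform.
# resid_fn(par_natural_named_list_per_block) -> concatenated residual vector,
# built by the callers; here we only see theta -> residuals.
.lm_core <- function(resid_fn, slots, weighted, n_points) {
  theta0 <- mapply(.to_internal, slots$init, slots$transform)
  lower <- mapply(.to_internal, slots$lower, slots$transform)
  upper <- mapply(.to_internal, slots$upper, slots$transform)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = theta0, fn = resid_fn, lower = lower,
                       upper = upper, control = .LM_CONTROL()),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(list(converged = FALSE, message = conditionMessage(fit),
                theta = theta0, values = NULL, cov_theta = NULL,
                red_chi2 = NA_real_, residuals = NULL))
  }
  theta <- fit$par
  res <- resid_fn(theta)
  n_free <- length(theta)
  dof <- max(n_points - n_free, 1L)
  ssr <- sum(res^2)
  red_chi2 <- ssr / dof
  converged <- fit$info %in% c(1L, 2L, 3L, 4L)
  message <- fit$message
  J <- .num_jacobian(resid_fn, theta)
  jtj <- crossprod(J)
  cov_theta <- tryCatch(solve(jtj), error = function(e) NULL)
  if (is.null(cov_theta)) {
    message <- paste(message,
                     "| singular normal matrix: standard errors unavailable")
  } else if (!weighted) {
    cov_theta <- cov_theta * red_chi2
  }
  list(converged = converged, message = message, theta = theta,
       cov_theta = cov_theta, red_chi2 = red_chi2, residuals = res)
}

# validate/normalize a spec list against a model; returns data.frame
.specs_table <- function(specs, model) {
  if (!is.list(specs) || !all(vapply(specs, inherits, TRUE, "param_spec"))) {
    stop("'specs' must be a list of param_spec objects", call. = FALSE)
  }
  nm <- vapply(specs, `[[`, "", "name")
  if (!setequal(nm, model$pnames) || anyDuplicated(nm)) {
    stop("specs must cover exactly the parameters: ",
         paste(model$pnames, collapse = ", "), call. = FALSE)
  }
  specs <- specs[match(model$pnames, nm)]
  tr <- .transforms(model)
  data.frame(
    name = model$pnames,
    init = vapply(specs, `[[`, 0, "init"),
    lower = vapply(specs, `[[`, 0, "lower"),
    upper = vapply(specs, `[[`, 0, "upper"),
    fixed = vapply(specs, `[[`, TRUE, "fixed"),
    share_group = vapply(specs, function(s)
      if (is.null(s$share_group)) NA_character_ else s$share_group, ""),
    transform = unname(tr[model$pnames]),
    stringsAsFactors = FALSE
  )
}

.check_positive_inits <- function(tab) {
  bad <- tab$name[tab$transform == "log" & tab$init <= 0]
  if (length(bad)) {
    stop("parameter(s) ", paste(bad, collapse = ", "),
         " must have positive initial values", call. = FALSE)
  }
  tab$lower[tab$transform == "log" & tab$lower <= 0] <- 1e-300
  tab
}

.boundary_warnings <- function(estimates, tab) {
  w <- character()
  for (i in seq_len(nrow(tab))) {
    if (tab$fixed[i]) next
    est <- estimates[[tab$name[i]]]
    for (b in c(tab$lower[i], tab$upper[i])) {
      if (is.finite(b) && b != 0 && abs(est - b) < 0.01 * abs(b)) {
        w <- c(w, paste0("estimate of '", tab$name[i],
                         "' within 1% of its bound ", format(b)))
      }
    }
  }
  if (!is.null(estimates[["r"]]) && estimates[["r"]] > 1) {
    w <- c(w, "fitted relative transition width r > 1")
  }
  w
}

#' Fit a property model to a titration curve
#'
#' Weighted damped least squares of the selected forward model. Weights are
#' `1/y_err^2` when the curve carries uncertainties, else unit weights.
#' Critical concentrations, transition widths and equilibrium constants are
#' fitted on the log scale (back-transformed estimates and delta-method
#' standard errors are reported). Unweighted fits scale the covariance by the
#' reduced chi-squared; weighted fits do not.
#'
#' @param curve a [titration_curve].
#' @param specs list of [param_spec]; defaults to [initial_guess()].
#' @param model_kind model to fit (default: the curve's kind). Use
#'   `"carpena"` to fit the integrated Boltzmann model to conductivity data.
#' @param mask optional concentration range `c(lo, hi)`; only points inside
#'   are fitted.
#' @return Object of class `cmc_fit`: list with `estimates` (all parameters),
#'   `std_errors` (`NA` for fixed parameters), `covariance` (free parameters,
#'   natural scale), `red_chi2`, `residuals`, `fitted`, `n_points`, `n_free`,
#'   `converged`, `message`, `warnings`, `weighted`, `kind`, `specs`, `curve`.
#' @examples
#' crv <- simulate_curve("conductivity",
#'   c(cmc = 8.1, r = 0.11, a = 66.7, b = 26.4, kappa_s = 0),
#'   grid = list(type = "linear", min = 0.5, max = 16, n = 40))
#' fit <- fit_curve(crv)
#' fit$estimates["cmc"]
#' @export
fit_curve <- function(curve, specs = NULL, model_kind = NULL, mask = NULL) {
  stopifnot(inherits(curve, "titration_curve"))
  kind <- if (is.null(model_kind)) curve$kind else model_kind
  model <- .get_model(kind)
  if (is.null(specs)) specs <- initial_guess(curve, model_kind = kind)
  tab <- .check_positive_inits(.specs_table(specs, model))

  x <- curve$x; y <- curve$y; y_err <- curve$y_err
  if (!is.null(mask)) {
    stopifnot(length(mask) == 2L, mask[1] < mask[2])
    keep <- x >= mask[1] & x <= mask[2]
    if (sum(keep) < 4L) stop("mask leaves fewer than 4 points", call. = FALSE)
    x <- x[keep]; y <- y[keep]
    if (!is.null(y_err)) y_err <- y_err[keep]
  }
  weighted <- !is.null(y_err)
  sw <- if (weighted) 1 / y_err else rep(1, length(x))

  free <- !tab$fixed
  if (!any(free)) stop("no free parameters to fit", call. = FALSE)
  full <- tab$init
  names(full) <- tab$name
  resid_fn <- function(theta) {
    p <- full
    p[free] <- mapply(.from_internal, theta, tab$transform[free])
    sw * (y - model$forward(x, p))
  }
  core <- .lm_core(resid_fn, tab[free, ], weighted, length(x))

  estimates <- full
  if (!is.null(core$theta)) {
    estimates[free] <- mapply(.from_internal, core$theta, tab$transform[free])
  }
  std_errors <- rep(NA_real_, nrow(tab))
  names(std_errors) <- tab$name
  covariance <- NULL
  if (!is.null(core$cov_theta)) {
    d <- mapply(.jac_internal, estimates[free], tab$transform[free])
    covariance <- diag(d, nrow = length(d)) %*% core$cov_theta %*%
      diag(d, nrow = length(d))
    dimnames(covariance) <- list(tab$name[free], tab$name[free])
    std_errors[free] <- sqrt(pmax(diag(covariance), 0))
  }
  warnings <- .boundary_warnings(as.list(estimates), tab)
  structure(list(
    estimates = estimates, std_errors = std_errors, covariance = covariance,
    red_chi2 = core$red_chi2,
    residuals = if (is.null(core$residuals)) NULL else core$residuals / sw,
    fitted = model$forward(x, estimates),
    n_points = length(x), n_free = sum(free),
    converged = core$converged, message = core$message, warnings = warnings,
    weighted = weighted, kind = kind, specs = tab, curve = curve
  ), class = "cmc_fit")
}

#' @export
print.cmc_fit <- function(x, ...) {
  cat("Model fit (", x$kind, "), ", x$n_points, " points, ", x$n_free,
      " free parameters\n", sep = "")
  cat(if (x$converged) "converged" else "NOT CONVERGED", "-", x$message, "\n")
  est <- x$estimates
  se <- x$std_errors
  for (nm in names(est)) {
    cat(sprintf("  %-12s %#.6g", nm, est[[nm]]))
    if (is.na(se[[nm]])) cat("  (fixed)") else cat(" +-", format(se[[nm]], digits = 3))
    cat("\n")
  }
  cat("  reduced chi^2:", format(x$red_chi2, digits = 4),
      if (x$weighted) "(weighted)" else "(unweighted)", "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Global fit with shared parameters
#'
#' Fits one model per curve as a single joint least-squares problem in which
#' parameters carrying the same share group across curves occupy a single
#' free slot. Sharing pools the information of all curves into one estimate
#' (e.g. a temperature-independent relative transition width across a
#' conductivity temperature series).
#'
#' @param curves list of [titration_curve] objects.
#' @param specs_list list of spec lists, one per curve; defaults to
#'   [initial_guess()] per curve.
#' @param share character vector of parameter names to share across all
#'   curves (shorthand for setting `share_group = name` everywhere).
#' @return Object of class `cmc_global_fit`: `shared` (data.frame of shared
#'   estimates and standard errors), `per_curve` (list of per-curve views with
#'   estimates, standard errors and residuals), `red_chi2` (over all points
#'   and free slots), `converged`, `message`, `n_points`, `n_free`.
#' @export
global_fit <- function(curves, specs_list = NULL, share = NULL) {
  stopifnot(is.list(curves), length(curves) >= 1L,
            all(vapply(curves, inherits, TRUE, "titration_curve")))
  nc <- length(curves)
  if (is.null(specs_list)) specs_list <- lapply(curves, initial_guess)
  stopifnot(length(specs_list) == nc)

  models <- lapply(curves, function(cv) .get_model(cv$kind))
  tabs <- vector("list", nc)
  for (i in seq_len(nc)) {
    tab <- .check_positive_inits(.specs_table(specs_list[[i]], models[[i]]))
    if (!is.null(share)) {
      tab$share_group[tab$name %in% share & !tab$fixed] <-
        tab$name[tab$name %in% share & !tab$fixed]
    }
    tab$curve <- i
    tabs[[i]] <- tab
  }
  all_tab <- do.call(rbind, tabs)

  # validate share groups: same parameter name, never fixed
  for (g in unique(stats::na.omit(all_tab$share_group))) {
    rows <- all_tab[!is.na(all_tab$share_group) & all_tab$share_group == g, ]
    if (length(unique(rows$name)) != 1L) {
      stop("share group '", g, "' mixes parameter names: ",
           paste(unique(rows$name), collapse = ", "), call. = FALSE)
    }
    if (any(rows$fixed)) {
      stop("share group '", g, "' contains a fixed parameter", call. = FALSE)
    }
  }

  # slot table: one row per free slot (shared groups collapse to one)
  free_tab <- all_tab[!all_tab$fixed, ]
  shared_mask <- !is.na(free_tab$share_group)
  shared_groups <- unique(free_tab$share_group[shared_mask])
  slot_rows <- rbind(
    free_tab[!shared_mask, ],
    do.call(rbind, lapply(shared_groups, function(g) {
      rows <- free_tab[shared_mask & free_tab$share_group == g, ]
      rows$init[1] <- mean(rows$init)
      rows[1, ]
    }))
  )
  n_slots <- nrow(slot_rows)

  # map (curve, name) -> slot index
  slot_of <- function(i, nm) {
    row <- all_tab[all_tab$curve == i & all_tab$name == nm, ]
    if (row$fixed) return(NA_integer_)
    if (!is.na(row$share_group)) {
      which(!is.na(slot_rows$share_group) &
              slot_rows$share_group == row$share_group)
    } else {
      which(slot_rows$curve == i & slot_rows$name == nm &
              is.na(slot_rows$share_group))
    }
  }
  maps <- lapply(seq_len(nc), function(i) {
    vapply(tabs[[i]]$name, function(nm) slot_of(i, nm), 1L)
  })

  weighted <- all(vapply(curves, function(cv) !is.null(cv$y_err), TRUE))
  sw_list <- lapply(curves, function(cv) {
    if (weighted) 1 / cv$y_err else rep(1, length(cv$x))
  })
  n_total <- sum(vapply(curves, function(cv) length(cv$x), 1L))

  resid_fn <- function(theta) {
    p_nat <- mapply(.from_internal, theta, slot_rows$transform)
    unlist(lapply(seq_len(nc), function(i) {
      p <- tabs[[i]]$init
      names(p) <- tabs[[i]]$name
      hit <- !is.na(maps[[i]])
      p[hit] <- p_nat[maps[[i]][hit]]
      sw_list[[i]] * (curves[[i]]$y - models[[i]]$forward(curves[[i]]$x, p))
    }), use.names = FALSE)
  }
  core <- .lm_core(resid_fn, slot_rows, weighted, n_total)

  p_nat <- mapply(.from_internal, core$theta, slot_rows$transform)
  se_nat <- rep(NA_real_, n_slots)
  if (!is.null(core$cov_theta)) {
    d <- mapply(.jac_internal, p_nat, slot_rows$transform)
    se_nat <- sqrt(pmax(diag(core$cov_theta), 0)) * abs(d)
  }

  offsets <- cumsum(c(0, vapply(curves, function(cv) length(cv$x), 1L)))
  per_curve <- lapply(seq_len(nc), function(i) {
    p <- tabs[[i]]$init
    names(p) <- tabs[[i]]$name
    se <- rep(NA_real_, length(p))
    names(se) <- names(p)
    hit <- !is.na(maps[[i]])
    p[hit] <- p_nat[maps[[i]][hit]]
    se[hit] <- se_nat[maps[[i]][hit]]
    idx <- (offsets[i] + 1):offsets[i + 1]
    res <- if (is.null(core$residuals)) NULL else
      core$residuals[idx] / sw_list[[i]]
    list(estimates = p, std_errors = se, residuals = res,
         kind = curves[[i]]$kind, meta = curves[[i]]$meta)
  })

  shared <- data.frame(group = character(), name = character(),
                       estimate = numeric(), std_error = numeric(),
                       stringsAsFactors = FALSE)
  for (g in shared_groups) {
    j <- which(!is.na(slot_rows$share_group) & slot_rows$share_group == g)
    shared <- rbind(shared, data.frame(group = g, name = slot_rows$name[j],
                                       estimate = p_nat[j],
                                       std_error = se_nat[j]))
  }

  structure(list(
    shared = shared, per_curve = per_curve, red_chi2 = core$red_chi2,
    converged = core$converged, message = core$message,
    n_points = n_total, n_free = n_slots, weighted = weighted
  ), class = "cmc_global_fit")
}

#' @export
print.cmc_global_fit <- function(x, ...) {
  cat("Global fit:", length(x$per_curve), "curves,", x$n_points, "points,",
      x$n_free, "free slots\n")
  cat(if (x$converged) "converged" else "NOT CONVERGED", "-", x$message, "\n")
  if (nrow(x$shared)) {
    cat("shared parameters:\n")
    for (i in seq_len(nrow(x$shared))) {
      cat(sprintf("  %-12s %#.6g +- %s\n", x$shared$name[i],
                  x$shared$estimate[i], format(x$shared$std_error[i],
                                               digits = 3)))
    }
  }
  cat("  total reduced chi^2:", format(x$red_chi2, digits = 4), "\n")
  invisible(x)
}
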