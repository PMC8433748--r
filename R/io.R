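# Curve files are plain CSV ('.' decimals, ',' delimiter) with a header row
# "concentration,value[,error]" and optional '# key: value' metadata comments.
# Fit reports are JSON at full precision so a reload reproduces the numbers
# bit-exactly.

#' Write a titration curve to CSV
#'
#' @param curve a [titration_curve].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "titration_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# kind:", curve$kind), con)
  for (nm in names(curve$meta)) {
    writeLines(paste0("# ", nm, ": ", curve$meta[[nm]]), con)
  }
  has_err <- !is.null(curve$y_err)
  writeLines(if (has_err) "concentration,value,error" else
    "concentration,value", con)
  fmt <- function(v) formatC(v, digits = 17, format = "g")
  rows <- if (has_err) {
    paste(fmt(curve$x), fmt(curve$y), fmt(curve$y_err), sep = ",")
  } else {
    paste(fmt(curve$x), fmt(curve$y), sep = ",")
  }
  writeLines(rows, con)
  invisible(path)
}

#' Read a titration curve from CSV
#'
#' Expects columns `concentration,value` and optionally `error`; lines
#' starting with `#` are comments, and `# key: value` comments become
#' metadata (`kind` selects the property kind). Rows are sorted by
#' concentration with a warning if needed.
#'
#' @param path input file path.
#' @param kind property kind; overrides any `# kind:` metadata.
#' @return A [titration_curve].
#' @export
read_curve <- function(path, kind = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*([^:]+):\\s*(.*)$", ml))[[1]]
    if (length(m) == 3L) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) < 2L) stop("no data rows in ", path, call. = FALSE)
  header <- tolower(trimws(strsplit(body[1], ",")[[1]]))
  need <- c("concentration", "value")
  if (!all(need %in% header)) {
    stop("missing column(s): ", paste(setdiff(need, header), collapse = ", "),
         " in ", path, call. = FALSE)
  }
  rows <- body[-1]
  if (length(rows) < 4L) stop("fewer than 4 data rows in ", path, call. = FALSE)
  cells <- strsplit(rows, ",")
  ncol <- length(header)
  vals <- matrix(NA_real_, length(rows), ncol)
  for (i in seq_along(cells)) {
    if (length(cells[[i]]) != ncol) {
      stop("row ", i, " has ", length(cells[[i]]), " fields, expected ", ncol,
           call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(cells[[i]]))
    if (any(is.na(v))) {
      bad <- which(is.na(v))[1]
      stop("non-numeric value '", cells[[i]][bad], "' at data row ", i,
           ", column '", header[bad], "'", call. = FALSE)
    }
    vals[i, ] <- v
  }
  if (is.null(kind)) {
    kind <- meta[["kind"]]
    if (is.null(kind)) {
      stop("property kind not given and no '# kind:' metadata in ", path,
           call. = FALSE)
    }
  }
  meta[["kind"]] <- NULL
  y_err <- if ("error" %in% header) vals[, match("error", header)] else NULL
  titration_curve(vals[, match("concentration", header)],
                  vals[, match("value", header)],
                  kind = kind, y_err = y_err, meta = meta)
}

.fit_report_list <- function(result, seed = NULL) {
  if (inherits(result, "cmc_fit")) {
    list(
      type = "fit",
      kind = result$kind,
      converged = result$converged,
      message = result$message,
      estimates = as.list(result$estimates),
      std_errors = as.list(result$std_errors),
      covariance = result$covariance,
      red_chi2 = result$red_chi2,
      residuals = result$residuals,
      n_points = result$n_points,
      n_free = result$n_free,
      weighted = result$weighted,
      warnings = result$warnings,
      seed = seed,
      version = as.character(utils::packageVersion("cmcfit")),
      summary = paste0(
        "fit of '", result$kind, "' model to ", result$n_points, " points; ",
        if (result$converged) "converged" else "NOT converged",
        "; reduced chi^2 = ", format(result$red_chi2, digits = 6))
    )
  } else if (inherits(result, "cmc_global_fit")) {
    list(
      type = "global_fit",
      converged = result$converged,
      message = result$message,
      shared = result$shared,
      per_curve = lapply(result$per_curve, function(pc) {
        list(kind = pc$kind, estimates = as.list(pc$estimates),
             std_errors = as.list(pc$std_errors), residuals = pc$residuals,
             meta = pc$meta)
      }),
      red_chi2 = result$red_chi2,
      n_points = result$n_points,
      n_free = result$n_free,
      weighted = result$weighted,
      warnings = character(0),
      seed = seed,
      version = as.character(utils::packageVersion("cmcfit")),
      summary = paste0(
        "global fit of ", length(result$per_curve), " curves (",
        result$n_points, " points, ", result$n_free, " free slots); ",
        if (result$converged) "converged" else "NOT converged",
        "; total reduced chi^2 = ", format(result$red_chi2, digits = 6))
    )
  } else {
    stop("'result' must be a cmc_fit or cmc_global_fit", call. = FALSE)
  }
}

#' Write a machine-readable fit report
#'
#' Serializes a [fit_curve()] or [global_fit()] result to JSON at full
#' precision (estimates, standard errors, covariance, reduced chi-squared,
#' residuals, convergence status, warnings, seed and package version), with a
#' one-line human-readable summary embedded.
#'
#' @param result a `cmc_fit` or `cmc_global_fit`.
#' @param path output file path.
#' @param seed seed used to produce the inputs, recorded for reproducibility.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, seed = NULL) {
  rep <- .fit_report_list(result, seed)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a fit report
#'
#' @param path a JSON report written by [write_report()].
#' @return The report as a list; `estimates` and `std_errors` are numeric
#'   vectors.
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(rep$estimates)) rep$estimates <- unlist(rep$estimates)
  if (!is.null(rep$std_errors)) {
    se <- rep$std_errors
    se[vapply(se, is.null, TRUE)] <- NA_real_
    rep$std_errors <- unlist(se)
  }
  rep
}

#' Read a fit configuration
#'
#' YAML document with fields: `property` (model kind), `datasets` (list of
#' CSV paths), `parameters` (map of name to `{init, lower, upper, fixed,
#' share_group}`), optional `mask` (`[lo, hi]`), `seed` and `output`.
#'
#' @param path YAML file path.
#' @return Named list with the configuration.
#' @export
read_fit_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$grid)) {
    # YAML 1.1 reads a bare key 'n' as a boolean; map it (and the alias
    # 'points') back to the grid size
    nm <- names(cfg$grid)
    nm[nm %in% c("FALSE", "no", "points")] <- "n"
    names(cfg$grid) <- nm
  }
  if (!is.null(cfg$datasets)) {
    missing <- cfg$datasets[!file.exists(unlist(cfg$datasets))]
    if (length(missing)) {
      stop("dataset file(s) not found: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  cfg
}

# turn a config 'parameters' block into specs, on top of defaults
.specs_from_config <- function(curve, kind, par_block,
                               fix = NULL, init = NULL) {
  specs <- initial_guess(curve, model_kind = kind)
  names(specs) <- vapply(specs, `[[`, "", "name")
  if (!is.null(par_block)) {
    for (nm in names(par_block)) {
      b <- par_block[[nm]]
      old <- specs[[nm]]
      if (is.null(old)) stop("unknown parameter '", nm, "'", call. = FALSE)
      specs[[nm]] <- param_spec(
        nm,
        init = if (!is.null(b$init)) b$init else old$init,
        lower = if (!is.null(b$lower)) b$lower else old$lower,
        upper = if (!is.null(b$upper)) b$upper else old$upper,
        fixed = isTRUE(b$fixed) || (!is.null(b$fixed) && b$fixed),
        share_group = b$share_group
      )
    }
  }
  for (nm in names(init)) {
    if (is.null(specs[[nm]])) stop("unknown parameter '", nm, "'", call. = FALSE)
    specs[[nm]]$init <- init[[nm]]
  }
  for (nm in names(fix)) {
    if (is.null(specs[[nm]])) stop("unknown parameter '", nm, "'", call. = FALSE)
    specs[[nm]] <- param_spec(nm, fix[[nm]], fixed = TRUE)
  }
  unname(specs)
}
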