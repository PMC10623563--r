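#' Read a scattering, Rayleigh or correlation curve from a text file
#'
#' Reads two- or three-column ASCII/CSV data (abscissa, ordinate, optional
#' uncertainty). Lines starting with \code{#} are comments; whitespace- and
#' comma-separated layouts are auto-detected. Rows are sorted on the
#' abscissa and duplicated abscissa values are merged by averaging, with a
#' warning.
#'
#' @param path file path.
#' @param kind what the columns represent: \code{"saxs"} (q, I[, sigma]),
#'   \code{"mals"} (q, Rayleigh ratio[, sigma]) or \code{"dls"} (tau,
#'   g2-1).
#' @param q_unit unit of the q column for scattering kinds.
#' @param ... extra arguments passed to the container constructor (for
#'   \code{kind = "dls"}: instrument constants of [correlation_trace()]).
#' @return a [scattering_curve()], [rayleigh_curve()] or
#'   [correlation_trace()].
#' @export
read_curve <- function(path, kind = c("saxs", "mals", "dls"),
                       q_unit = NULL, ...) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no data lines in ", path)
  sep <- if (grepl(",", lines[1L])) "," else ""
  df <- tryCatch(
    utils::read.table(text = lines, sep = sep, header = FALSE,
                      colClasses = "numeric"),
    error = function(e) {
      # locate the first non-numeric payload line for the error message
      for (i in seq_along(lines)) {
        ok <- !inherits(tryCatch(scan(text = gsub(",", " ", lines[i]),
                                      quiet = TRUE),
                                 error = function(e) e), "error")
        if (!ok) stop("non-numeric payload at data line ", i, " of ", path,
                      call. = FALSE)
      }
      stop("cannot parse ", path, ": ", conditionMessage(e), call. = FALSE)
    })
  if (ncol(df) < 2L) stop("need at least 2 numeric columns in ", path)
  x <- df[[1L]]; y <- df[[2L]]
  s <- if (ncol(df) >= 3L) df[[3L]] else NULL
  ord <- order(x)
  x <- x[ord]; y <- y[ord]; if (!is.null(s)) s <- s[ord]
  if (anyDuplicated(x)) {
    warning("duplicated abscissa rows in ", basename(path),
            ": merged by averaging")
    y <- as.numeric(tapply(y, x, mean))
    if (!is.null(s)) s <- as.numeric(tapply(s, x, mean))
    x <- sort(unique(x))
  }
  switch(kind,
         saxs = scattering_curve(x, y, sigma = s, technique = "SAXS",
                                 q_unit = if (is.null(q_unit)) "nm^-1"
                                 else q_unit),
         mals = rayleigh_curve(x, pmax(y, 0), sigma = s,
                               q_unit = if (is.null(q_unit)) "um^-1"
                               else q_unit),
         dls = correlation_trace(x, y, ...))
}

#' Write a curve or table to CSV
#'
#' Writes the numeric columns of a curve container (or plain data frame)
#' as comma-separated text with a \code{#}-prefixed header line, the format
#' [read_curve()] accepts.
#'
#' @param x a curve object or data frame.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_curve <- function(x, path) {
  df <- if (inherits(x, "correlation_trace"))
    data.frame(tau = x$tau, g2m1 = x$g2m1)
  else as.data.frame(x)[vapply(as.data.frame(x), is.numeric, logical(1))]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", paste(names(df), collapse = ",")), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

pipeline_known_keys <- list(
  top = c("seed", "stages", "output_dir", "saxs", "mals", "dls", "fusion",
          "loading"),
  saxs = c("input", "q_unit", "fixture", "scale", "noise_scale", "qmin",
           "qmax", "restarts"),
  mals = c("input", "q_unit", "fixture", "amplitude", "noise_scale",
           "thickness", "init_R"),
  dls = c("input", "q", "wavelength", "temperature", "eta", "beta",
          "lambda", "basis", "fixture", "median_R", "sigma_log",
          "noise_scale"),
  fusion = c("window"),
  loading = c("prep", "dl_denominator"))

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML file) with a mandatory
#' \code{seed}, a \code{stages} vector choosing among \code{"saxs"},
#' \code{"mals"}, \code{"dls"}, \code{"fusion"}, \code{"loading"}, and one
#' parameter block per requested stage. Each stage block either names an
#' \code{input} file (with declared \code{q_unit} for scattering stages) or
#' a synthetic \code{fixture} (\code{"lip0"} / \code{"lipcas"}). Unknown
#' keys are rejected.
#'
#' @param config named list or path to a YAML file.
#' @return the validated config, invisibly classed
#'   \code{"pipeline_config"}.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("'config' must be a list or a YAML file path")
  unknown <- setdiff(names(config), pipeline_known_keys$top)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (is.null(config$seed))
    stop("'seed' is mandatory (reproducibility of stochastic stages)")
  config$stages <- as.character(config$stages %||% character())
  bad <- setdiff(config$stages, c("saxs", "mals", "dls", "fusion",
                                  "loading"))
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  for (st in intersect(config$stages, names(pipeline_known_keys))) {
    blk <- config[[st]]
    if (is.null(blk)) next
    unknown <- setdiff(names(blk), pipeline_known_keys[[st]])
    if (length(unknown))
      stop("unknown keys in '", st, "' block: ",
           paste(unknown, collapse = ", "))
    if (!is.null(blk$input) && st %in% c("saxs", "mals") &&
        is.null(blk$q_unit))
      stop("stage '", st, "': file input requires a declared q_unit")
  }
  if ("fusion" %in% config$stages &&
      !all(c("saxs", "mals") %in% config$stages))
    stop("'fusion' requires the 'saxs' and 'mals' stages upstream")
  class(config) <- c("pipeline_config", "list")
  invisible(config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the vesicle characterization pipeline
#'
#' Executes the requested stages in dependency order (SAXS fit, MALS fit,
#' DLS inversion, MALS/SAXS fusion, loading arithmetic) on file inputs or
#' synthetic fixtures, and writes a machine-readable JSON report plus CSV
#' tables. An empty stage list is a no-op success. Identical config and
#' seed produce an identical report.
#'
#' @param config a [pipeline_config()] (list or YAML path accepted).
#' @param output_dir directory for the report files; created if needed.
#'   \code{NULL} (default) writes nothing and only returns the bundle.
#' @return list with one entry per executed stage plus \code{ok} (no
#'   stage failed to converge), invisibly written to
#'   \code{report.json} when \code{output_dir} is given.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- pipeline_config(config)
  seed <- as.integer(cfg$seed)
  report <- list()
  fixture_profile <- function(name)
    switch(name %||% "lip0", lip0 = lip0_profile(),
           lipcas = lipcas_profile(),
           stop("unknown fixture: ", name))
  fixture_shell <- function(name)
    switch(name %||% "lip0", lip0 = lip0_mals_model(),
           lipcas = lipcas_mals_model(),
           stop("unknown fixture: ", name))

  saxs_fit_res <- NULL; saxs_curve <- NULL; mals_fit_res <- NULL

  if ("saxs" %in% cfg$stages) {
    blk <- cfg$saxs %||% list()
    saxs_curve <- if (!is.null(blk$input))
      read_curve(blk$input, "saxs", q_unit = blk$q_unit)
    else {
      ns <- blk$noise_scale %||% 0
      gen_saxs(fixture_profile(blk$fixture), scale = blk$scale %||% 1,
               noise = if (ns > 0)
                 noise_model("gaussian-relative", ns, seed) else
                   noise_model())
    }
    saxs_fit_res <- fit_saxs(saxs_curve, n_restarts = blk$restarts %||% 8,
                             seed = seed,
                             qmin = blk$qmin %||% 0.1,
                             qmax = blk$qmax %||% 5)
    report$saxs <- list(R = saxs_fit_res$params$R, d = saxs_fit_res$params$d,
                        chi2_reduced = saxs_fit_res$chi2_reduced,
                        converged = saxs_fit_res$converged)
  }
  if ("mals" %in% cfg$stages) {
    blk <- cfg$mals %||% list()
    crv <- if (!is.null(blk$input))
      read_curve(blk$input, "mals", q_unit = blk$q_unit)
    else {
      ns <- blk$noise_scale %||% 0
      gen_mals(fixture_shell(blk$fixture),
               amplitude = blk$amplitude %||% 1e-4,
               noise = if (ns > 0)
                 noise_model("gaussian-relative", ns, seed + 1L) else
                   noise_model())
    }
    mals_fit_res <- fit_mals(crv, t_fixed = blk$thickness %||% 4,
                             init_R = blk$init_R %||% 30)
    report$mals <- list(R_mid = mals_fit_res$params$R_mid,
                        Rg = mals_fit_res$params$Rg,
                        converged = mals_fit_res$converged)
  }
  if ("dls" %in% cfg$stages) {
    blk <- cfg$dls %||% list()
    trace <- if (!is.null(blk$input))
      read_curve(blk$input, "dls",
                 q = blk$q %||% 22.3,
                 temperature = blk$temperature %||% 293.15,
                 eta = blk$eta %||% 1.002e-3)
    else {
      ns <- blk$noise_scale %||% 0
      gen_dls(lognormal_sizes(blk$median_R %||% 45,
                              blk$sigma_log %||% 0.15),
              noise = if (ns > 0)
                noise_model("gaussian-absolute", ns, seed + 2L) else
                  noise_model())
    }
    dist <- invert_dls(trace, beta = blk$beta,
                       lambda_reg = blk$lambda %||% "lcurve",
                       basis = blk$basis %||% "mass")
    report$dls <- list(basis = dist$basis,
                       median_R = distribution_median(dist),
                       radii = dist$radii, weights = dist$weights)
  }
  if ("fusion" %in% cfg$stages) {
    if (is.null(saxs_fit_res) || is.null(mals_fit_res))
      stop("fusion stage: missing upstream SAXS/MALS products")
    blk <- cfg$fusion %||% list()
    comp <- sew(mals_fit_res, saxs_curve, saxs_fit_res$profile,
                window = unlist(blk$window %||% c(0.1, 0.3)))
    report$fusion <- list(saxs_scale = attr(comp, "saxs_scale"),
                          n_points = nrow(comp))
    report$.composite <- comp
  }
  if ("loading" %in% cfg$stages) {
    blk <- cfg$loading %||% list()
    prep <- do.call(prep_spec, blk$prep %||% list())
    lr <- loading_percentages(prep,
                              dl_denominator = blk$dl_denominator %||%
                                "lipid")
    report$loading <- unclass(lr)
  }

  conv <- unlist(lapply(report[c("saxs", "mals")],
                        function(x) x$converged))
  report$ok <- length(conv) == 0L || all(conv)

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    comp <- report$.composite
    report$.composite <- NULL
    jsonlite::write_json(report, file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(comp))
      utils::write.csv(comp, file.path(output_dir, "composite.csv"),
                       row.names = FALSE)
    report$.composite <- comp
  }
  report
}
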