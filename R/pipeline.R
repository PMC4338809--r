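#' Run the full microcosm analysis pipeline
#'
#' One reproducible entry point composing every stage: in `"simulate"` mode a
#' synthetic experiment is generated from a [generator_config()]; in
#' `"analyze"` mode the affinity TSV, design JSON, Eh CSV and endpoint CSV
#' written by a previous simulate run (or a lab export in the same formats)
#' are read back. Either way the chain is: niche metrics per consortium ->
#' wavelet-variance stability per microcosm -> endpoint table join ->
#' six-way correlation battery (replicate- and consortium-level) -> cubic
#' CMD-vs-richness trend. Results are returned as a report object and,
#' if `outdir` is given, written as JSON/CSV side tables.
#'
#' @param mode `"simulate"` or `"analyze"`.
#' @param config a [generator_config()] (simulate mode); defaults to
#'   `generator_config(seed = seed)`.
#' @param seed master seed stamped into (and, in simulate mode, driving) the
#'   run.
#' @param affinity,design,eh,endpoints input file paths (analyze mode).
#' @param n_voices,normalization,omega0,squared,center,boundary wavelet
#'   settings, see [treatment_stability()].
#' @param outdir optional output directory (created if needed).
#' @param quiet suppress per-stage log lines.
#' @return an object of class `run_report` (see Details), invisibly written to
#'   `outdir/report.json` when requested.
#' @export
run_microstab <- function(mode = c("simulate", "analyze"),
                          config = NULL, seed = 1L,
                          affinity = NULL, design = NULL, eh = NULL,
                          endpoints = NULL,
                          n_voices = 8L,
                          normalization = c("paper", "conventional"),
                          omega0 = 6, squared = c("modulus", "real"),
                          center = TRUE, boundary = c("zero", "periodic"),
                          outdir = NULL, quiet = FALSE) {
  mode <- match.arg(mode)
  normalization <- match.arg(normalization)
  squared <- match.arg(squared)
  boundary <- match.arg(boundary)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            "microstab_pipeline_error"))
    say("stage %-12s done in %.2f s", name, proc.time()[["elapsed"]] - t0)
    out
  }
  if (mode == "simulate") {
    if (is.null(config)) config <- generator_config(seed = seed)
    stopifnot(inherits(config, "generator_config"))
    exp <- stage("simulate", generate_experiment(config))
    mat <- exp$matrix; dsg <- exp$design; ehs <- exp$eh; ept <- exp$endpoints
  } else {
    for (p in c(affinity, design, eh, endpoints)) {
      if (is.null(p) || !file.exists(p))
        abort("analyze mode needs existing affinity/design/eh/endpoints files",
              "microstab_config_error")
    }
    mat <- stage("affinity", read_affinity(affinity))
    dsg <- stage("design", read_design(design))
    ehs <- stage("eh", read_eh(eh))
    ept <- stage("endpoints", read_endpoints(endpoints))
    config <- NULL
  }
  report <- stage("analyze",
                  analyze_experiment(mat, dsg, ehs, ept, seed = seed,
                                     config = config, n_voices = n_voices,
                                     normalization = normalization,
                                     omega0 = omega0, squared = squared,
                                     center = center, boundary = boundary))
  validate_report(report)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(report), file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = 12, pretty = TRUE)
    write_endpoints(report$endpoints, file.path(outdir, "endpoints.csv"))
    if (mode == "simulate") {
      write_affinity(mat, file.path(outdir, "affinity.tsv"))
      write_design(dsg, file.path(outdir, "design.json"))
      write_eh(ehs, file.path(outdir, "eh.csv"))
      ept_raw <- ept[, setdiff(names(ept), "stability")]
      write_endpoints(ept_raw, file.path(outdir, "endpoints_raw.csv"))
    }
    utils::write.csv(report$variance_curves,
                     file.path(outdir, "variance_curves.csv"),
                     row.names = FALSE)
    say("outputs written to %s", outdir)
  }
  report
}

#' Analyze an assembled experiment (in-memory core of the pipeline)
#'
#' @param matrix pool [affinity_matrix()].
#' @param design [consortium_design].
#' @param eh named list (microcosm id) of lists of [eh_series()].
#' @param endpoints endpoint data.frame (per microcosm).
#' @inheritParams run_microstab
#' @return a `run_report` list.
#' @keywords internal
#' @export
analyze_experiment <- function(matrix, design, eh, endpoints, seed = 1L,
                               config = NULL, n_voices = 8L,
                               normalization = "paper", omega0 = 6,
                               squared = "modulus", center = TRUE,
                               boundary = "zero") {
  labels <- vapply(design$consortia, `[[`, character(1), "label")
  # niche metrics per consortium
  niche <- do.call(rbind, lapply(design$consortia, function(co) {
    nm <- niche_metrics(matrix, co)
    data.frame(consortium = co$label, level = co$level, richness = co$richness,
               cmd = nm$cmd, mean_overlap = nm$mean_pairwise_overlap,
               redundancy = nm$redundancy)
  }))
  # wavelet stability per microcosm (kernels shared across all microcosms)
  mids <- names(eh)
  first <- eh[[1]][[1]]
  wv <- stability_batch(eh, n_voices = n_voices, normalization = normalization,
                        omega0 = omega0, center = center, boundary = boundary,
                        squared = squared)
  stab <- data.frame(
    microcosm_id = mids,
    v_t = vapply(wv, `[[`, numeric(1), "overall"),
    stability = vapply(wv, `[[`, numeric(1), "stability"),
    degenerate = vapply(wv, `[[`, logical(1), "degenerate"))
  ept <- merge(endpoints, stab, by = "microcosm_id", sort = FALSE)
  ept <- ept[order(match(ept$consortium, labels),
                   ept$microcosm_id), , drop = FALSE]
  rownames(ept) <- NULL
  # consortium-level summary; both aggregation orders for the reciprocal
  agg <- stats::aggregate(ept[c("v_t", "stability")],
                          by = list(consortium = ept$consortium), mean)
  names(agg) <- c("consortium", "v_t", "stability_mean_of_reciprocal")
  agg$stability_reciprocal_of_mean <- 1 / agg$v_t
  consortia <- merge(niche, agg, by = "consortium", sort = FALSE)
  consortia <- consortia[match(labels, consortia$consortium), , drop = FALSE]
  rownames(consortia) <- NULL
  # correlation battery at both units of analysis
  corr_rep <- correlation_battery(ept, unit = "replicate")
  corr_con <- correlation_battery(ept, unit = "consortium")
  cubic <- cubic_trend(niche$richness, niche$cmd)
  # probe-mean V(a) curves for plotting/export
  curves <- do.call(rbind, lapply(mids, function(mid) {
    data.frame(microcosm_id = mid,
               scale_s = wv[[mid]]$grid$scales,
               v_t_a = as.numeric(wv[[mid]]$probe_mean))
  }))
  settings <- list(n_voices = as.integer(n_voices),
                   normalization = normalization, omega0 = omega0,
                   squared = squared, centered = center, boundary = boundary,
                   dt = first$dt, n_samples = length(first$values))
  cfg_json <- if (is.null(config)) "" else
    as.character(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA))
  structure(list(
    provenance = list(
      package = "microstab",
      package_version = as.character(utils::packageVersion("microstab")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = as.integer(seed),
      settings = settings,
      config = if (is.null(config)) NULL else unclass(config),
      config_checksum = checksum_string(cfg_json)),
    consortia = consortia,
    endpoints = ept,
    correlations_replicate = corr_rep,
    correlations_consortium = corr_con,
    cmd_cubic = list(coefficients = as.list(cubic$coefficients),
                     rss = cubic$rss),
    variance_curves = curves
  ), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: %d consortia, %d microcosms [%s normalization]\n",
              nrow(x$consortia), nrow(x$endpoints),
              x$provenance$settings$normalization))
  cat("replicate-level correlations:\n")
  print(x$correlations_replicate, row.names = FALSE)
  invisible(x)
}

#' Hash of a report's serialized content
#'
#' Two runs with the same seed and settings produce byte-identical report
#' JSON and therefore equal hashes.
#'
#' @param report a `run_report`.
#' @return character checksum.
#' @export
report_hash <- function(report) {
  checksum_string(as.character(jsonlite::toJSON(unclass(report),
                                                auto_unbox = TRUE,
                                                digits = 12)))
}

# Minimal structural schema check; the bundled JSON schema at
# system.file("extdata", "report_schema.json", package = "microstab")
# mirrors this for external consumers.
report_schema <- function() {
  list(provenance = "list", consortia = "data.frame",
       endpoints = "data.frame", correlations_replicate = "data.frame",
       correlations_consortium = "data.frame", cmd_cubic = "list",
       variance_curves = "data.frame")
}

#' Validate a run report against the bundled schema
#'
#' Checks required top-level fields and their types, required columns of the
#' tabular fields, and internal consistency (each design consortium appears
#' exactly once; six correlations per battery).
#'
#' @param report a `run_report`.
#' @return `TRUE` invisibly; classed error otherwise.
#' @export
validate_report <- function(report) {
  sch <- report_schema()
  for (f in names(sch)) {
    if (is.null(report[[f]]))
      abort(sprintf("report lacks field '%s'", f), "microstab_schema_error")
    ok <- switch(sch[[f]], list = is.list(report[[f]]),
                 data.frame = is.data.frame(report[[f]]))
    if (!ok)
      abort(sprintf("report field '%s' has wrong type", f),
            "microstab_schema_error")
  }
  need_cols <- list(
    consortia = c("consortium", "level", "richness", "cmd", "mean_overlap",
                  "redundancy", "v_t", "stability_mean_of_reciprocal",
                  "stability_reciprocal_of_mean"),
    endpoints = c("microcosm_id", "consortium", "richness", "cmd", "etsa",
                  "doc", "v_t", "stability"),
    correlations_replicate = c("response", "predictor", "r", "p", "n"),
    correlations_consortium = c("response", "predictor", "r", "p", "n"))
  for (f in names(need_cols)) {
    missing <- setdiff(need_cols[[f]], names(report[[f]]))
    if (length(missing) > 0L)
      abort(sprintf("report field '%s' lacks column '%s'", f, missing[1]),
            "microstab_schema_error")
  }
  if (anyDuplicated(report$consortia$consortium))
    abort("duplicate consortium in report", "microstab_schema_error")
  if (nrow(report$correlations_replicate) != 6L ||
      nrow(report$correlations_consortium) != 6L)
    abort("correlation battery must have exactly 6 rows",
          "microstab_schema_error")
  if (length(report$cmd_cubic$coefficients) != 4L)
    abort("cubic trend must have 4 coefficients", "microstab_schema_error")
  invisible(TRUE)
}
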