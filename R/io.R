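# Long-format CSV interchange for Eh traces and endpoint tables. Generated
# data round-trip through these writers/readers bit-for-bit up to decimal
# printing (17 significant digits), so analyze-mode reruns match in-memory
# analyses to numerical precision.

#' Read / write Eh time series as long CSV
#'
#' Columns: `microcosm_id, probe_depth_mm, time_s, eh_mV` (header required).
#' `read_eh` reassembles one [eh_series()] per (microcosm, probe) and rejects
#' irregular sampling.
#'
#' @param path file path.
#' @return `read_eh`: named list (microcosm id) of lists of [eh_series()];
#'   `write_eh` returns `path` invisibly.
#' @export
read_eh <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("microcosm_id", "probe_depth_mm", "time_s", "eh_mV")
  if (!all(need %in% names(df)))
    abort("Eh CSV must have columns microcosm_id, probe_depth_mm, time_s, eh_mV",
          "microstab_format_error")
  out <- list()
  for (mid in unique(df$microcosm_id)) {
    sub <- df[df$microcosm_id == mid, ]
    probes <- sort(unique(sub$probe_depth_mm))
    out[[as.character(mid)]] <- lapply(probes, function(p) {
      sp <- sub[sub$probe_depth_mm == p, ]
      sp <- sp[order(sp$time_s), ]
      eh_series(sp$eh_mV, t = sp$time_s, microcosm_id = as.character(mid),
                probe_depth = p)
    })
  }
  out
}

#' @rdname read_eh
#' @param eh named list of lists of [eh_series()] (as in a
#'   `microcosm_experiment$eh`).
#' @export
write_eh <- function(eh, path) {
  blocks <- lapply(unlist(eh, recursive = FALSE), function(s) {
    data.frame(microcosm_id = s$microcosm_id, probe_depth_mm = s$probe_depth,
               time_s = s$t, eh_mV = s$values)
  })
  df <- do.call(rbind, blocks)
  df$eh_mV <- format(df$eh_mV, digits = 17, trim = TRUE, scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write endpoint tables as CSV
#'
#' Columns: `microcosm_id, consortium, level, richness, cmd, etsa, doc`
#' (plus `stability` once the wavelet stage has been joined).
#'
#' @param path file path.
#' @return `read_endpoints` returns a data.frame; `write_endpoints` returns
#'   `path` invisibly.
#' @export
read_endpoints <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("microcosm_id", "consortium", "level", "richness", "cmd", "etsa", "doc")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    abort(sprintf("endpoint CSV lacks column '%s'", missing[1]),
          "microstab_format_error")
  df
}

#' @rdname read_endpoints
#' @param endpoints endpoint data.frame to serialize.
#' @export
write_endpoints <- function(endpoints, path) {
  df <- endpoints
  for (col in intersect(c("etsa", "doc", "stability"), names(df)))
    df[[col]] <- format(df[[col]], digits = 17, trim = TRUE, scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
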