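#' Pearson correlation with t-based two-sided p-value
#'
#' Standard product-moment correlation; the p-value comes from
#' `t = r * sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom (two-sided).
#' Perfect correlations get `p = 0` by continuity.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return a list of class `correlation_result`: `r`, `p`, `n`, `t`.
#' @examples
#' pearson(1:10, (1:10) * 2 + 1)$r   # 1
#' @export
pearson <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    abort("x and y differ in length", "microstab_shape_error")
  n <- length(x)
  if (n < 3L)
    abort("need at least 3 observations", "microstab_shape_error")
  if (anyNA(x) || anyNA(y) || !all(is.finite(c(x, y))))
    abort("inputs must be finite and complete", "microstab_shape_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    abort("zero-variance input: correlation undefined",
          "microstab_degenerate_correlation_error")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    tval <- Inf; p <- 0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  structure(list(r = r, p = p, n = n, t = tval), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.4f, p = %.4g, n = %d%s\n", x$r, x$p, x$n, sig_stars(x$p)))
  invisible(x)
}

# Significance marks matching the reporting convention: * p < 0.05, ** p < 0.01.
sig_stars <- function(p) if (p < 0.01) " **" else if (p < 0.05) " *" else ""

#' The six-way correlation battery
#'
#' Correlates the three functional responses (ETSA, DOC proxy, temporal
#' stability 1/Vt) with the two diversity predictors (species richness SR and
#' community metabolic diversity CMD), in the fixed order ETSA~SR, DOC~SR,
#' stability~SR, ETSA~CMD, DOC~CMD, stability~CMD. By default correlations use
#' replicate microcosms as observations; `unit = "consortium"` first averages
#' replicates within consortium (the unit of analysis is ambiguous in such
#' designs, so both are available). No multiple-testing correction is applied
#' (flagged in the output).
#'
#' @param table data.frame with columns `consortium`, `richness`, `cmd`,
#'   `etsa`, `doc`, `stability` (one row per microcosm).
#' @param unit `"replicate"` (default) or `"consortium"`.
#' @return data.frame with columns `response`, `predictor`, `r`, `p`, `n`,
#'   `sig`; attribute `flags` records the unit and the absence of
#'   multiple-testing correction.
#' @export
correlation_battery <- function(table, unit = c("replicate", "consortium")) {
  unit <- match.arg(unit)
  need <- c("consortium", "richness", "cmd", "etsa", "doc", "stability")
  missing <- setdiff(need, names(table))
  if (length(missing) > 0L)
    abort(sprintf("endpoint table lacks column '%s'", missing[1]),
          "microstab_format_error")
  if (anyNA(table[need[-1]]))
    abort("endpoint table has missing values in analyzed columns",
          "microstab_format_error")
  if (unit == "consortium") {
    agg <- stats::aggregate(table[c("richness", "cmd", "etsa", "doc", "stability")],
                            by = list(consortium = table$consortium), mean)
    table <- agg
  }
  pairs <- expand.grid(response = c("etsa", "doc", "stability"),
                       predictor = c("richness", "cmd"),
                       stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    res <- tryCatch(pearson(table[[pairs$predictor[i]]], table[[pairs$response[i]]]),
                    microstab_error = function(e)
                      abort(sprintf("correlation %s ~ %s failed: %s",
                                    pairs$response[i], pairs$predictor[i],
                                    conditionMessage(e)),
                            "microstab_degenerate_correlation_error"))
    data.frame(response = pairs$response[i], predictor = pairs$predictor[i],
               r = res$r, p = res$p, n = res$n, sig = trimws(sig_stars(res$p)))
  }))
  attr(out, "flags") <- list(unit = unit, multiple_testing_correction = "none")
  out
}

#' Third-order polynomial trend fit
#'
#' Least-squares cubic `y = b0 + b1*x + b2*x^2 + b3*x^3`, the standard smooth
#' summary of a saturating diversity-function curve. Requires at least 4
#' distinct x values; with exactly 4 points in general position the fit
#' interpolates.
#'
#' @param x,y numeric vectors of equal length.
#' @return list of class `cubic_trend` with `coefficients` (b0..b3), `fitted`
#'   and `rss`.
#' @export
cubic_trend <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    abort("x and y differ in length", "microstab_shape_error")
  if (length(unique(x)) < 4L)
    abort("cubic fit needs at least 4 distinct x values",
          "microstab_rank_error")
  fit <- stats::lm(y ~ x + I(x^2) + I(x^3))
  co <- stats::setNames(as.numeric(stats::coef(fit)),
                        c("b0", "b1", "b2", "b3"))
  structure(list(coefficients = co, fitted = as.numeric(stats::fitted(fit)),
                 rss = sum(stats::residuals(fit)^2)),
            class = "cubic_trend")
}

#' @export
print.cubic_trend <- function(x, ...) {
  cat(sprintf("cubic trend: y = %.4g %+.4g x %+.4g x^2 %+.4g x^3 (rss %.4g)\n",
              x$coefficients[1], x$coefficients[2], x$coefficients[3],
              x$coefficients[4], x$rss))
  invisible(x)
}
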