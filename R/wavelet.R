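#' Redox-potential time series
#'
#' An `eh_series` holds one probe's regularly sampled redox potential (Eh, mV)
#' trace for one microcosm. Sampling must be strictly regular (relative
#' spacing tolerance 1e-9); irregular series are rejected rather than
#' interpolated.
#'
#' @param values numeric vector of Eh readings (mV), length >= 16, all finite.
#' @param dt sampling interval in seconds (default 900 s = 15 min).
#' @param t optional explicit sample times (seconds); must be uniform.
#' @param microcosm_id,probe_depth identifiers (probe depth in mm, 0-7 by
#'   convention for the 8-probe profile of the upper sediment layer).
#' @return an object of class `eh_series`.
#' @export
eh_series <- function(values, dt = 900, t = NULL, microcosm_id = "m1",
                      probe_depth = 0L) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 16L)
    abort("eh_series needs at least 16 samples", "microstab_length_error")
  if (!all(is.finite(values)))
    abort("eh_series values must be finite", "microstab_format_error")
  if (is.null(t)) {
    if (!is_number(dt) || dt <= 0)
      abort("dt must be a positive number", "microstab_format_error")
    t <- (seq_len(n) - 1) * dt
  } else {
    if (length(t) != n)
      abort("t and values differ in length", "microstab_format_error")
    d <- diff(t)
    if (any(d <= 0) || max(abs(d - d[1])) > 1e-9 * abs(d[1]))
      abort("sample times must be strictly increasing with uniform spacing",
            "microstab_format_error")
    dt <- d[1]
  }
  structure(list(microcosm_id = microcosm_id,
                 probe_depth = as.integer(probe_depth),
                 t = t, dt = dt, values = values),
            class = "eh_series")
}

#' @export
print.eh_series <- function(x, ...) {
  cat(sprintf("eh_series %s depth %d mm: %d samples @ %g s (%.1f .. %.1f mV)\n",
              x$microcosm_id, x$probe_depth, length(x$values), x$dt,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Complex Morlet mother wavelet
#'
#' The standard admissible (in the usual approximation, `omega0 >= 5`) complex
#' Morlet wavelet `g(eta) = pi^(-1/4) * exp(1i*omega0*eta) * exp(-eta^2/2)`,
#' a plane wave of dimensionless centre frequency `omega0` under a unit
#' Gaussian envelope. Its squared modulus integrates to 1.
#'
#' @param eta dimensionless offset(s) (t - location)/scale.
#' @param omega0 dimensionless centre frequency (default 6).
#' @return complex vector of wavelet values.
#' @export
morlet <- function(eta, omega0 = 6) {
  pi^(-0.25) * exp(1i * omega0 * eta) * exp(-eta^2 / 2)
}

#' Equivalent Fourier period of a Morlet scale
#'
#' Converts a wavelet scale `a` to the period of the sinusoid whose transform
#' modulus peaks at that scale: `lambda = 4*pi*a / (omega0 + sqrt(2 + omega0^2))`
#' (about 1.03 a for `omega0 = 6`).
#'
#' @param scale wavelet scale(s), time units.
#' @param omega0 Morlet centre frequency.
#' @return Fourier period(s) in the same units as `scale`.
#' @export
fourier_period <- function(scale, omega0 = 6) {
  4 * pi * scale / (omega0 + sqrt(2 + omega0^2))
}

#' Logarithmic scale grids
#'
#' Scales run from `2*dt` upward at a constant ratio `2^(1/n_voices)`
#' (`n_voices` scales per octave), capped at a quarter of the series span
#' `n_samples*dt/4`; the grid has `floor(log2(cap/(2*dt)) * n_voices) + 1`
#' points, so the largest grid scale is the last ratio point at or below the
#' cap.
#'
#' @param n_samples series length (>= 16).
#' @param dt sampling interval, seconds.
#' @param n_voices scales per octave (>= 4, default 8).
#' @return an object of class `scale_grid`: list with `scales` and `n_voices`.
#' @export
default_scale_grid <- function(n_samples, dt = 900, n_voices = 8L) {
  if (!is_count(n_samples) || n_samples < 16L)
    abort("n_samples must be an integer >= 16", "microstab_domain_error")
  if (!is_number(dt) || dt <= 0)
    abort("dt must be positive", "microstab_domain_error")
  if (!is_count(n_voices) || n_voices < 4L)
    abort("n_voices must be an integer >= 4", "microstab_domain_error")
  smin <- 2 * dt
  smax <- n_samples * dt / 4
  octaves <- log2(smax / smin)
  k <- 0:floor(octaves * n_voices)
  scale_grid(smin * 2^(k / n_voices), n_voices = as.integer(n_voices))
}

#' @rdname default_scale_grid
#' @param scales strictly increasing positive scale values (time units).
#' @export
scale_grid <- function(scales, n_voices = NA_integer_) {
  scales <- as.numeric(scales)
  if (length(scales) == 0L || any(!is.finite(scales)) || any(scales <= 0) ||
      any(diff(scales) <= 0))
    abort("scales must be strictly increasing positive values",
          "microstab_domain_error")
  structure(list(scales = scales, n_voices = n_voices), class = "scale_grid")
}

check_grid_for_series <- function(grid, n, dt) {
  stopifnot(inherits(grid, "scale_grid"))
  if (min(grid$scales) < 2 * dt - 1e-9 * dt)
    abort("smallest scale below 2*dt", "microstab_scale_range_error")
  if (max(grid$scales) > n * dt / 4 + 1e-9 * dt)
    abort("largest scale exceeds series span / 4", "microstab_scale_range_error")
  invisible(grid)
}

# Signed circular offsets 0, 1, ..., N/2, -(N/2-1), ..., -1 for an fft grid.
signed_offsets <- function(N) {
  m <- 0:(N - 1)
  m[m > N / 2] <- m[m > N / 2] - N
  m
}

# Precompute per-scale frequency-domain kernels so a batch of same-shaped
# series (e.g. the 8 probes of a microcosm, or all microcosms of a run) pays
# the kernel cost once. The discrete transform implemented is
#   W(a, x_j) = norm(a) * sum_i f(x_i) * Conj(g((x_i - x_j)/a))
# evaluated as a circular convolution on an fft grid zero-padded (boundary =
# "zero") far enough that no wrap-around reaches the data window, or wrapped
# on the series' own length (boundary = "periodic"). Scales are binned into
# the smallest power-of-two fft length their kernel support allows, so small
# scales run on short transforms.
cwt_kernels <- function(grid, n, dt, omega0 = 6,
                        normalization = c("paper", "conventional"),
                        boundary = c("zero", "periodic")) {
  normalization <- match.arg(normalization)
  boundary <- match.arg(boundary)
  scales <- grid$scales
  if (boundary == "zero") {
    L <- pmin(ceiling(8 * scales / dt), n - 1)
    Ns <- 2^ceiling(log2(n + L))
  } else {
    Ns <- rep(n, length(scales))
  }
  tiers <- lapply(unique(Ns), function(N) {
    idx <- which(Ns == N)
    m <- signed_offsets(N)
    H <- matrix(0i, nrow = N, ncol = length(idx))
    for (s in seq_along(idx)) {
      a <- scales[idx[s]]
      eta <- (-m) * dt / a      # convolution kernel h(m) = k(-m)
      keep <- abs(eta) <= 8     # Gaussian envelope < 1.3e-14 beyond
      k <- rep(0i, N)
      k[keep] <- Conj(morlet(eta[keep], omega0))
      k <- k * if (normalization == "paper") 1 / a else 1 / sqrt(a)
      H[, s] <- stats::fft(k)
    }
    list(N = N, idx = idx, H = H)
  })
  list(tiers = tiers, n = n, dt = dt, scales = scales, omega0 = omega0,
       normalization = normalization, boundary = boundary)
}

# Transform one numeric vector with precomputed kernels.
cwt_apply <- function(f, kern) {
  n <- kern$n
  W <- matrix(0i, nrow = length(kern$scales), ncol = n)
  for (tier in kern$tiers) {
    N <- tier$N
    Ff <- stats::fft(c(f, rep(0, N - n)))
    for (s in seq_along(tier$idx)) {
      w <- stats::fft(Ff * tier$H[, s], inverse = TRUE) / N
      W[tier$idx[s], ] <- w[seq_len(n)]
    }
  }
  W
}

# Per-scale variance without materializing the full field (used by the batch
# stability path).
cwt_variance_apply <- function(f, kern, squared) {
  n <- kern$n
  v <- numeric(length(kern$scales))
  for (tier in kern$tiers) {
    N <- tier$N
    Ff <- stats::fft(c(f, rep(0, N - n)))
    for (s in seq_along(tier$idx)) {
      w <- stats::fft(Ff * tier$H[, s], inverse = TRUE)[seq_len(n)] / N
      v[tier$idx[s]] <- if (squared == "modulus") mean(Mod(w)^2) else mean(Re(w)^2)
    }
  }
  v
}

#' Continuous Morlet wavelet transform of an Eh series
#'
#' Computes `W(a, x_j) = norm(a) * sum_i f(x_i) * Conj(g((x_i - x_j)/a))` for
#' every scale in `grid` and every sample location, where `g` is the complex
#' Morlet wavelet ([morlet()]). The default prefactor is the literal `1/a`
#' ("paper"); `"conventional"` uses the energetic `1/sqrt(a)`. The series is
#' mean-centred per probe by default so the downstream variance measures
#' fluctuation amplitude rather than offset. The sum is evaluated by FFT
#' convolution; [cwt_direct()] is the literal double-sum reference path.
#'
#' @param series an [eh_series()] (or numeric vector; then `dt` applies).
#' @param grid a [scale_grid()]; default [default_scale_grid()] for the series.
#' @param normalization `"paper"` (1/a) or `"conventional"` (1/sqrt(a)).
#' @param omega0 Morlet centre frequency; values below 5 compromise
#'   admissibility and trigger a warning.
#' @param center subtract the series mean first? (default `TRUE`)
#' @param boundary `"zero"` pads with zeros (default); `"periodic"` wraps the
#'   series on itself, making the variance of a periodic signal shift
#'   invariant.
#' @param dt sampling interval, used only when `series` is a bare vector.
#' @return an object of class `wavelet_field`: list with `scales`, `t`,
#'   `coefficients` (complex matrix, scales x locations) and the settings used.
#' @export
cwt <- function(series, grid = NULL,
                normalization = c("paper", "conventional"), omega0 = 6,
                center = TRUE, boundary = c("zero", "periodic"), dt = 900) {
  normalization <- match.arg(normalization)
  boundary <- match.arg(boundary)
  if (!inherits(series, "eh_series")) series <- eh_series(series, dt = dt)
  f <- series$values
  n <- length(f)
  if (omega0 < 5)
    warning("omega0 < 5: Morlet admissibility approximation degrades")
  if (is.null(grid)) grid <- default_scale_grid(n, series$dt)
  check_grid_for_series(grid, n, series$dt)
  if (center) f <- f - mean(f)
  kern <- cwt_kernels(grid, n, series$dt, omega0, normalization, boundary)
  W <- cwt_apply(f, kern)
  structure(list(scales = grid$scales, t = series$t, coefficients = W,
                 normalization = normalization, omega0 = omega0,
                 centered = center, boundary = boundary),
            class = "wavelet_field")
}

#' Literal double-sum Morlet transform (reference path)
#'
#' Evaluates the transform definition directly, one term per (sample,
#' location) pair, with no FFT, padding or kernel truncation. O(n^2) per
#' scale; used as the independent oracle for [cwt()].
#'
#' @inheritParams cwt
#' @return a `wavelet_field` (see [cwt()]).
#' @export
cwt_direct <- function(series, grid = NULL,
                       normalization = c("paper", "conventional"), omega0 = 6,
                       center = TRUE, dt = 900) {
  normalization <- match.arg(normalization)
  if (!inherits(series, "eh_series")) series <- eh_series(series, dt = dt)
  f <- series$values
  n <- length(f)
  if (is.null(grid)) grid <- default_scale_grid(n, series$dt)
  check_grid_for_series(grid, n, series$dt)
  if (center) f <- f - mean(f)
  x <- series$t
  W <- matrix(0i, nrow = length(grid$scales), ncol = n)
  for (s in seq_along(grid$scales)) {
    a <- grid$scales[s]
    G <- Conj(morlet(outer(x, x, "-") / a, omega0))  # G[i, j] = g*((x_i-x_j)/a)
    W[s, ] <- as.vector(f %*% G) *
      (if (normalization == "paper") 1 / a else 1 / sqrt(a))
  }
  structure(list(scales = grid$scales, t = x, coefficients = W,
                 normalization = normalization, omega0 = omega0,
                 centered = center, boundary = "none"),
            class = "wavelet_field")
}

#' Wavelet variance per scale
#'
#' `V(a) = (1/n) * sum_j W^2(a, x_j)` with `n` the series length. For the
#' complex Morlet, `W^2` is read as the squared modulus by default
#' (`squared = "modulus"`), which is real and non-negative; `"real"` squares
#' the real part instead, matching a real-valued-transform reading.
#'
#' @param field a `wavelet_field` from [cwt()] or [cwt_direct()].
#' @param squared `"modulus"` (default) or `"real"`.
#' @return named numeric vector `V(a)`, one entry per scale, all >= 0.
#' @export
scale_variance <- function(field, squared = c("modulus", "real")) {
  squared <- match.arg(squared)
  stopifnot(inherits(field, "wavelet_field"))
  W <- field$coefficients
  if (length(W) == 0L)
    abort("empty wavelet field", "microstab_domain_error")
  v <- if (squared == "modulus") rowMeans(Mod(W)^2) else rowMeans(Re(W)^2)
  names(v) <- format(field$scales, trim = TRUE)
  v
}

#' Probe-averaged wavelet variance
#'
#' Element-wise unweighted mean of the per-probe `V(a)` curves of one
#' microcosm or treatment; all curves must share the same scale grid.
#'
#' @param per_probe list of equal-length `V(a)` vectors (or a matrix with one
#'   column per probe).
#' @return numeric `V_t(a)` curve.
#' @export
probe_mean_variance <- function(per_probe) {
  if (is.matrix(per_probe)) per_probe <- asplit(per_probe, 2)
  if (length(per_probe) == 0L)
    abort("need at least one probe", "microstab_domain_error")
  len <- lengths(per_probe)
  if (any(len != len[1]))
    abort("probe variance curves have mismatched scale grids",
          "microstab_alignment_error")
  nm <- lapply(per_probe, names)
  if (!is.null(nm[[1]]) && !all(vapply(nm, identical, logical(1), nm[[1]])))
    abort("probe variance curves have mismatched scale grids",
          "microstab_alignment_error")
  Reduce(`+`, per_probe) / length(per_probe)
}

#' Overall wavelet variance and temporal stability
#'
#' `overall_variance` collapses a `V_t(a)` curve to the scalar `V_t` by an
#' unweighted mean over the (log-spaced) scale grid. `stability` is the
#' reciprocal `1/V_t`; a zero variance (perfectly constant signal) raises a
#' classed degenerate-stability error rather than silently dividing.
#'
#' @param vta non-empty numeric `V_t(a)` curve, all entries >= 0.
#' @return scalar `V_t` (>= 0).
#' @export
overall_variance <- function(vta) {
  vta <- as.numeric(vta)
  if (length(vta) == 0L)
    abort("empty variance curve", "microstab_domain_error")
  if (any(!is.finite(vta)) || any(vta < 0))
    abort("variance curve must be finite and non-negative",
          "microstab_domain_error")
  mean(vta)
}

#' @rdname overall_variance
#' @param vt scalar overall variance `V_t` (>= 0).
#' @export
stability <- function(vt) {
  if (!is_number(vt) || vt < 0)
    abort("V_t must be a non-negative number", "microstab_domain_error")
  if (vt == 0)
    abort("degenerate stability: V_t = 0 (perfectly constant signal)",
          "microstab_degenerate_stability_error")
  1 / vt
}

#' Wavelet-variance stability of a set of Eh probes
#'
#' Composes the full statistic for one microcosm (or one treatment's pooled
#' probes): per-probe Morlet transform, per-scale wavelet variance `V(a)`,
#' probe-averaged `V_t(a)`, scale-averaged scalar `V_t`, and temporal
#' stability `1/V_t`. A perfectly constant input (after centring) yields
#' `overall = 0` with `stability = Inf` and `degenerate = TRUE` rather than an
#' error, so screening runs are never aborted by a dead probe set.
#'
#' @param series_set list of [eh_series()] sharing `dt` and length (>= 1).
#' @param grid a [scale_grid()]; default [default_scale_grid()] with `n_voices`.
#' @param n_voices voices per octave for the default grid.
#' @inheritParams cwt
#' @param squared passed to [scale_variance()].
#' @param kernels precomputed [cwt_kernels()] (internal fast path for batches
#'   of same-shaped microcosms); must match the grid and settings.
#' @return an object of class `wavelet_variance` with fields
#'   `per_scale_per_probe` (matrix scales x probes), `probe_mean`, `overall`,
#'   `stability`, `degenerate`, plus the grid and normalization settings.
#' @export
treatment_stability <- function(series_set, grid = NULL, n_voices = 8L,
                                normalization = c("paper", "conventional"),
                                omega0 = 6, center = TRUE,
                                boundary = c("zero", "periodic"),
                                squared = c("modulus", "real"),
                                kernels = NULL) {
  normalization <- match.arg(normalization)
  boundary <- match.arg(boundary)
  squared <- match.arg(squared)
  if (inherits(series_set, "eh_series")) series_set <- list(series_set)
  if (length(series_set) == 0L)
    abort("need at least one probe series", "microstab_domain_error")
  stopifnot(all(vapply(series_set, inherits, logical(1), "eh_series")))
  n <- length(series_set[[1]]$values)
  dt <- series_set[[1]]$dt
  for (s in series_set) {
    if (length(s$values) != n || abs(s$dt - dt) > 1e-9 * dt)
      abort("all probe series must share dt and length",
            "microstab_alignment_error")
  }
  if (is.null(grid)) grid <- default_scale_grid(n, dt, n_voices)
  check_grid_for_series(grid, n, dt)
  if (is.null(kernels)) kernels <- cwt_kernels(grid, n, dt, omega0,
                                               normalization, boundary)
  V <- vapply(series_set, function(s) {
    f <- s$values
    if (center) f <- f - mean(f)
    cwt_variance_apply(f, kernels, squared)
  }, numeric(length(grid$scales)))
  V <- matrix(V, nrow = length(grid$scales),
              dimnames = list(format(grid$scales, trim = TRUE),
                              vapply(series_set, function(s)
                                sprintf("p%d", s$probe_depth), character(1))))
  vta <- rowMeans(V)
  vt <- mean(vta)
  degen <- vt == 0
  structure(list(per_scale_per_probe = V, probe_mean = vta, overall = vt,
                 stability = if (degen) Inf else 1 / vt, degenerate = degen,
                 grid = grid, normalization = normalization, omega0 = omega0,
                 centered = center, boundary = boundary, squared = squared,
                 n_probes = length(series_set)),
            class = "wavelet_variance")
}

#' Wavelet-variance stability for a batch of microcosms
#'
#' Applies [treatment_stability()] to every element of a named list of probe
#' sets, all sharing the same series length and `dt`, computing the
#' frequency-domain kernels once for the whole batch.
#'
#' @param eh named list: microcosm id -> list of [eh_series()].
#' @inheritParams treatment_stability
#' @return named list of `wavelet_variance` objects.
#' @export
stability_batch <- function(eh, grid = NULL, n_voices = 8L,
                            normalization = c("paper", "conventional"),
                            omega0 = 6, center = TRUE,
                            boundary = c("zero", "periodic"),
                            squared = c("modulus", "real")) {
  normalization <- match.arg(normalization)
  boundary <- match.arg(boundary)
  squared <- match.arg(squared)
  stopifnot(length(eh) >= 1L)
  first <- eh[[1]][[1]]
  n <- length(first$values)
  dt <- first$dt
  if (is.null(grid)) grid <- default_scale_grid(n, dt, n_voices)
  check_grid_for_series(grid, n, dt)
  kern <- cwt_kernels(grid, n, dt, omega0, normalization, boundary)
  lapply(eh, treatment_stability, grid = grid, normalization = normalization,
         omega0 = omega0, center = center, boundary = boundary,
         squared = squared, kernels = kern)
}

#' @export
print.wavelet_variance <- function(x, ...) {
  cat(sprintf(paste0("wavelet_variance: %d probes x %d scales | V_t = %.6g, ",
                     "stability = %.6g%s [%s, |W|^2 = %s]\n"),
              x$n_probes, length(x$probe_mean), x$overall, x$stability,
              if (x$degenerate) " (degenerate)" else "",
              x$normalization, x$squared))
  invisible(x)
}
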