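#' Generator configuration for synthetic microcosm experiments
#'
#' Bundles every tunable of the synthetic world: the affinity-matrix sampler,
#' the compensatory abundance dynamics, the composite multi-probe Eh signal
#' and the decomposition endpoints. Defaults reproduce the classic microcosm
#' setting: 12 species, 95 Biolog-GN substrates, 17-consortium nested design
#' with 3 replicates, 8 Eh probes (0-7 mm) read every 15 min over 13 days.
#' See the methods vignette for the rationale behind each default.
#'
#' @param n_species,n_substrates pool and substrate-panel sizes.
#' @param substrate_popularity_concentration Dirichlet concentration of the
#'   shared substrate-popularity weights; lower values concentrate affinity on
#'   a common substrate core and so raise niche overlap.
#' @param breadth_range integer interval from which each species' niche
#'   breadth is drawn uniformly.
#' @param redox_setpoint_range interval (mV) of species-specific redox
#'   setpoints; setpoints are mapped from the species' substrate-popularity
#'   score so metabolically similar species occupy similar redox niches.
#' @param setpoint_jitter_sd species-specific random setpoint jitter (mV).
#' @param abundance_rel_sd stationary relative fluctuation of total community
#'   abundance (dimensionless).
#' @param fluctuation_timescale AR(1) mean-reversion timescale of abundance
#'   fluctuations, seconds.
#' @param fluctuation_sd composite-Eh fluctuation amplitude (mV) implied by
#'   the abundance dynamics in the uncompensated case.
#' @param compensation_strength coefficient in \[0, 1\]: the fraction of each
#'   species' abundance shock absorbed by overlapping partners (weighted by
#'   pairwise Jaccard overlap), producing anti-correlated, function-conserving
#'   compensatory dynamics.
#' @param observation_noise_sd white electrode noise per reading (mV).
#' @param probe_perturbation_sd smooth probe-level perturbation amplitude (mV).
#' @param probe_decorrelation fraction in \[0, 1\] of probe perturbation
#'   variance that is probe-specific rather than shared across depths.
#' @param drift_amplitude,drift_timescale initial incubation settling
#'   transient: `drift_amplitude * exp(-t/drift_timescale)` mV.
#' @param dt,duration sampling interval and incubation span, seconds.
#' @param n_probes probes (depths) per microcosm.
#' @param etsa_slope,doc_slope true endpoint effects per CMD unit.
#' @param endpoint_noise_sd Gaussian endpoint noise.
#' @param replicates microcosms per consortium.
#' @param seed master integer seed; all module substreams derive from it.
#' @return a validated list of class `generator_config`.
#' @export
generator_config <- function(n_species = 12L, n_substrates = 95L,
                             substrate_popularity_concentration = 10,
                             breadth_range = c(40L, 55L),
                             redox_setpoint_range = c(-200, 400),
                             setpoint_jitter_sd = 15,
                             abundance_rel_sd = 0.05,
                             fluctuation_timescale = 86400,
                             fluctuation_sd = 30,
                             compensation_strength = 0.7,
                             observation_noise_sd = 5,
                             probe_perturbation_sd = 8,
                             probe_decorrelation = 0.5,
                             drift_amplitude = 60,
                             drift_timescale = 129600,
                             dt = 900, duration = 13 * 86400,
                             n_probes = 8L,
                             etsa_slope = 0.12, doc_slope = 0.4,
                             endpoint_noise_sd = 2,
                             replicates = 3L, seed = 1L) {
  cfg <- list(n_species = as.integer(n_species),
              n_substrates = as.integer(n_substrates),
              substrate_popularity_concentration = substrate_popularity_concentration,
              breadth_range = as.integer(breadth_range),
              redox_setpoint_range = as.numeric(redox_setpoint_range),
              setpoint_jitter_sd = setpoint_jitter_sd,
              abundance_rel_sd = abundance_rel_sd,
              fluctuation_timescale = fluctuation_timescale,
              fluctuation_sd = fluctuation_sd,
              compensation_strength = compensation_strength,
              observation_noise_sd = observation_noise_sd,
              probe_perturbation_sd = probe_perturbation_sd,
              probe_decorrelation = probe_decorrelation,
              drift_amplitude = drift_amplitude,
              drift_timescale = drift_timescale,
              dt = dt, duration = duration,
              n_probes = as.integer(n_probes),
              etsa_slope = etsa_slope, doc_slope = doc_slope,
              endpoint_noise_sd = endpoint_noise_sd,
              replicates = as.integer(replicates),
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  sds <- c("setpoint_jitter_sd", "abundance_rel_sd", "fluctuation_sd",
           "observation_noise_sd", "probe_perturbation_sd", "drift_amplitude",
           "endpoint_noise_sd")
  for (f in sds) {
    if (!is_number(cfg[[f]]) || cfg[[f]] < 0)
      abort(sprintf("%s must be >= 0", f), "microstab_config_error")
  }
  if (!is_number(cfg$compensation_strength) ||
      cfg$compensation_strength < 0 || cfg$compensation_strength > 1)
    abort("compensation_strength must lie in [0, 1]", "microstab_config_error")
  if (!is_number(cfg$probe_decorrelation) ||
      cfg$probe_decorrelation < 0 || cfg$probe_decorrelation > 1)
    abort("probe_decorrelation must lie in [0, 1]", "microstab_config_error")
  if (length(cfg$breadth_range) != 2L ||
      cfg$breadth_range[1] > cfg$breadth_range[2] || cfg$breadth_range[1] < 0)
    abort("breadth_range must be a non-decreasing integer interval",
          "microstab_config_error")
  if (cfg$breadth_range[2] > cfg$n_substrates)
    abort("breadth_range exceeds the number of substrates",
          "microstab_config_error")
  if (cfg$duration / cfg$dt < 16)
    abort("duration/dt must be >= 16 samples", "microstab_config_error")
  if (cfg$substrate_popularity_concentration <= 0)
    abort("substrate_popularity_concentration must be positive",
          "microstab_config_error")
  invisible(cfg)
}

n_steps <- function(cfg) as.integer(floor(cfg$duration / cfg$dt))

#' Sample a binary affinity matrix with tunable niche overlap
#'
#' Each species draws its breadth uniformly from `breadth_range`, then samples
#' that many substrates without replacement with probability proportional to a
#' shared popularity weight vector drawn once per matrix from a symmetric
#' Dirichlet with concentration `substrate_popularity_concentration`. Low
#' concentration makes a few substrates very popular, so species pile onto a
#' common core: overlap rises and the CMD-vs-richness curve saturates, the way
#' a small real species pool forces functional redundancy at modest richness.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [generator_config()].
#' @return an [affinity_matrix()] with attribute `popularity` (the weight
#'   vector used).
#' @export
generate_affinity_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(derive_seed(cfg$seed, "affinity"), {
    w <- stats::rgamma(cfg$n_substrates,
                       shape = cfg$substrate_popularity_concentration, rate = 1)
    w <- pmax(w, 1e-12)
    w <- w / sum(w)
    cells <- matrix(0L, cfg$n_species, cfg$n_substrates)
    bseq <- cfg$breadth_range[1]:cfg$breadth_range[2]
    for (i in seq_len(cfg$n_species)) {
      b <- bseq[sample.int(length(bseq), 1L)]   # safe for length-1 ranges
      if (b > 0L) cells[i, sample.int(cfg$n_substrates, b, prob = w)] <- 1L
    }
    m <- affinity_matrix(cells,
                         species_ids = sprintf("sp%02d", seq_len(cfg$n_species)),
                         substrate_ids = sprintf("sub%02d", seq_len(cfg$n_substrates)))
    attr(m, "popularity") <- w
    m
  })
}

#' Species redox setpoints
#'
#' Maps each species' mean substrate popularity (how "core" its resources are)
#' linearly onto `redox_setpoint_range` and adds a species-specific seeded
#' jitter. Species with similar substrate profiles therefore occupy similar
#' redox niches, which is what lets compensatory abundance dynamics stabilize
#' the composite Eh signal. Deterministic per (matrix, seed): the same species
#' gets the same setpoint in every consortium.
#'
#' @param matrix an [affinity_matrix()] for the full pool.
#' @param cfg a [generator_config()].
#' @return named numeric vector of setpoints (mV).
#' @export
species_setpoints <- function(matrix, cfg) {
  p <- colMeans(matrix)             # empirical substrate popularity in pool
  br <- rowSums(matrix)
  score <- vapply(seq_len(nrow(matrix)), function(i) {
    if (br[i] > 0) mean(p[matrix[i, ] == 1L]) else mean(p)
  }, numeric(1))
  rng <- cfg$redox_setpoint_range
  base <- if (diff(range(score)) > 0) {
    rng[1] + (score - min(score)) / diff(range(score)) * diff(rng)
  } else rep(mean(rng), length(score))
  jit <- vapply(rownames(matrix), function(id)
    with_seed(derive_seed(cfg$seed, paste0("setpoint_", id)),
              stats::rnorm(1, 0, cfg$setpoint_jitter_sd)), numeric(1))
  stats::setNames(base + jit, rownames(matrix))
}

# Compensation response matrix R: column i distributes a fraction
# c * min(1, S_i) of species i's abundance shock onto its overlapping
# partners j (weights o_ij / S_i), where S_i = sum_j o_ij. The effective
# innovation is (I - R) eta: partners move opposite to the shocked species
# (anti-correlated compensatory growth) and, at full overlap and c = 1, the
# community total - and with it total metabolism - is conserved.
compensation_matrix <- function(O, c) {
  k <- nrow(O)
  R <- matrix(0, k, k)
  if (c <= 0 || k < 2) return(R)
  S <- colSums(O)
  for (i in seq_len(k)) {
    if (S[i] > 0) R[, i] <- c * O[, i] / max(S[i], 1)
  }
  R
}

#' Simulate overlap-coupled species abundance dynamics
#'
#' Each member's abundance follows a discrete AR(1) mean-reverting fluctuation
#' around an equal baseline share 1/k. With compensation, a fraction
#' `compensation_strength * min(1, sum of partner overlaps)` of every
#' species' shock is absorbed by its overlapping partners in proportion to
#' pairwise Jaccard overlap, so highly overlapping pairs fluctuate in
#' antiphase and the community total stays steady - the compensatory-
#' metabolism mechanism. Innovation size is scaled by 1/sqrt(k) so the total
#' community fluctuation amplitude is richness-independent in the
#' uncompensated null. Paths are truncated at 0 and renormalized, so returned
#' shares are non-negative and sum to 1 at every step (<= 1e-9).
#'
#' @param consortium a [consortium()] (members must be rows of `matrix`).
#' @param matrix pool [affinity_matrix()].
#' @param cfg a [generator_config()].
#' @param seed optional substream seed (defaults to one derived from
#'   `cfg$seed` and the consortium label).
#' @return numeric matrix of shares, species x time, with attributes `latent`
#'   (pre-closure deviations, the plane on which independence/anti-correlation
#'   diagnostics live), `total` (pre-closure community total), `setpoints` and
#'   `absorbed` (per-species compensated shock fraction `c*min(1, S_i)`).
#' @export
simulate_abundances <- function(consortium, matrix, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  members <- resolve_members(matrix, consortium)
  k <- length(members)
  Tn <- n_steps(cfg)
  phi <- exp(-cfg$dt / cfg$fluctuation_timescale)
  # fluctuation_sd = 0 means "no abundance fluctuation at all"; otherwise the
  # stationary per-species deviation is scaled by 1/sqrt(k) so the community
  # total fluctuates with a richness-independent amplitude in the null.
  sd_delta <- if (cfg$fluctuation_sd > 0) cfg$abundance_rel_sd / sqrt(k) else 0
  sd_eta <- sd_delta * sqrt(1 - phi^2)
  O <- overlap_matrix(matrix, members)
  R <- compensation_matrix(O, cfg$compensation_strength)
  if (is.null(seed)) seed <- derive_seed(cfg$seed, paste0("abund_", consortium$label))
  delta <- with_seed(seed, {
    eta <- matrix(stats::rnorm(k * Tn, 0, sd_eta), k, Tn)
    eta <- eta - R %*% eta
    t(vapply(seq_len(k), function(i)
      as.numeric(stats::filter(eta[i, ], phi, method = "recursive")),
      numeric(Tn)))
  })
  nmat <- pmax(1 / k + delta, 0)
  tot <- colSums(nmat)
  shares <- sweep(nmat, 2, ifelse(tot > 0, tot, 1), "/")
  shares[, tot == 0] <- 1 / k
  rownames(shares) <- members
  attr(shares, "latent") <- delta
  attr(shares, "total") <- 1 + colSums(delta)
  attr(shares, "setpoints") <- species_setpoints(matrix, cfg)[members]
  attr(shares, "absorbed") <- cfg$compensation_strength * pmin(1, colSums(O))
  shares
}

#' Simulate a multi-probe composite Eh signal
#'
#' The community redox potential is modelled as the abundance-share-weighted
#' mixture of species redox setpoints, minus a total-metabolism excursion term
#' (more total activity pulls Eh down), plus a smooth exponential incubation
#' settling drift. Each probe adds a smooth perturbation that mixes a shared
#' and a probe-specific AR(1) stream (`probe_decorrelation` sets the
#' probe-specific fraction) plus white electrode noise. The metabolism term is
#' scaled so its uncompensated amplitude is `fluctuation_sd` mV; compensation
#' shrinks it, which is how niche overlap stabilizes the composite signal.
#'
#' @param consortium the [consortium()] the abundances belong to.
#' @param abundances a share matrix from [simulate_abundances()].
#' @param cfg a [generator_config()].
#' @param seed optional substream seed for the probe/observation noise.
#' @param microcosm_id id stamped on the returned series.
#' @return list of `cfg$n_probes` [eh_series()] objects (depths 0..n-1 mm).
#' @export
simulate_eh <- function(consortium, abundances, cfg, seed = NULL,
                        microcosm_id = consortium$label) {
  stopifnot(inherits(cfg, "generator_config"), is.matrix(abundances))
  Tn <- ncol(abundances)
  E <- attr(abundances, "setpoints")
  stopifnot(length(E) == nrow(abundances))
  tt <- (seq_len(Tn) - 1) * cfg$dt
  mixture <- as.numeric(E %*% abundances)
  gamma <- if (cfg$abundance_rel_sd > 0) cfg$fluctuation_sd / cfg$abundance_rel_sd else 0
  metab <- gamma * (attr(abundances, "total") - 1)
  drift <- cfg$drift_amplitude * exp(-tt / cfg$drift_timescale)
  base <- mixture - metab + drift
  phi <- exp(-cfg$dt / cfg$fluctuation_timescale)
  if (is.null(seed)) seed <- derive_seed(cfg$seed, paste0("eh_", microcosm_id))
  with_seed(seed, {
    ar_stream <- function() {
      if (cfg$probe_perturbation_sd == 0) return(numeric(Tn))
      as.numeric(stats::filter(
        stats::rnorm(Tn, 0, cfg$probe_perturbation_sd * sqrt(1 - phi^2)),
        phi, method = "recursive"))
    }
    shared <- ar_stream()
    d <- cfg$probe_decorrelation
    lapply(seq_len(cfg$n_probes), function(p) {
      pert <- sqrt(1 - d) * shared + sqrt(d) * ar_stream()
      obs <- if (cfg$observation_noise_sd > 0)
        stats::rnorm(Tn, 0, cfg$observation_noise_sd) else 0
      eh_series(base + pert + obs, dt = cfg$dt, microcosm_id = microcosm_id,
                probe_depth = p - 1L)
    })
  })
}

#' Simulate decomposition endpoints
#'
#' Per replicate microcosm, electron transport system activity (ETSA) and the
#' DOC proxy are linear in the consortium's CMD plus Gaussian noise, clipped
#' at zero: `etsa = etsa_slope*CMD + N(0, sd)`, `doc = doc_slope*CMD + N(0, sd)`.
#'
#' @param design a [build_design()] result.
#' @param matrix pool [affinity_matrix()].
#' @param cfg a [generator_config()].
#' @param seed optional substream seed.
#' @return data.frame with one row per microcosm: `microcosm_id`, `consortium`,
#'   `level`, `richness`, `cmd`, `etsa`, `doc`; attribute `truth` records the
#'   generating slopes.
#' @export
simulate_endpoints <- function(design, matrix, cfg, seed = NULL) {
  stopifnot(inherits(design, "consortium_design"),
            inherits(cfg, "generator_config"))
  if (is.null(seed)) seed <- derive_seed(cfg$seed, "endpoints")
  rows <- do.call(rbind, lapply(design$consortia, function(co) {
    data.frame(consortium = co$label, level = co$level,
               richness = co$richness,
               cmd = community_metabolic_diversity(matrix, co),
               rep = seq_len(design$replicates))
  }))
  rows$microcosm_id <- sprintf("%s_rep%d", rows$consortium, rows$rep)
  n <- nrow(rows)
  with_seed(seed, {
    rows$etsa <- pmax(0, cfg$etsa_slope * rows$cmd +
                        stats::rnorm(n, 0, cfg$endpoint_noise_sd))
    rows$doc <- pmax(0, cfg$doc_slope * rows$cmd +
                       stats::rnorm(n, 0, cfg$endpoint_noise_sd))
  })
  out <- rows[, c("microcosm_id", "consortium", "level", "richness", "cmd",
                  "etsa", "doc")]
  attr(out, "truth") <- list(etsa_slope = cfg$etsa_slope,
                             doc_slope = cfg$doc_slope,
                             endpoint_noise_sd = cfg$endpoint_noise_sd)
  out
}

#' Generate a complete synthetic microcosm experiment
#'
#' Composes the generator: one affinity matrix, the 17-consortium nested
#' design, `17 * replicates` microcosms each with `n_probes` Eh series, and
#' the endpoint table. At defaults this is 51 microcosms, 408 Eh series of
#' 1248 samples (13 days at 15 min). Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [generator_config()].
#' @return an object of class `microcosm_experiment`: list with `matrix`,
#'   `design`, `eh` (named list, microcosm id -> list of [eh_series()]),
#'   `endpoints`, `truth` (per-microcosm generating record) and `config`.
#' @export
generate_experiment <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  mat <- generate_affinity_matrix(cfg)
  design <- build_design(rownames(mat), replicates = cfg$replicates)
  endpoints <- simulate_endpoints(design, mat, cfg)
  eh <- vector("list", nrow(endpoints))
  names(eh) <- endpoints$microcosm_id
  truth <- vector("list", nrow(endpoints))
  for (i in seq_len(nrow(endpoints))) {
    co <- design$consortia[[match(endpoints$consortium[i],
                                  vapply(design$consortia, `[[`, character(1), "label"))]]
    mid <- endpoints$microcosm_id[i]
    sh <- simulate_abundances(co, mat, cfg,
                              seed = derive_seed(cfg$seed, paste0("abund_", mid)))
    eh[[mid]] <- simulate_eh(co, sh, cfg,
                             seed = derive_seed(cfg$seed, paste0("eh_", mid)),
                             microcosm_id = mid)
    truth[[i]] <- data.frame(
      microcosm_id = mid, consortium = co$label,
      cmd = endpoints$cmd[i],
      mean_overlap = niche_metrics(mat, co)$mean_pairwise_overlap,
      mean_absorbed = mean(attr(sh, "absorbed")))
  }
  structure(list(matrix = mat, design = design, eh = eh,
                 endpoints = endpoints, truth = do.call(rbind, truth),
                 config = cfg),
            class = "microcosm_experiment")
}

#' @export
print.microcosm_experiment <- function(x, ...) {
  cat(sprintf(paste0("microcosm_experiment: %d microcosms (%d consortia x %d",
                     " replicates), %d probes x %d samples each\n"),
              length(x$eh), length(x$design$consortia), x$design$replicates,
              x$config$n_probes, n_steps(x$config)))
  invisible(x)
}
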