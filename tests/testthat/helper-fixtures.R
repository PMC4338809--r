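# Shared fixtures and independent oracles, built in code at test time.

# small deterministic affinity matrix
toy_matrix <- function() {
  affinity_matrix(rbind(
    spA = c(1, 1, 0, 0, 1),
    spB = c(0, 1, 1, 0, 0),
    spC = c(0, 0, 0, 0, 0),
    spD = c(1, 0, 1, 1, 0)
  ), substrate_ids = paste0("s", 1:5))
}

random_affinity <- function(n_species, n_substrates, p = 0.3) {
  affinity_matrix(matrix(rbinom(n_species * n_substrates, 1, p),
                         nrow = n_species))
}

# independent set-algebra oracles: operate on lists of substrate index sets
profile_sets <- function(m) {
  lapply(seq_len(nrow(m)), function(i) which(m[i, ] == 1L))
}
oracle_cmd <- function(m, members) {
  sets <- profile_sets(m)[match(members, rownames(m))]
  length(Reduce(union, sets))
}
oracle_jaccard <- function(m, a, b) {
  sa <- which(m[a, ] == 1L); sb <- which(m[b, ] == 1L)
  length(intersect(sa, sb)) / length(union(sa, sb))
}
oracle_redundancy <- function(m, members) {
  1 - oracle_cmd(m, members) / sum(m[members, , drop = FALSE])
}

# quick generator config: 1-day incubation, defaults otherwise
quick_config <- function(seed = 1, ...) {
  generator_config(duration = 86400, seed = seed, ...)
}

# a pool matrix containing two species with identical profiles (sp01 == sp02)
twin_matrix <- function(seed = 1, breadth = 40) {
  set.seed(seed)
  prof <- as.integer(seq_len(95) %in% sample.int(95, breadth))
  cells <- rbind(prof, prof,
                 matrix(rbinom(10 * 95, 1, breadth / 95), nrow = 10))
  affinity_matrix(cells, species_ids = sprintf("sp%02d", 1:12),
                  substrate_ids = sprintf("sub%02d", 1:95))
}
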