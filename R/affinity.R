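#' Binary substrate-affinity matrices
#'
#' An `affinity_matrix` stores which of a panel of single carbon substrates
#' (Biolog-GN-style, 95 substrates by convention) each bacterial species can
#' utilize. It is a plain 0/1 integer matrix with species as rows and
#' substrates as columns, validated on construction. All niche statistics in
#' the package (niche breadth, community metabolic diversity, Jaccard overlap,
#' functional redundancy) are set operations on its rows.
#'
#' @param x matrix (or object coercible to one) of 0/1 cells.
#' @param species_ids optional character vector of unique row labels;
#'   defaults to `rownames(x)`.
#' @param substrate_ids optional character vector of unique column labels;
#'   defaults to `colnames(x)`.
#' @return an object of class `affinity_matrix` (an integer matrix).
#' @examples
#' m <- affinity_matrix(rbind(a = c(1, 0, 1), b = c(0, 1, 1)),
#'                      substrate_ids = c("s1", "s2", "s3"))
#' niche_breadth(m, "a")
#' @export
affinity_matrix <- function(x, species_ids = NULL, substrate_ids = NULL) {
  x <- as.matrix(x)
  if (!is.null(species_ids)) rownames(x) <- species_ids
  if (!is.null(substrate_ids)) colnames(x) <- substrate_ids
  if (is.null(rownames(x))) rownames(x) <- sprintf("sp%02d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("sub%02d", seq_len(ncol(x)))
  storage.mode(x) <- "integer"
  validate_affinity(x)
  class(x) <- c("affinity_matrix", class(x))
  x
}

validate_affinity <- function(x) {
  if (nrow(x) < 1L || ncol(x) < 1L)
    abort("affinity matrix needs at least one species and one substrate",
          "microstab_format_error")
  bad <- which(is.na(x) | (x != 0L & x != 1L), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(sprintf("non-binary cell at species '%s', substrate '%s'",
                  rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]]),
          "microstab_format_error")
  }
  if (anyDuplicated(rownames(x)))
    abort(sprintf("duplicate species id '%s'",
                  rownames(x)[duplicated(rownames(x))][1]),
          "microstab_format_error")
  if (anyDuplicated(colnames(x)))
    abort("duplicate substrate ids", "microstab_format_error")
  invisible(x)
}

#' @export
print.affinity_matrix <- function(x, ...) {
  cat(sprintf("affinity_matrix: %d species x %d substrates (mean breadth %.1f)\n",
              nrow(x), ncol(x), mean(rowSums(x))))
  invisible(x)
}

# Row lookup with a classed error.
species_row <- function(matrix, species) {
  stopifnot(inherits(matrix, "affinity_matrix"))
  if (length(species) != 1L || !species %in% rownames(matrix))
    abort(sprintf("unknown species '%s'", paste(species, collapse = ",")),
          "microstab_lookup_error")
  matrix[species, , drop = TRUE]
}

resolve_members <- function(matrix, consortium) {
  members <- if (inherits(consortium, "consortium")) consortium$members
             else as.character(consortium)
  if (length(members) == 0L)
    abort("consortium has no members", "microstab_domain_error")
  missing <- setdiff(members, rownames(matrix))
  if (length(missing) > 0L)
    abort(sprintf("unknown species '%s'", missing[1]), "microstab_lookup_error")
  members
}

#' Niche breadth of a species
#'
#' Number of substrates a species utilizes (the size of its resource niche):
#' the row sum of its binary affinity profile.
#'
#' @param matrix an [affinity_matrix()].
#' @param species a species id, or `NULL` for all species.
#' @return integer (named integer vector if `species` is `NULL`).
#' @export
niche_breadth <- function(matrix, species = NULL) {
  stopifnot(inherits(matrix, "affinity_matrix"))
  if (is.null(species)) return(rowSums(matrix))
  sum(species_row(matrix, species))
}

#' Community metabolic diversity (CMD)
#'
#' CMD is the number of unique substrates utilized by at least one member of a
#' consortium: the cardinality of the union of the members' substrate sets. It
#' is monotone non-decreasing under species addition and bounded below by the
#' largest member breadth and above by both the substrate count and the sum of
#' member breadths.
#'
#' @param matrix an [affinity_matrix()].
#' @param consortium a [consortium()] or character vector of member ids.
#' @return integer CMD.
#' @export
community_metabolic_diversity <- function(matrix, consortium) {
  members <- resolve_members(matrix, consortium)
  sum(colSums(matrix[members, , drop = FALSE]) > 0L)
}

#' Pairwise niche overlap (Jaccard)
#'
#' Jaccard index of two species' substrate sets, |A&B| / |A|B|, in \[0, 1\].
#' Undefined (error) when both species utilize no substrate.
#'
#' @param matrix an [affinity_matrix()].
#' @param a,b species ids.
#' @return numeric fraction in \[0, 1\].
#' @export
pairwise_overlap <- function(matrix, a, b) {
  ra <- species_row(matrix, a)
  rb <- species_row(matrix, b)
  uni <- sum(ra | rb)
  if (uni == 0L)
    abort(sprintf("overlap undefined: '%s' and '%s' both have zero breadth", a, b),
          "microstab_undefined_overlap_error")
  sum(ra & rb) / uni
}

# Symmetric Jaccard overlap matrix with zero diagonal; both-zero-breadth pairs
# get overlap 0 (they share no resources to compensate over).
overlap_matrix <- function(matrix, members) {
  k <- length(members)
  m <- matrix[members, , drop = FALSE]
  inter <- tcrossprod(m)
  br <- rowSums(m)
  uni <- outer(br, br, "+") - inter
  o <- ifelse(uni > 0, inter / uni, 0)
  diag(o) <- 0
  o
}

#' Functional redundancy of a consortium
#'
#' Redundancy is defined as `1 - CMD / sum(member breadths)`: the fraction of
#' the members' summed substrate affinities that is duplicated within the
#' consortium. It is 0 exactly when all member profiles are pairwise disjoint
#' and approaches `(k-1)/k` for k identical species.
#'
#' @inheritParams community_metabolic_diversity
#' @return numeric fraction in \[0, 1).
#' @export
community_redundancy <- function(matrix, consortium) {
  members <- resolve_members(matrix, consortium)
  total <- sum(matrix[members, , drop = FALSE])
  if (total == 0L)
    abort("redundancy undefined: all members have zero breadth",
          "microstab_domain_error")
  1 - community_metabolic_diversity(matrix, members) / total
}

#' Niche metric summary for a consortium
#'
#' @inheritParams community_metabolic_diversity
#' @return a list of class `niche_metrics` with fields `breadth_per_species`,
#'   `cmd`, `mean_pairwise_overlap` and `redundancy`.
#' @export
niche_metrics <- function(matrix, consortium) {
  members <- resolve_members(matrix, consortium)
  br <- rowSums(matrix[members, , drop = FALSE])
  o <- overlap_matrix(matrix, members)
  mo <- if (length(members) > 1L) mean(o[upper.tri(o)]) else 0
  structure(list(
    breadth_per_species = br,
    cmd = community_metabolic_diversity(matrix, members),
    mean_pairwise_overlap = mo,
    redundancy = if (sum(br) > 0) 1 - community_metabolic_diversity(matrix, members) / sum(br) else NA_real_
  ), class = "niche_metrics")
}

#' Read / write affinity matrices as TSV
#'
#' The interchange format is a tab-separated table whose first column is
#' `species_id` and whose remaining columns are substrate ids, with 0/1 cells
#' (well A1 water controls are assumed excluded upstream, so a Biolog GN plate
#' contributes exactly 95 substrate columns).
#'
#' @param path file path.
#' @return `read_affinity` returns an [affinity_matrix()];
#'   `write_affinity` returns `path` invisibly.
#' @export
read_affinity <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L || names(df)[1] != "species_id")
    abort("affinity TSV must have a leading 'species_id' column",
          "microstab_format_error")
  ids <- df[[1]]
  cells <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells),
                                 dimnames = dimnames(cells)))
  bad <- which(is.na(num) | (num != 0 & num != 1), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    abort(sprintf("non-binary cell '%s' at species '%s', substrate '%s'",
                  cells[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                  colnames(cells)[bad[1, 2]]),
          "microstab_format_error")
  if (anyDuplicated(ids))
    abort(sprintf("duplicate species id '%s'", ids[duplicated(ids)][1]),
          "microstab_format_error")
  affinity_matrix(num, species_ids = ids, substrate_ids = colnames(cells))
}

#' @rdname read_affinity
#' @param matrix an [affinity_matrix()] to serialize.
#' @export
write_affinity <- function(matrix, path) {
  stopifnot(inherits(matrix, "affinity_matrix"))
  df <- data.frame(species_id = rownames(matrix), unclass(matrix),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
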