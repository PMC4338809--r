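#' Consortium and consortium design objects
#'
#' A `consortium` is a set of species drawn from a declared pool, labelled by
#' the richness level it belongs to and a composition letter (A, B, C, or
#' "single" for the two largest assemblies). A `consortium_design` is an
#' ordered list of consortia plus a replicate count.
#'
#' Note on the classic 17-consortium layout (see [build_design()]): the
#' published assembly table lists only six strains for the richness-7 /
#' composition-C consortium. The design is reproduced as printed; `richness`
#' always equals the actual member count (6 in that one case) while `level`
#' keeps the nominal richness row it came from.
#'
#' @param members character vector of species ids (must be distinct).
#' @param composition_label one of "A", "B", "C", "single".
#' @param level nominal richness level (defaults to `length(members)`).
#' @param pool optional species pool; membership is validated against it.
#' @return an object of class `consortium`.
#' @export
consortium <- function(members, composition_label = "single",
                       level = length(members), pool = NULL) {
  members <- as.character(members)
  if (length(members) == 0L || anyDuplicated(members))
    abort("consortium members must be a non-empty set of distinct ids",
          "microstab_design_error")
  if (!is.null(pool) && length(setdiff(members, pool)) > 0L)
    abort("consortium members outside the declared species pool",
          "microstab_design_error")
  structure(list(
    members = members,
    richness = length(members),
    level = as.integer(level),
    composition_label = composition_label,
    label = sprintf("r%02d%s", as.integer(level),
                    if (composition_label == "single") "" else composition_label)
  ), class = "consortium")
}

#' @export
print.consortium <- function(x, ...) {
  cat(sprintf("consortium %s: %d members {%s}\n", x$label, x$richness,
              paste(x$members, collapse = ", ")))
  invisible(x)
}

# Positional member indices (1-based into the 12-species pool) of the classic
# nested assembly: 5 richness levels x compositions A-C, plus single
# compositions at 11 and 12 species.
design_indices <- function() {
  list(
    list(level = 2L,  label = "A", idx = 1:2),
    list(level = 2L,  label = "B", idx = 6:7),
    list(level = 2L,  label = "C", idx = 11:12),
    list(level = 3L,  label = "A", idx = 1:3),
    list(level = 3L,  label = "B", idx = 6:8),
    list(level = 3L,  label = "C", idx = 10:12),
    list(level = 4L,  label = "A", idx = 1:4),
    list(level = 4L,  label = "B", idx = 5:8),
    list(level = 4L,  label = "C", idx = 9:12),
    list(level = 5L,  label = "A", idx = 1:5),
    list(level = 5L,  label = "B", idx = 5:9),
    list(level = 5L,  label = "C", idx = 8:12),
    list(level = 7L,  label = "A", idx = 1:7),
    list(level = 7L,  label = "B", idx = 4:10),
    list(level = 7L,  label = "C", idx = 7:12),
    list(level = 11L, label = "single", idx = 1:11),
    list(level = 12L, label = "single", idx = 1:12)
  )
}

#' Build the 17-consortium assembly design
#'
#' Reproduces, by positional index into a user-supplied 12-species pool, the
#' nested assembly layout used in small-pool biodiversity-function microcosm
#' experiments: richness levels 2, 3, 4, 5 and 7 each realized by three
#' compositions (A, B, C), plus single compositions of the first 11 and all 12
#' pool species. The small pool forces consortia to become increasingly
#' similar (functionally redundant) as richness grows.
#'
#' @param pool character vector of exactly 12 distinct species ids; index i in
#'   the design table maps to `pool[i]`.
#' @param replicates replicate microcosms per consortium (default 3).
#' @return an object of class `consortium_design`: list with `consortia`
#'   (length 17) and `replicates`.
#' @examples
#' d <- build_design(sprintf("sp%02d", 1:12))
#' d$consortia[[8]]   # richness 4, composition B
#' @export
build_design <- function(pool, replicates = 3L) {
  pool <- as.character(pool)
  if (length(pool) != 12L || anyDuplicated(pool))
    abort("species pool must contain exactly 12 distinct labels",
          "microstab_design_error")
  if (!is_count(replicates))
    abort("replicates must be a positive integer", "microstab_design_error")
  cons <- lapply(design_indices(), function(row)
    consortium(pool[row$idx], composition_label = row$label,
               level = row$level, pool = pool))
  structure(list(consortia = cons, replicates = as.integer(replicates),
                 pool = pool),
            class = "consortium_design")
}

#' @export
print.consortium_design <- function(x, ...) {
  cat(sprintf("consortium_design: %d consortia x %d replicates (pool of %d)\n",
              length(x$consortia), x$replicates, length(x$pool)))
  invisible(x)
}

#' CMD as a function of richness across a design
#'
#' One row per consortium with its composition label, nominal level, actual
#' member count and community metabolic diversity. Within any nested
#' composition chain, CMD is non-decreasing in richness (union monotonicity).
#'
#' @param matrix an [affinity_matrix()] containing all design members.
#' @param design a [build_design()] result.
#' @return data.frame with columns `label`, `level`, `composition`, `richness`,
#'   `cmd`.
#' @export
cmd_richness_curve <- function(matrix, design) {
  stopifnot(inherits(design, "consortium_design"))
  rows <- lapply(design$consortia, function(co) {
    data.frame(label = co$label, level = co$level,
               composition = co$composition_label, richness = co$richness,
               cmd = community_metabolic_diversity(matrix, co))
  })
  do.call(rbind, rows)
}

#' Read / write consortium designs as JSON
#'
#' The interchange format is a JSON object with `pool`, `replicates` and a
#' `consortia` array of `{level, composition_label, member_indices}` records
#' (1-based indices into `pool`).
#'
#' @param path file path.
#' @return `read_design` returns a `consortium_design`; `write_design`
#'   returns `path` invisibly.
#' @export
read_design <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pool <- as.character(obj$pool)
  if (length(pool) != 12L)
    abort("design JSON must declare a 12-species pool", "microstab_design_error")
  rows <- obj$consortia
  cons <- lapply(seq_len(nrow(rows)), function(i) {
    idx <- unlist(rows$member_indices[i])
    consortium(pool[idx], composition_label = rows$composition_label[i],
               level = rows$level[i], pool = pool)
  })
  structure(list(consortia = cons, replicates = as.integer(obj$replicates),
                 pool = pool),
            class = "consortium_design")
}

#' @rdname read_design
#' @param design a `consortium_design` to serialize.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "consortium_design"))
  rows <- data.frame(
    level = vapply(design$consortia, `[[`, integer(1), "level"),
    composition_label = vapply(design$consortia, `[[`, character(1),
                               "composition_label")
  )
  rows$member_indices <- lapply(design$consortia, function(co)
    match(co$members, design$pool))
  jsonlite::write_json(list(pool = design$pool, replicates = design$replicates,
                            consortia = rows),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
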