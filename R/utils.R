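# Internal helpers: classed conditions, seeded evaluation, checksums.

abort <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "microstab_error")))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random stream set from `seed`, then restores the
#' previous stream so callers never perturb each other's draws.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv) else
      suppressWarnings(rm(".Random.seed", envir = genv))
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a reproducible 31-bit sub-seed from a master seed and a label, so each
# generator module consumes an independent named substream: adding a module
# never shifts another module's draws.
derive_seed <- function(seed, label) {
  stopifnot(is_number(seed))
  h <- as.double(seed %% 2147483647)
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Small rolling-hash checksum over a character scalar (provenance identity,
# not cryptographic).
checksum_string <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
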