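# Internal helpers: classed conditions and RNG scoping.

stop_evospec <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "evospec_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' seeded internals (fold assignment, the GA loop, the cohort generator) never
#' disturb the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv, inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# Normalize free-text identifiers: trim whitespace, collapse case.
normalize_id <- function(x) tolower(trimws(as.character(x)))

mask_key <- function(mask) paste(as.integer(mask), collapse = "")

# Deterministic ranking used everywhere candidates are ordered:
# fitness descending, then fewer selected bits (parsimony), then the 0/1
# string lexicographically. `keys` are mask strings.
rank_candidates <- function(fitness, nbits, keys) {
  order(-fitness, nbits, keys, method = "radix")
}
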