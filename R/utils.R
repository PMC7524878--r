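# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Structured error so callers can distinguish failure modes by class.
mint_error <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "mint_error", "error")))
}

#' Reverse complement of nucleotide strings
#'
#' Complements A/C/G/T (and U) with case preserved; `N` and `-` map to
#' themselves. Vectorized over `x`.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse-complemented strings.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  comp <- chartr("ACGTUacgtu", "TGCAAtgcaa", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Run `expr` under a deterministic RNG stream derived from (seed, tag),
# restoring the caller's RNG state afterwards. Each generated table draws
# from its own stream, so adding a table to a study never perturbs the
# draws of the others.
with_stream <- function(seed, tag, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  code <- utf8ToInt(tag)
  offset <- sum(code * seq_along(code))
  derived <- (abs(as.double(seed)) * 1009 + offset) %% 2147483629
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(derived))
  force(expr)
}

# Hamming mismatch count between two equal-length character vectors of bases.
hamming <- function(a, b) sum(a != b)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}
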