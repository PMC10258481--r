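# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the current `.Random.seed`, seeds the generator, evaluates `expr`
#' and restores the previous RNG state. Used internally so that every
#' stochastic operation accepting a `seed` argument is reproducible without
#' disturbing the caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# split sequences into an n x L character matrix
seq_mat <- function(seqs) {
  if (length(seqs) == 0L) return(matrix(character(), 0L, 0L))
  L <- nchar(seqs[1L])
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), ncol = L, byrow = TRUE)
}

# numerically stable softmax
softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

stop_scfv <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "scfvdesign_error")))
}
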