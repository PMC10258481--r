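#' The 20 canonical amino-acid letters
#'
#' Alphabetically ordered one-letter codes of the canonical amino acids, the
#' default design alphabet.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Define a sequence design space
#'
#' A design space fixes the full-length template sequence of one antibody
#' variable domain, the positions that may be mutated (typically the CDR
#' residues), and the residue alphabet. All variants handled by the package
#' are full-length sequences that differ from the template only at designable
#' positions.
#'
#' @param template Amino-acid string (the candidate/template sequence).
#' @param designable_positions Integer vector of 1-based positions that may be
#'   mutated. Duplicates are removed; order is ascending.
#' @param alphabet Character vector of distinct residue letters; defaults to
#'   the 20 canonical amino acids.
#' @param chain_id Text label for the chain (e.g. `"H"` or `"L"`).
#'
#' @return An object of class `design_space` with elements `chain_id`,
#'   `template`, `designable`, `alphabet` and `length`.
#' @export
#' @examples
#' sp <- design_space("ACDEFGHIKL", designable_positions = c(3, 5, 7))
#' sp
design_space <- function(template, designable_positions,
                         alphabet = aa_alphabet(), chain_id = "chain") {
  stopifnot(is.character(template), length(template) == 1L, nchar(template) >= 1L)
  alphabet <- as.character(alphabet)
  if (anyDuplicated(alphabet) || any(nchar(alphabet) != 1L)) {
    stop_scfv("alphabet must be distinct single letters", class = "invalid_alphabet")
  }
  L <- nchar(template)
  pos <- sort(unique(as.integer(designable_positions)))
  if (length(pos) && (min(pos) < 1L || max(pos) > L)) {
    stop_scfv("designable positions must lie in 1..", L, class = "invalid_positions")
  }
  tmpl_chars <- strsplit(template, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(tmpl_chars), alphabet)
  if (length(bad)) {
    stop_scfv("template contains letters outside the alphabet: ",
              paste(bad, collapse = ", "), class = "invalid_template")
  }
  structure(
    list(chain_id = chain_id, template = template, designable = pos,
         alphabet = alphabet, length = L),
    class = "design_space"
  )
}

#' @export
print.design_space <- function(x, ...) {
  cat("Design space '", x$chain_id, "': L = ", x$length, ", ",
      length(x$designable), " designable positions, alphabet size ",
      length(x$alphabet), "\n", sep = "")
  invisible(x)
}

#' Check that a sequence is a valid variant of a design space
#'
#' A valid variant has the template's length, uses only alphabet letters and
#' differs from the template only at designable positions.
#'
#' @param space A [design_space()].
#' @param seqs Character vector of sequences.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_variant <- function(space, seqs) {
  if (any(nchar(seqs) != space$length)) {
    stop_scfv("variant length differs from template length",
              class = "length_mismatch")
  }
  m <- seq_mat(seqs)
  if (!all(m %in% space$alphabet)) {
    stop_scfv("variant contains letters outside the alphabet",
              class = "invalid_letters")
  }
  tmpl <- strsplit(space$template, "", fixed = TRUE)[[1L]]
  diffs <- sweep(m, 2L, tmpl, FUN = "!=")
  fixed <- setdiff(seq_len(space$length), space$designable)
  if (length(fixed) && any(diffs[, fixed, drop = FALSE])) {
    stop_scfv("variant differs from template at a non-designable position",
              class = "invalid_variant")
  }
  invisible(TRUE)
}

#' Hamming distance between two equal-length sequences
#'
#' Number of positions at which the two sequences differ — the mutational
#' distance used throughout for library diversity and distance-binned model
#' evaluation.
#'
#' @param a,b Amino-acid strings of equal length.
#' @return Non-negative integer.
#' @export
#' @examples
#' hamming_distance("ACDEF", "ACDKF") # 1
hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop_scfv("sequences have unequal lengths (", nchar(a), " vs ", nchar(b), ")",
              class = "length_mismatch")
  }
  sum(strsplit(a, "", fixed = TRUE)[[1L]] != strsplit(b, "", fixed = TRUE)[[1L]])
}

#' Hamming distances from one reference to many sequences
#'
#' Vectorised companion of [hamming_distance()].
#'
#' @param ref Reference sequence.
#' @param seqs Character vector of sequences, all the same length as `ref`.
#' @return Integer vector of distances.
#' @export
hamming_to <- function(ref, seqs) {
  if (length(seqs) == 0L) return(integer())
  if (any(nchar(seqs) != nchar(ref))) {
    stop_scfv("sequences have unequal lengths", class = "length_mismatch")
  }
  rc <- strsplit(ref, "", fixed = TRUE)[[1L]]
  m <- seq_mat(seqs)
  as.integer(rowSums(sweep(m, 2L, rc, FUN = "!=")))
}

#' All single-substitution neighbours of a variant
#'
#' Every sequence differing from `seq` at exactly one designable position, in
#' deterministic position-major, alphabet order (the k = 1 shell of the local
#' search neighbourhood).
#'
#' @param space A [design_space()].
#' @param seq A valid variant of `space` (defaults to the template).
#' @return Character vector of `|designable| * (|alphabet| - 1)` sequences.
#' @export
k1_neighbors <- function(space, seq = space$template) {
  out <- character(0)
  for (p in space$designable) {
    cur <- substr(seq, p, p)
    letters <- setdiff(space$alphabet, cur)
    out <- c(out, paste0(substr(seq, 1L, p - 1L), letters,
                         substr(seq, p + 1L, space$length)))
  }
  out
}

# truncated-Poisson draw on [1, upper]; mean approximately lambda
rtrunc_pois <- function(n, lambda, upper) {
  support <- seq_len(upper)
  probs <- stats::dpois(support, lambda)
  if (sum(probs) <= 0) probs <- rep(1, upper) # absurd lambda; fall back to uniform
  sample(support, n, replace = TRUE, prob = probs)
}

# mean of Poisson(lambda) truncated to [1, upper] (used by tests/docs)
trunc_pois_mean <- function(lambda, upper) {
  support <- seq_len(upper)
  probs <- stats::dpois(support, lambda)
  sum(support * probs) / sum(probs)
}

#' Randomly mutate a variant at designable positions
#'
#' Draws the substitution count m from a Poisson(`expected_k`) distribution
#' truncated to `[1, n_designable]` (so the mean number of substitutions is
#' approximately `expected_k` while at least one position always changes),
#' picks m designable positions uniformly without replacement, and replaces
#' each with a letter drawn uniformly from the other alphabet letters.
#'
#' @param space A [design_space()].
#' @param seq Variant to perturb.
#' @param expected_k Positive mean substitution count; must not exceed the
#'   number of designable positions.
#' @param n Number of mutants to draw.
#' @param seed Optional integer seed for reproducibility.
#' @return Character vector of `n` mutant sequences.
#' @export
random_mutant <- function(space, seq = space$template, expected_k = 2,
                          n = 1L, seed = NULL) {
  nd <- length(space$designable)
  if (nd == 0L) {
    stop_scfv("design space has no designable positions",
              class = "unsupported_design_space")
  }
  if (expected_k <= 0 || expected_k > nd) {
    stop_scfv("expected_k must be in (0, ", nd, "]", class = "invalid_config")
  }
  with_seed(seed, {
    ms <- rtrunc_pois(n, expected_k, nd)
    vapply(ms, function(m) {
      chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
      pos <- space$designable[sample.int(nd, m)]
      for (p in pos) {
        chars[p] <- sample(setdiff(space$alphabet, chars[p]), 1L)
      }
      paste(chars, collapse = "")
    }, character(1L))
  })
}

#' Exact-k mutants of a variant
#'
#' Substitutes exactly `k` distinct designable positions with non-template
#' letters (used by the assay simulator's distance-stratified sampling).
#'
#' @inheritParams random_mutant
#' @param k Exact number of substitutions per mutant.
#' @return Character vector of `n` sequences at Hamming distance `k` from `seq`.
#' @export
exact_k_mutant <- function(space, seq = space$template, k, n = 1L, seed = NULL) {
  nd <- length(space$designable)
  if (k < 1L || k > nd) stop_scfv("k must be in 1..", nd, class = "invalid_config")
  with_seed(seed, {
    vapply(seq_len(n), function(i) {
      chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
      pos <- space$designable[sample.int(nd, k)]
      for (p in pos) {
        chars[p] <- sample(setdiff(space$alphabet, chars[p]), 1L)
      }
      paste(chars, collapse = "")
    }, character(1L))
  })
}
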