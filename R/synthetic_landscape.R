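#' Synthetic ground-truth affinity landscape
#'
#' Builds an additive-plus-epistatic ground-truth map from variant sequences
#' to log-scale binding affinity (lower = stronger binding), standing in for
#' a high-throughput binding assay so that the whole design pipeline can be
#' exercised and benchmarked at desk scale. Per-(position, residue) additive
#' effects are drawn from a Gaussian, a configurable number of random
#' pairwise epistatic terms is added, and the template carries zero effect.
#'
#' @param space A [design_space()].
#' @param baseline Log-affinity of the template sequence.
#' @param additive_sd Standard deviation of random additive effects.
#' @param n_epistatic Number of random pairwise epistatic terms.
#' @param epistatic_sd Standard deviation of epistatic effects.
#' @param noise_sd Replicate measurement noise (log-scale).
#' @param detection_limit Measurements above this value are censored to
#'   missing by the assay simulator.
#' @param replicates Number of replicate measurements per variant.
#' @param seed Integer seed for the random effect tables.
#' @param additive_effects Optional explicit effect matrix
#'   (`n_designable x |alphabet|`, rows named by position) overriding the
#'   random draw; template letters must have zero effect.
#' @param epistatic_terms Optional explicit data frame with columns `pos1`,
#'   `res1`, `pos2`, `res2`, `effect` overriding the random draw.
#'
#' @return An object of class `synthetic_landscape`.
#' @export
#' @examples
#' sp <- design_space(strrep("A", 10), 1:5)
#' land <- synthetic_landscape(sp, seed = 1)
#' true_affinity(land, sp$template) # baseline
synthetic_landscape <- function(space, baseline = 4, additive_sd = 1,
                                n_epistatic = 30L, epistatic_sd = 0.5,
                                noise_sd = 0.3, detection_limit = baseline + 2,
                                replicates = 3L, seed = 1L,
                                additive_effects = NULL, epistatic_terms = NULL) {
  stopifnot(inherits(space, "design_space"), replicates >= 1L, noise_sd >= 0)
  nd <- length(space$designable)
  A <- length(space$alphabet)
  tmpl <- strsplit(space$template, "", fixed = TRUE)[[1L]]

  with_seed(seed, {
    if (is.null(additive_effects)) {
      additive_effects <- matrix(stats::rnorm(nd * A, sd = additive_sd), nd, A,
                                 dimnames = list(space$designable, space$alphabet))
    }
    # the template residue is the reference state: zero effect by definition
    for (i in seq_len(nd)) {
      additive_effects[i, tmpl[space$designable[i]]] <- 0
    }
    if (is.null(epistatic_terms)) {
      n_epistatic <- if (nd >= 2L) n_epistatic else 0L
      if (n_epistatic > 0L) {
        pr <- t(replicate(n_epistatic, sort(space$designable[sample.int(nd, 2L)])))
        epistatic_terms <- data.frame(
          pos1 = pr[, 1L], res1 = NA_character_,
          pos2 = pr[, 2L], res2 = NA_character_,
          effect = stats::rnorm(n_epistatic, sd = epistatic_sd),
          stringsAsFactors = FALSE
        )
        for (j in seq_len(n_epistatic)) {
          epistatic_terms$res1[j] <- sample(setdiff(space$alphabet, tmpl[epistatic_terms$pos1[j]]), 1L)
          epistatic_terms$res2[j] <- sample(setdiff(space$alphabet, tmpl[epistatic_terms$pos2[j]]), 1L)
        }
      } else {
        epistatic_terms <- data.frame(pos1 = integer(), res1 = character(),
                                      pos2 = integer(), res2 = character(),
                                      effect = numeric(), stringsAsFactors = FALSE)
      }
    }
  })

  bad <- setdiff(c(epistatic_terms$pos1, epistatic_terms$pos2), space$designable)
  if (length(bad)) {
    stop_scfv("epistatic positions must be designable", class = "invalid_config")
  }

  structure(
    list(space = space, baseline = baseline, additive = additive_effects,
         epistatic = epistatic_terms, noise_sd = noise_sd,
         detection_limit = detection_limit, replicates = as.integer(replicates),
         seed = seed),
    class = "synthetic_landscape"
  )
}

#' @export
print.synthetic_landscape <- function(x, ...) {
  cat("Synthetic affinity landscape: baseline ", x$baseline, ", ",
      nrow(x$epistatic), " epistatic terms, noise sd ", x$noise_sd,
      ", detection limit ", x$detection_limit, "\n", sep = "")
  invisible(x)
}

#' Ground-truth affinity of variants
#'
#' Deterministic oracle: baseline plus the additive effects of all
#' non-template residues plus every epistatic term whose two
#' (position, residue) conditions both hold.
#'
#' @param land A [synthetic_landscape()].
#' @param seqs Character vector of variants.
#' @return Numeric vector of log-scale affinities (lower = stronger).
#' @export
true_affinity <- function(land, seqs) {
  if (length(seqs) == 0L) return(numeric())
  sp <- land$space
  m <- seq_mat(seqs)
  tmpl <- strsplit(sp$template, "", fixed = TRUE)[[1L]]
  aff <- rep(land$baseline, length(seqs))
  for (i in seq_along(sp$designable)) {
    p <- sp$designable[i]
    res <- m[, p]
    mut <- res != tmpl[p]
    if (any(mut)) {
      aff[mut] <- aff[mut] + land$additive[i, ][res[mut]]
    }
  }
  if (nrow(land$epistatic)) {
    for (j in seq_len(nrow(land$epistatic))) {
      term <- land$epistatic[j, ]
      hit <- m[, term$pos1] == term$res1 & m[, term$pos2] == term$res2
      if (any(hit)) aff[hit] <- aff[hit] + term$effect
    }
  }
  aff
}

# number of distinct variants at exact distance k from the template
n_variants_at_k <- function(space, k) {
  nd <- length(space$designable)
  choose(nd, k) * (length(space$alphabet) - 1)^k
}

#' Simulate a mutagenesis assay table
#'
#' Emulates the training-data generation of a randomized CDR mutagenesis
#' campaign: `n` unique random mutants of the template, each at an exact
#' mutational distance drawn uniformly from `k_values`, measured in
#' `replicates` noisy replicates on the log scale, with values above the
#' detection limit censored to missing. The template itself is included as
#' an additional assayed record by default, so that the candidate's averaged
#' assay value is available as a fitness threshold.
#'
#' @param land A [synthetic_landscape()].
#' @param n Number of unique mutant variants.
#' @param k_values Integer set of mutational distances to draw uniformly from.
#' @param seed Integer seed.
#' @param include_template Include an assayed template record (id
#'   `"candidate"`).
#' @return Data frame with columns `id`, `sequence`, `rep1..repN`
#'   (`NA` = censored).
#' @export
generate_training_data <- function(land, n, k_values = 1:3, seed = NULL,
                                   include_template = TRUE) {
  sp <- land$space
  stopifnot(n >= 1L)
  k_values <- sort(unique(as.integer(k_values)))
  if (any(k_values < 1L) || any(k_values > length(sp$designable))) {
    stop_scfv("k_values must lie in 1..", length(sp$designable),
              class = "invalid_config")
  }
  capacity <- sum(vapply(k_values, function(k) n_variants_at_k(sp, k), numeric(1)))
  if (n > capacity) {
    stop_scfv("requested ", n, " variants but only ", capacity,
              " exist at the requested distances", class = "capacity_error")
  }

  with_seed(seed, {
    # stratum sizes: one uniform draw over k_values per variant, then clamp at
    # each stratum's capacity and push any excess into strata with room (the
    # k = 1 shell saturates quickly on small CDR spans)
    caps <- vapply(k_values, function(k) n_variants_at_k(sp, k), numeric(1))
    counts <- as.vector(stats::rmultinom(1L, n,
                                         rep(1 / length(k_values), length(k_values))))
    repeat {
      excess <- sum(pmax(counts - caps, 0))
      counts <- pmin(counts, caps)
      if (excess == 0) break
      room <- caps - counts
      i <- which.max(room)
      counts[i] <- counts[i] + min(room[i], excess)
    }
    seqs <- character(0)
    for (ki in seq_along(k_values)) {
      k <- k_values[ki]
      m <- counts[ki]
      if (m == 0) next
      if (k == 1L) {
        shell <- k1_neighbors(sp)
        stratum <- shell[sample.int(length(shell), m)]
      } else {
        stratum <- character(0)
        tries <- 0L
        while (length(stratum) < m && tries < 200L) {
          batch <- exact_k_mutant(sp, sp$template, k,
                                  n = ceiling((m - length(stratum)) * 1.3))
          stratum <- unique(c(stratum, batch))
          tries <- tries + 1L
        }
        if (length(stratum) < m) {
          stop_scfv("could not generate ", m, " unique variants at distance ", k,
                    class = "capacity_error")
        }
        stratum <- stratum[seq_len(m)]
      }
      seqs <- c(seqs, stratum)
    }
    if (include_template) seqs <- c(sp$template, seqs)

    aff <- true_affinity(land, seqs)
    R <- land$replicates
    reps <- matrix(rep(aff, R) + stats::rnorm(length(seqs) * R, sd = land$noise_sd),
                   nrow = length(seqs), ncol = R)
    reps[reps > land$detection_limit] <- NA_real_
    ids <- if (include_template) {
      c("candidate", sprintf("v%05d", seq_len(n)))
    } else sprintf("v%05d", seq_len(n))
    df <- data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE)
    colnames(reps) <- paste0("rep", seq_len(R))
    cbind(df, as.data.frame(reps))
  })
}

#' Ground-truth percent of success of a library
#'
#' Fraction of library variants whose true (oracle) affinity is strictly
#' below `threshold` — the benchmark counterpart of the empirical percent of
#' success.
#'
#' @param land A [synthetic_landscape()].
#' @param library Character vector of variant sequences.
#' @param threshold Log-affinity threshold (typically the candidate's value).
#' @return Fraction in `[0, 1]`.
#' @export
ground_truth_percent_success <- function(land, library, threshold) {
  if (length(library) == 0L) {
    stop_scfv("percent success is undefined for an empty library",
              class = "undefined_metric")
  }
  stopifnot(is.finite(threshold))
  mean(true_affinity(land, library) < threshold)
}
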