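# Library construction and the evaluation battery: rank-and-select,
# percent success under the replicate-count rule, diversity metrics,
# fold improvement, and estimated-vs-actual library ranking.

#' Rank-order sampler traces and select the top-n library
#'
#' Pools one or more traces, de-duplicates by sequence (keeping the first
#' recorded fitness — identical across visits for a deterministic
#' landscape), sorts by fitness descending with a lexicographic tie-break
#' and truncates to `n`.
#'
#' @param traces A `sampler_trace`, plain data frame with `sequence` and
#'   `fitness` columns, or a list of these.
#' @param n Library size (default 6000).
#' @param name Library name recorded in the result.
#' @return Object of class `design_library`: data frame with `rank`,
#'   `sequence`, `fitness` (plus a `provenance` attribute).
#' @export
rank_select_top_n <- function(traces, n = 6000L, name = "library") {
  if (is.data.frame(traces)) traces <- list(traces)
  pooled <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(sequence = tr$sequence, fitness = tr$fitness,
               stringsAsFactors = FALSE)
  }))
  pooled <- pooled[!duplicated(pooled$sequence), , drop = FALSE]
  ord <- order(-pooled$fitness, pooled$sequence)
  pooled <- pooled[ord, , drop = FALSE]
  if (nrow(pooled) < n) {
    warning("only ", nrow(pooled), " unique sequences available (requested ", n, ")")
    n <- nrow(pooled)
  }
  out <- pooled[seq_len(n), , drop = FALSE]
  out <- data.frame(rank = seq_len(n), sequence = out$sequence,
                    fitness = out$fitness, stringsAsFactors = FALSE)
  structure(out, provenance = list(name = name),
            class = c("design_library", "data.frame"))
}

# qualifying replicate means under the >= min_replicates rule
measured_means <- function(reps, min_replicates) {
  n_obs <- rowSums(!is.na(reps))
  means <- rowMeans(reps, na.rm = TRUE)
  means[is.nan(means)] <- NA_real_
  list(mean = means, qualifies = n_obs >= min_replicates)
}

#' Empirical percent of success of a measured library
#'
#' Fraction of all library variants whose replicate mean is strictly below
#' the success threshold, counting only variants with at least
#' `min_replicates` non-missing measurements in the numerator; variants with
#' fewer measurements (including fully unmeasured ones) are poor binders by
#' convention and count as failures in the denominator.
#'
#' @param measured Data frame with a `sequence` column and replicate columns
#'   `rep1..repN` (rows of all-`NA` = unmeasured).
#' @param threshold Success threshold (the candidate's averaged value).
#' @param min_replicates Minimum non-missing replicates to qualify
#'   (3 in a 6-replicate validation assay; 2 for the 3-replicate synthetic
#'   assay).
#' @return Fraction in `[0, 1]`.
#' @export
percent_success <- function(measured, threshold, min_replicates = 3L) {
  stopifnot(nrow(measured) >= 1L)
  rep_cols <- grep("^rep[0-9]+$", names(measured), value = TRUE)
  mm <- measured_means(as.matrix(measured[rep_cols]), min_replicates)
  ok <- mm$qualifies & !is.na(mm$mean) & mm$mean < threshold
  sum(ok) / nrow(measured)
}

#' Per-variant affinities with the worst value assigned to failures
#'
#' Variants qualifying under the replicate rule get their replicate mean;
#' all others (unmeasured or under-replicated) are assigned `worst_value`
#' (e.g. the largest assay value observed for the chain) — the convention
#' used for library-level affinity distribution summaries.
#'
#' @inheritParams percent_success
#' @param worst_value Value assigned to unsuccessful variants; warns if an
#'   observed qualifying mean exceeds it.
#' @return Numeric vector of per-variant affinities, one per row.
#' @export
assign_worst_to_unsuccessful <- function(measured, worst_value,
                                         min_replicates = 3L) {
  rep_cols <- grep("^rep[0-9]+$", names(measured), value = TRUE)
  mm <- measured_means(as.matrix(measured[rep_cols]), min_replicates)
  qual <- mm$qualifies & !is.na(mm$mean)
  if (any(qual) && max(mm$mean[qual]) > worst_value) {
    warning("worst_value ", worst_value,
            " is below the largest observed qualifying mean")
  }
  out <- rep(worst_value, nrow(measured))
  out[qual] <- mm$mean[qual]
  out
}

#' Library diversity metrics
#'
#' `d_avg`: mean Hamming distance of the library to the candidate sequence.
#' `d_pw`: mean pairwise Hamming distance between library members, computed
#' exactly for any library size via the per-position letter-count identity
#' (mean pairwise distance = sum over positions of the probability that a
#' random unordered pair differs there), which equals the brute-force
#' double loop at O(nL) cost.
#'
#' @param library Character vector of variant sequences (a `design_library`'s
#'   `sequence` column).
#' @param candidate Candidate sequence.
#' @return Named list with `d_avg` and `d_pw`.
#' @export
diversity <- function(library, candidate) {
  if (length(library) == 0L) {
    stop_scfv("diversity is undefined for an empty library",
              class = "undefined_metric")
  }
  d_avg <- mean(hamming_to(candidate, library))
  n <- length(library)
  if (n < 2L) {
    warning("d_pw of a singleton library is defined as 0")
    return(list(d_avg = d_avg, d_pw = 0))
  }
  m <- seq_mat(library)
  total_pairs <- n * (n - 1) / 2
  d_pw <- 0
  for (j in seq_len(ncol(m))) {
    cnt <- table(m[, j])
    same <- sum(cnt * (cnt - 1) / 2)
    d_pw <- d_pw + (total_pairs - same) / total_pairs
  }
  list(d_avg = d_avg, d_pw = d_pw)
}

#' Fold improvement of a library's best binder over a baseline
#'
#' Ratio `baseline / library` of the best (lowest) linear-scale affinities;
#' values above 1 mean the library's best binder is stronger.
#'
#' @param best_baseline_affinity Best affinity of the baseline library
#'   (linear scale, e.g. pM; must be positive).
#' @param best_library_affinity Best affinity of the evaluated library.
#' @return Positive fold improvement.
#' @export
#' @examples
#' fold_improvement(109.602, 3.817) # ~28.7
fold_improvement <- function(best_baseline_affinity, best_library_affinity) {
  if (best_baseline_affinity <= 0 || best_library_affinity <= 0) {
    stop_scfv("affinities must be positive on the linear scale",
              class = "invalid_input")
  }
  best_baseline_affinity / best_library_affinity
}

#' Rank libraries by estimated percent of success
#'
#' @param estimated Named numeric vector of estimated percent-success values.
#' @return Character vector of library names, best first.
#' @export
rank_libraries <- function(estimated) {
  stopifnot(length(estimated) >= 2L, !is.null(names(estimated)))
  names(sort(estimated, decreasing = TRUE))
}

#' Rank agreement between estimated and actual library performance
#'
#' Spearman rank correlation between the estimated and measured
#' percent-success values of the same named libraries.
#'
#' @param estimated,actual Named numeric vectors over the same library names.
#' @return Spearman correlation in `[-1, 1]`.
#' @export
rank_agreement <- function(estimated, actual) {
  if (!setequal(names(estimated), names(actual))) {
    stop_scfv("library name sets differ", class = "name_mismatch")
  }
  actual <- actual[names(estimated)]
  stats::cor(estimated, actual, method = "spearman")
}

#' Write a design library with per-variant annotations
#'
#' TSV columns: `rank`, `id`, `sequence`, `fitness`,
#' `mutations_from_candidate`.
#'
#' @param library A `design_library` from [rank_select_top_n()].
#' @param space A [design_space()] (for mutation counts vs the template).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_library <- function(library, space, path) {
  df <- data.frame(
    rank = library$rank,
    id = sprintf("d%05d", library$rank),
    sequence = library$sequence,
    fitness = library$fitness,
    mutations_from_candidate = hamming_to(space$template, library$sequence),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
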