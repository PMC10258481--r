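#' Construct an affinity dataset from an assay table
#'
#' Wraps a replicated assay table (as produced by
#' [generate_training_data()] or [read_assay_tsv()]) and precomputes the
#' per-variant average of the non-missing replicate measurements, the target
#' used throughout for evaluation and seed selection.
#'
#' @param df Data frame with `sequence` (unique keys), optional `id`, and
#'   replicate columns `rep1..repN` (`NA` = censored/missing).
#' @return Object of class `affinity_dataset` with elements `id`, `sequence`,
#'   `reps` (numeric matrix) and `avg` (mean of non-missing replicates;
#'   `NA` when every replicate is missing).
#' @export
affinity_dataset <- function(df) {
  stopifnot(is.data.frame(df), "sequence" %in% names(df))
  rep_cols <- grep("^rep[0-9]+$", names(df), value = TRUE)
  if (length(rep_cols) == 0L) {
    stop_scfv("no replicate columns (rep1..repN) found", class = "parse_error")
  }
  if (anyDuplicated(df$sequence)) {
    stop_scfv("duplicate sequences in assay table", class = "invalid_dataset")
  }
  reps <- as.matrix(df[rep_cols])
  storage.mode(reps) <- "double"
  avg <- rowMeans(reps, na.rm = TRUE)
  avg[is.nan(avg)] <- NA_real_
  structure(
    list(id = df$id %||% paste0("s", seq_len(nrow(df))),
         sequence = df$sequence, reps = reps, avg = avg),
    class = "affinity_dataset"
  )
}

#' @export
print.affinity_dataset <- function(x, ...) {
  cat("Affinity dataset: ", length(x$sequence), " variants, ",
      ncol(x$reps), " replicates, ",
      sum(is.na(x$reps)), " censored measurements\n", sep = "")
  invisible(x)
}

#' @export
length.affinity_dataset <- function(x) length(x$sequence)

#' Subset an affinity dataset by record index
#' @param data An [affinity_dataset()].
#' @param idx Integer or logical index vector.
#' @return An `affinity_dataset` with the selected records.
#' @export
subset_dataset <- function(data, idx) {
  structure(
    list(id = data$id[idx], sequence = data$sequence[idx],
         reps = data$reps[idx, , drop = FALSE], avg = data$avg[idx]),
    class = "affinity_dataset"
  )
}

#' Preprocess replicated measurements into regression targets
#'
#' Two policies for detection-limit missingness, mirroring the two
#' preprocessing arms of the surrogate-model ensemble:
#' `"drop"` removes missing replicates before averaging (records with all
#' replicates missing are excluded); `"impute"` replaces each missing
#' replicate with the median of all non-missing measurements in the dataset,
#' then averages.
#'
#' @param data An [affinity_dataset()].
#' @param policy `"drop"` or `"impute"`.
#' @return Data frame with columns `sequence` and `target`.
#' @export
preprocess <- function(data, policy = c("drop", "impute")) {
  policy <- match.arg(policy)
  if (length(data) == 0L) stop_scfv("empty dataset", class = "invalid_dataset")
  if (policy == "drop") {
    keep <- !is.na(data$avg)
    if (!any(keep)) {
      stop_scfv("all measurements missing under the drop policy",
                class = "empty_training_set")
    }
    data.frame(sequence = data$sequence[keep], target = data$avg[keep],
               stringsAsFactors = FALSE)
  } else {
    med <- stats::median(data$reps, na.rm = TRUE)
    if (is.na(med)) {
      stop_scfv("no non-missing measurements to impute from",
                class = "empty_training_set")
    }
    reps <- data$reps
    reps[is.na(reps)] <- med
    data.frame(sequence = data$sequence, target = rowMeans(reps),
               stringsAsFactors = FALSE)
  }
}

#' Split a dataset into train/validation/test partitions
#'
#' Disjoint-by-sequence random partition with sizes within one record of
#' `n * fraction` (defaults to the conventional 0.8/0.1/0.1 split).
#'
#' @param data An [affinity_dataset()].
#' @param fractions Positive numeric vector summing to 1.
#' @param seed Integer seed.
#' @return Named list of `affinity_dataset`s: `train`, `validation`, `test`
#'   (or `split1..splitK` for other fraction counts).
#' @export
split_dataset <- function(data, fractions = c(0.8, 0.1, 0.1), seed = NULL) {
  stopifnot(all(fractions > 0), abs(sum(fractions) - 1) < 1e-8)
  n <- length(data)
  if (n < length(fractions)) {
    stop_scfv("need at least ", length(fractions), " records to split",
              class = "insufficient_data")
  }
  with_seed(seed, {
    perm <- sample.int(n)
    bounds <- round(cumsum(fractions) * n)
    bounds[length(bounds)] <- n
    starts <- c(0L, bounds[-length(bounds)]) + 1L
    parts <- lapply(seq_along(fractions), function(i) {
      subset_dataset(data, sort(perm[starts[i]:bounds[i]]))
    })
    names(parts) <- if (length(parts) == 3L) c("train", "validation", "test") else
      paste0("split", seq_along(parts))
    parts
  })
}
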