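# The Bayesian acquisition layer: a fitness landscape maps a sequence to the
# posterior probability that its (predicted) affinity beats a threshold
# sigma, under a Gaussian predictive distribution:
#   f(x) = p(aff(x) < sigma | x) = Phi((sigma - mu) / s).

#' Construct a Bayesian fitness landscape from a surrogate model
#'
#' @param model A fitted `ensemble_model` or `gp_model`.
#' @param sigma Log-affinity threshold defining a "strong binder" (lower =
#'   stronger); typically the candidate's averaged assay value, see
#'   [threshold_from_candidate()].
#' @return Object of class `fitness_landscape`.
#' @export
fitness_landscape <- function(model, sigma) {
  stopifnot(is.finite(sigma))
  structure(list(model = model, sigma = sigma), class = "fitness_landscape")
}

#' Wrap a plain fitness function as a landscape
#'
#' Creates a landscape whose fitness values come from `fn(seqs)` directly —
#' used for oracle-driven benchmarks of the samplers (e.g. injecting the
#' ground-truth landscape or an enumerable toy fitness).
#'
#' @param fn Function mapping a character vector of sequences to a numeric
#'   vector of fitness values.
#' @return Object of class `c("function_landscape", "fitness_landscape")`.
#' @export
function_landscape <- function(fn) {
  stopifnot(is.function(fn))
  structure(list(fn = fn, sigma = NA_real_),
            class = c("function_landscape", "fitness_landscape"))
}

#' Fitness threshold from the candidate's assayed value
#'
#' Returns the averaged non-missing measurement of the candidate sequence in
#' the training data — the threshold sigma that defines success.
#'
#' @param data An [affinity_dataset()].
#' @param candidate Candidate sequence (must be present with at least one
#'   non-missing measurement).
#' @return Numeric threshold.
#' @export
threshold_from_candidate <- function(data, candidate) {
  i <- match(candidate, data$sequence)
  if (is.na(i) || is.na(data$avg[i])) {
    stop_scfv("candidate absent from the dataset or fully censored; ",
              "supply sigma explicitly", class = "threshold_unavailable")
  }
  data$avg[i]
}

#' Posterior success probabilities of variants
#'
#' For a model-backed landscape, computes `Phi((sigma - mu) / s)` from the
#' model's predictive mean and sd; a degenerate `s = 0` yields the step rule
#' (1 if `mu < sigma`, 0 if `mu > sigma`, 0.5 at equality). For a
#' function-backed landscape, returns `fn(seqs)` unchanged.
#'
#' @param land A [fitness_landscape()] or [function_landscape()].
#' @param seqs Character vector of sequences.
#' @param sigma Optional threshold override (model-backed landscapes only).
#' @return Numeric vector of fitness values, order-preserving.
#' @export
batch_fitness <- function(land, seqs, sigma = NULL) {
  if (length(seqs) == 0L) return(numeric())
  if (inherits(land, "function_landscape")) {
    return(land$fn(seqs))
  }
  sig <- sigma %||% land$sigma
  p <- stats::predict(land$model, seqs)
  bad <- !is.finite(p$mean) | !is.finite(p$sd)
  if (any(bad)) {
    stop_scfv("non-finite prediction for variant '", seqs[which(bad)[1L]], "'",
              class = "prediction_error")
  }
  f <- numeric(length(seqs))
  pos <- p$sd > 0
  f[pos] <- stats::pnorm((sig - p$mean[pos]) / p$sd[pos])
  if (any(!pos)) {
    mu0 <- p$mean[!pos]
    f[!pos] <- ifelse(mu0 < sig, 1, ifelse(mu0 > sig, 0, 0.5))
  }
  f
}

#' Fitness of a single variant
#'
#' @inheritParams batch_fitness
#' @param seq One sequence.
#' @return Probability in `[0, 1]`.
#' @export
fitness <- function(land, seq, sigma = NULL) {
  batch_fitness(land, seq, sigma = sigma)[1L]
}

#' Estimated percent of success of a library
#'
#' In-silico forecast of library performance: the mean posterior success
#' probability over the library's variants. A `sigma` override supports the
#' varying-threshold analysis.
#'
#' @inheritParams batch_fitness
#' @param library Character vector of variant sequences.
#' @return Fraction in `[0, 1]`.
#' @export
estimated_percent_success <- function(land, library, sigma = NULL) {
  if (length(library) == 0L) {
    stop_scfv("estimated percent success is undefined for an empty library",
              class = "undefined_metric")
  }
  mean(batch_fitness(land, library, sigma = sigma))
}
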