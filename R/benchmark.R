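# Desk-scale head-to-head benchmark on the synthetic ground-truth landscape:
# train surrogate models on simulated assay data, design libraries with each
# (model, sampler) combination plus directed-evolution baselines, and score
# every library against the oracle. Mirrors the full design campaign in
# miniature, at sizes chosen to run on a single CPU in minutes.

#' Build a benchmark design space
#'
#' Random full-length template with two CDR-like designable spans.
#'
#' @param n_designable Total designable positions (split over two spans).
#' @param length Template length.
#' @param seed Integer seed.
#' @return A [design_space()].
#' @export
benchmark_space <- function(n_designable = 30L, length = 60L, seed = 1L) {
  with_seed(seed, {
    tmpl <- paste(sample(aa_alphabet(), length, replace = TRUE), collapse = "")
    half <- ceiling(n_designable / 2)
    span1 <- seq(26L, by = 1L, length.out = half)
    span2 <- seq(45L, by = 1L, length.out = n_designable - half)
    if (max(span2, span1) > length) {
      span1 <- seq_len(half)
      span2 <- seq(half + 2L, by = 1L, length.out = n_designable - half)
    }
    design_space(tmpl, c(span1, span2), chain_id = "bench")
  })
}

#' Run the in-silico design head-to-head benchmark
#'
#' One full replicate of the design campaign on a seeded synthetic
#' landscape: simulate a censored triplicate mutagenesis assay on random
#' k = 1-3 CDR mutants, train the requested surrogate models, design a
#' library with each (model, sampler) combination (plus PSSM and
#' random-mutant baselines), rank-select the top `library_size` unique
#' sequences per library, and evaluate every library both in silico
#' (estimated percent of success under its own landscape) and against the
#' ground-truth oracle (true percent of success, diversity, best affinity).
#'
#' @param seed Integer seed controlling the landscape, assay and samplers.
#' @param n_train Number of training mutants.
#' @param n_designable Designable (CDR) positions in the benchmark space.
#' @param library_size Library size after rank-selection.
#' @param models Surrogate families to include: subset of
#'   `c("ensemble", "gp")`.
#' @param samplers Optimisers to run per model: subset of
#'   `c("hc", "ga", "gibbs")`.
#' @param include_baselines Also build PSSM and random-mutant baseline
#'   libraries.
#' @param hc_restarts,ga_restarts Restart counts (desk-scale defaults; the
#'   full-scale recipe uses 100).
#' @param gibbs_iterations Gibbs iterations per run (desk-scale default;
#'   the full-scale recipe uses 30000).
#' @param gp_pca_dim,gp_max_train GP configuration.
#' @return List with `space`, `landscape`, `sigma`, `libraries` (named list
#'   of character vectors) and `summary` (data frame: `library`,
#'   `estimated`, `ground_truth`, `d_avg`, `d_pw`, `best_true_affinity`).
#' @export
benchmark_design_methods <- function(seed = 1L, n_train = 2000L,
                                     n_designable = 30L, library_size = 500L,
                                     models = c("ensemble", "gp"),
                                     samplers = c("hc", "ga", "gibbs"),
                                     include_baselines = TRUE,
                                     hc_restarts = 10L, ga_restarts = 10L,
                                     gibbs_iterations = 2000L,
                                     gp_pca_dim = 256L, gp_max_train = 600L) {
  models <- match.arg(models, several.ok = TRUE)
  samplers <- match.arg(samplers, several.ok = TRUE)

  space <- benchmark_space(n_designable, seed = seed)
  land <- synthetic_landscape(space, seed = seed + 1L)
  assay <- generate_training_data(land, n_train, k_values = 1:3, seed = seed + 2L)
  data <- affinity_dataset(assay)
  sigma <- threshold_from_candidate(data, space$template)
  parts <- split_dataset(data, seed = seed + 3L)
  seeds10 <- select_seeds(parts$train, 10L)

  fitted <- list()
  if ("ensemble" %in% models) {
    fitted$En <- fitness_landscape(train_ensemble(parts$train, space), sigma)
  }
  if ("gp" %in% models) {
    fitted$GP <- fitness_landscape(
      train_gp(parts$train, space, pca_dim = gp_pca_dim,
               max_train = gp_max_train, seed = seed + 4L), sigma)
  }

  libraries <- list()
  landscapes <- list()
  for (mname in names(fitted)) {
    fl <- fitted[[mname]]
    # reference gamma recipes: single gamma for the ensemble landscape,
    # pooled multi-gamma chains for the GP landscape
    gammas <- if (mname == "En") 18 else c(10, 3, 2)
    for (sname in samplers) {
      trace <- switch(sname,
        hc = hill_climb(fl, space, seeds10[1L], restarts = hc_restarts,
                        seed = seed + 10L),
        ga = genetic_algorithm(fl, space, seeds10, beta = if (mname == "En") 0.2 else 0.5,
                               restarts = ga_restarts, max_generations = 30L,
                               seed = seed + 11L),
        gibbs = gibbs_sample(fl, space, seeds10[1L], gammas = gammas,
                             iterations = gibbs_iterations, seed = seed + 12L))
      lib_name <- paste0(mname, "-", toupper(sname))
      libraries[[lib_name]] <- rank_select_top_n(trace, library_size,
                                                 name = lib_name)$sequence
      landscapes[[lib_name]] <- fl
    }
  }

  if (include_baselines) {
    pssm <- fit_pssm(data, space, sigma)
    pool <- unique(sample_pssm(pssm, 4L * library_size, seed = seed + 13L))
    libraries[["PSSM"]] <- pool[seq_len(min(library_size, length(pool)))]
    libraries[["Random"]] <- random_mutant_library(space, seeds10, expected_k = 2,
                                                   n = library_size,
                                                   seed = seed + 14L)
    ref <- fitted[[1L]]
    landscapes[["PSSM"]] <- ref
    landscapes[["Random"]] <- ref
  }

  summary <- do.call(rbind, lapply(names(libraries), function(nm) {
    lib <- libraries[[nm]]
    div <- diversity(lib, space$template)
    data.frame(
      library = nm,
      estimated = estimated_percent_success(landscapes[[nm]], lib),
      ground_truth = ground_truth_percent_success(land, lib, sigma),
      d_avg = div$d_avg, d_pw = div$d_pw,
      best_true_affinity = min(true_affinity(land, lib)),
      stringsAsFactors = FALSE)
  }))

  list(space = space, landscape = land, sigma = sigma,
       libraries = libraries, summary = summary)
}
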