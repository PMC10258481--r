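# Optimization strategies over a fitness landscape: greedy hill climb,
# genetic algorithm with Wright-Fisher selection, and Gibbs sampling, plus
# the directed-evolution baselines (random mutant library, PSSM).
# Every sampler returns a trace data frame recording each sequence it
# evaluated together with its fitness at visit time; libraries are built
# downstream by rank-ordering traces.

new_trace <- function(df, sampler, config, seed) {
  rownames(df) <- NULL
  structure(df, sampler = sampler, config = config, seed = seed,
            class = c("sampler_trace", "data.frame"))
}

bind_trace_rows <- function(rows) {
  do.call(rbind, rows)
}

#' Select the strongest binders from the training data as seeds
#'
#' The `n` sequences with the lowest averaged measurement (lower = stronger
#' binding); ties at the cut are broken lexicographically by sequence.
#'
#' @param data An [affinity_dataset()].
#' @param n Number of seed sequences (default 10).
#' @return Character vector of `n` sequences, strongest first.
#' @export
select_seeds <- function(data, n = 10L) {
  usable <- which(!is.na(data$avg))
  if (length(usable) < n) {
    stop_scfv("only ", length(usable), " measured records; cannot select ", n,
              class = "insufficient_data")
  }
  ord <- usable[order(data$avg[usable], data$sequence[usable])]
  data$sequence[ord[seq_len(n)]]
}

#' Wright-Fisher parent-selection probabilities
#'
#' Softmax of fitness over temperature beta: `p(x) ~ exp(f(x)/beta)`,
#' computed with max-subtraction for numerical stability.
#'
#' @param fitnesses Numeric vector of fitness values.
#' @param beta Positive selection temperature; smaller = stronger selection.
#' @return Probability vector summing to 1.
#' @export
wright_fisher_probs <- function(fitnesses, beta) {
  stopifnot(length(fitnesses) >= 1L, beta > 0)
  if (any(!is.finite(fitnesses))) {
    stop_scfv("non-finite fitness values", class = "invalid_fitness")
  }
  softmax(fitnesses / beta)
}

#' Single-point crossover of two parent sequences
#'
#' Draws a crossover point c uniformly in `[1, L-1]` and returns
#' `p1[1..c] + p2[(c+1)..L]`.
#'
#' @param p1,p2 Parent sequences of equal length `L >= 2`.
#' @param seed Optional integer seed.
#' @return Child sequence of length `L`.
#' @export
single_point_crossover <- function(p1, p2, seed = NULL) {
  L <- nchar(p1)
  if (L != nchar(p2)) stop_scfv("parents differ in length", class = "length_mismatch")
  if (L < 2L) stop_scfv("crossover needs length >= 2", class = "invalid_config")
  with_seed(seed, {
    cpt <- sample.int(L - 1L, 1L)
    paste0(substr(p1, 1L, cpt), substr(p2, cpt + 1L, L))
  })
}

# build the hill-climb neighbourhood: all k = 1 mutants, topped up with
# distinct random k = 2 mutants to reach `size` sequences
hc_neighborhood <- function(space, cur, size) {
  nb <- k1_neighbors(space, cur)
  if (length(nb) >= size) return(nb[seq_len(size)])
  tries <- 0L
  while (length(nb) < size && tries < 50L) {
    fill <- exact_k_mutant(space, cur, k = min(2L, length(space$designable)),
                           n = 2L * (size - length(nb)))
    nb <- unique(c(nb, fill))
    tries <- tries + 1L
  }
  nb[seq_len(min(size, length(nb)))]
}

#' Greedy hill-climb sampler
#'
#' Per restart, starts from a random perturbation of the seed sequence
#' (expected `init_expected_k` substitutions), repeatedly evaluates a
#' neighbourhood of `neighborhood_size` distinct mutants (all k = 1 mutants
#' plus random k = 2 mutants) and moves to the best neighbour while it
#' strictly improves the fitness; each restart terminates at a local optimum
#' of its evaluated neighbourhood. All evaluated sequences are recorded.
#'
#' @param land A [fitness_landscape()].
#' @param space A [design_space()].
#' @param seed_seq Seed sequence (typically a strong binder from training).
#' @param neighborhood_size Neighbourhood size per step (default 1000).
#' @param restarts Number of random restarts (default 100).
#' @param init_expected_k Expected substitutions of the initial perturbation.
#' @param seed Integer seed.
#' @param record `"all"` records every evaluated neighbour; `"path"` only the
#'   accepted iterates and terminals.
#' @return A `sampler_trace` data frame (`sequence`, `fitness`, `run`,
#'   `step`, `role` in visit/evaluated/terminal).
#' @export
hill_climb <- function(land, space, seed_seq, neighborhood_size = 1000L,
                       restarts = 100L, init_expected_k = 2, seed = NULL,
                       record = c("all", "path")) {
  record <- match.arg(record)
  stopifnot(neighborhood_size >= 1L, restarts >= 1L)
  with_seed(seed, {
    rows <- list()
    for (run in seq_len(restarts)) {
      cur <- random_mutant(space, seed_seq, init_expected_k)
      cur_fit <- batch_fitness(land, cur)
      step <- 0L
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = cur, fitness = cur_fit, run = run, step = step,
        role = "visit", stringsAsFactors = FALSE)
      repeat {
        nb <- hc_neighborhood(space, cur, neighborhood_size)
        f <- batch_fitness(land, nb)
        if (record == "all") {
          rows[[length(rows) + 1L]] <- data.frame(
            sequence = nb, fitness = f, run = run, step = step,
            role = "evaluated", stringsAsFactors = FALSE)
        }
        best <- which.max(f)
        if (f[best] > cur_fit) {
          cur <- nb[best]; cur_fit <- f[best]; step <- step + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            sequence = cur, fitness = cur_fit, run = run, step = step,
            role = "visit", stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            sequence = cur, fitness = cur_fit, run = run, step = step,
            role = "terminal", stringsAsFactors = FALSE)
          break
        }
      }
    }
    new_trace(bind_trace_rows(rows), "hill_climb",
              list(neighborhood_size = neighborhood_size, restarts = restarts,
                   init_expected_k = init_expected_k), seed)
  })
}

#' Genetic-algorithm sampler with Wright-Fisher selection
#'
#' Per restart, initialises a population of `population_size` random
#' perturbations of a seed sequence (chosen uniformly from `seed_seqs`).
#' Each generation selects parent pairs with probability proportional to
#' `exp(f/beta)` (with replacement), produces children by single-point
#' crossover followed by a random mutation with expected `child_expected_k`
#' substitutions, and terminates when a generation introduces no sequence
#' unseen in the run (or at `max_generations`). Every evaluated population
#' member is recorded; there is no elitism — designs are harvested from the
#' trace, so the best-ever sequence is never lost.
#'
#' @param land A [fitness_landscape()].
#' @param space A [design_space()].
#' @param seed_seqs Character vector of seed sequences.
#' @param beta Positive selection temperature (0.2 for ensemble-backed
#'   landscapes, 0.5 for GP-backed in the reference configuration).
#' @param population_size Population size (default 100).
#' @param child_expected_k Expected substitutions per child (default 1).
#' @param restarts Number of independent runs (default 100).
#' @param max_generations Safety cap on generations per run.
#' @param seed Integer seed.
#' @return A `sampler_trace` data frame.
#' @export
genetic_algorithm <- function(land, space, seed_seqs, beta = 0.2,
                              population_size = 100L, child_expected_k = 1,
                              restarts = 100L, max_generations = 100L,
                              seed = NULL) {
  stopifnot(beta > 0, population_size >= 2L, restarts >= 1L,
            child_expected_k >= 0)
  mutate <- function(seqs) {
    if (child_expected_k == 0) return(seqs) # mutation disabled
    vapply(seqs, function(s) random_mutant(space, s, child_expected_k),
           character(1L), USE.NAMES = FALSE)
  }
  with_seed(seed, {
    rows <- list()
    for (run in seq_len(restarts)) {
      root <- seed_seqs[sample.int(length(seed_seqs), 1L)]
      pop <- mutate(rep(root, population_size))
      seen <- new.env(hash = TRUE, parent = emptyenv())
      for (gen in seq_len(max_generations)) {
        f <- batch_fitness(land, pop)
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = pop, fitness = f, run = run, step = gen - 1L,
          role = "population", stringsAsFactors = FALSE)
        new_any <- FALSE
        for (s in pop) {
          if (is.null(seen[[s]])) { seen[[s]] <- TRUE; new_any <- TRUE }
        }
        if (!new_any) break
        probs <- wright_fisher_probs(f, beta)
        i <- sample.int(population_size, population_size, replace = TRUE, prob = probs)
        j <- sample.int(population_size, population_size, replace = TRUE, prob = probs)
        children <- vapply(seq_len(population_size), function(cix) {
          single_point_crossover(pop[i[cix]], pop[j[cix]])
        }, character(1L))
        pop <- mutate(children)
      }
    }
    new_trace(bind_trace_rows(rows), "genetic_algorithm",
              list(beta = beta, population_size = population_size,
                   child_expected_k = child_expected_k, restarts = restarts,
                   max_generations = max_generations), seed)
  })
}

#' Gibbs single-site conditional distribution
#'
#' For a designable position, evaluates the fitness of the sequence with
#' that position set to each alphabet letter and returns the softmax of
#' `gamma * f` — the full conditional `p(x_i | x_-i) ~ exp(gamma f(x))`.
#'
#' @param land A [fitness_landscape()].
#' @param space A [design_space()].
#' @param seq Current sequence.
#' @param position Designable position (1-based).
#' @param gamma Non-negative inverse-temperature; `gamma = 0` gives the
#'   uniform distribution.
#' @return Named probability vector over the alphabet, summing to 1.
#' @export
gibbs_conditional <- function(land, space, seq, position, gamma) {
  if (!(position %in% space$designable)) {
    stop_scfv("position ", position, " is not designable", class = "invalid_position")
  }
  cands <- paste0(substr(seq, 1L, position - 1L), space$alphabet,
                  substr(seq, position + 1L, space$length))
  f <- batch_fitness(land, cands)
  p <- softmax(gamma * f)
  names(p) <- space$alphabet
  p
}

#' Gibbs sampler over the fitness landscape
#'
#' Markov-chain sampling targeting the Boltzmann law `exp(gamma f(x)) / Z`:
#' each iteration picks a designable position uniformly at random, draws a
#' residue from the single-site conditional ([gibbs_conditional()]) and
#' updates the sequence. Runs once per (gamma, repetition) combination from
#' `init` (the strongest training binder in the reference configuration) and
#' pools all traces; every iterate is recorded (no burn-in discarded —
#' selection pressure comes from downstream rank-ordering).
#'
#' @param land A [fitness_landscape()].
#' @param space A [design_space()].
#' @param init Initial sequence.
#' @param gammas Numeric vector of gamma values (a multi-gamma recipe pools
#'   several chains).
#' @param iterations Iterations per run (default 30000).
#' @param runs_per_gamma Chains per gamma value.
#' @param seed Integer seed.
#' @return A `sampler_trace` data frame.
#' @export
gibbs_sample <- function(land, space, init, gammas, iterations = 30000L,
                         runs_per_gamma = 1L, seed = NULL) {
  stopifnot(length(gammas) >= 1L, all(gammas >= 0), iterations >= 1L)
  nd <- length(space$designable)
  if (nd == 0L) stop_scfv("no designable positions", class = "unsupported_design_space")
  A <- length(space$alphabet)
  with_seed(seed, {
    rows <- list()
    run <- 0L
    for (g in gammas) {
      for (rep_i in seq_len(runs_per_gamma)) {
        run <- run + 1L
        cur <- init
        seqs <- character(iterations)
        fits <- numeric(iterations)
        for (it in seq_len(iterations)) {
          p <- space$designable[sample.int(nd, 1L)]
          cands <- paste0(substr(cur, 1L, p - 1L), space$alphabet,
                          substr(cur, p + 1L, space$length))
          f <- batch_fitness(land, cands)
          pick <- sample.int(A, 1L, prob = softmax(g * f))
          cur <- cands[pick]
          seqs[it] <- cur
          fits[it] <- f[pick]
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = seqs, fitness = fits, run = run,
          step = seq_len(iterations), role = "visit", gamma = g,
          stringsAsFactors = FALSE)
      }
    }
    new_trace(bind_trace_rows(rows), "gibbs",
              list(gammas = gammas, iterations = iterations,
                   runs_per_gamma = runs_per_gamma), seed)
  })
}

#' Fit a position-specific score matrix on strong training binders
#'
#' Counts residue occurrences at each designable position over the training
#' sequences whose averaged measurement is as good as or better than (<=)
#' the threshold, adds a small pseudocount and normalises:
#' `P[p, a] = (count(p, a) + pseudocount) / (n + pseudocount * |alphabet|)`.
#'
#' @param data An [affinity_dataset()].
#' @param space A [design_space()].
#' @param threshold Qualifying log-affinity threshold (typically the
#'   candidate's averaged value).
#' @param pseudocount Positive pseudocount (default 0.1).
#' @return Object of class `pssm_model` with a `designable x alphabet`
#'   probability matrix (rows sum to 1).
#' @export
fit_pssm <- function(data, space, threshold, pseudocount = 0.1) {
  stopifnot(pseudocount > 0)
  qual <- which(!is.na(data$avg) & data$avg <= threshold)
  if (length(qual) == 0L) {
    stop_scfv("no sequences at or below the threshold", class = "empty_model")
  }
  m <- seq_mat(data$sequence[qual])
  A <- length(space$alphabet)
  mat <- matrix(0, length(space$designable), A,
                dimnames = list(space$designable, space$alphabet))
  for (i in seq_along(space$designable)) {
    counts <- table(factor(m[, space$designable[i]], levels = space$alphabet))
    mat[i, ] <- (as.numeric(counts) + pseudocount) /
      (length(qual) + pseudocount * A)
  }
  structure(list(matrix = mat, pseudocount = pseudocount, space = space,
                 n_sequences = length(qual)),
            class = "pssm_model")
}

#' @export
print.pssm_model <- function(x, ...) {
  cat("PSSM over ", nrow(x$matrix), " designable positions (fit on ",
      x$n_sequences, " sequences, pseudocount ", x$pseudocount, ")\n", sep = "")
  invisible(x)
}

#' Sample variant sequences from a fitted PSSM
#'
#' Draws each designable position independently from its PSSM row;
#' non-designable positions keep the template residue. Sampling is not
#' restricted to a pre-defined mutational distance.
#'
#' @param model A [fit_pssm()] model.
#' @param n Number of sequences to draw (duplicates possible).
#' @param seed Integer seed.
#' @return Character vector of `n` sequences.
#' @export
sample_pssm <- function(model, n, seed = NULL) {
  sp <- model$space
  with_seed(seed, {
    chars <- matrix(rep(strsplit(sp$template, "", fixed = TRUE)[[1L]], each = n),
                    nrow = n)
    for (i in seq_along(sp$designable)) {
      chars[, sp$designable[i]] <- sample(sp$alphabet, n, replace = TRUE,
                                          prob = model$matrix[i, ])
    }
    apply(chars, 1L, paste, collapse = "")
  })
}

#' Random-mutant baseline library
#'
#' `n` unique variants, each a random mutation (expected `expected_k`
#' substitutions) of a seed chosen uniformly from `seeds` — the simplest
#' directed-evolution baseline.
#'
#' @param space A [design_space()].
#' @param seeds Character vector of seed sequences.
#' @param expected_k Expected substitutions per mutant (default 2).
#' @param n Number of unique variants.
#' @param seed Integer seed.
#' @param max_tries Retry cap for de-duplication.
#' @return Character vector of `n` unique sequences.
#' @export
random_mutant_library <- function(space, seeds, expected_k = 2, n,
                                  seed = NULL, max_tries = 200L) {
  stopifnot(length(seeds) >= 1L, n >= 1L)
  with_seed(seed, {
    out <- character(0)
    tries <- 0L
    while (length(out) < n && tries < max_tries) {
      need <- n - length(out)
      roots <- seeds[sample.int(length(seeds), ceiling(need * 1.3), replace = TRUE)]
      batch <- vapply(roots, function(r) random_mutant(space, r, expected_k),
                      character(1L), USE.NAMES = FALSE)
      out <- unique(c(out, batch))
      tries <- tries + 1L
    }
    if (length(out) < n) {
      stop_scfv("could not generate ", n, " unique mutants", class = "capacity_error")
    }
    out[seq_len(n)]
  })
}

#' Write a sampler trace and its configuration to disk
#'
#' The trace rows go to a TSV; sampler name, configuration and seed go to a
#' JSON sidecar (`<path>.json`).
#'
#' @param trace A `sampler_trace`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(as.data.frame(trace), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(sampler = attr(trace, "sampler"), config = attr(trace, "config"),
               seed = attr(trace, "seed"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}
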