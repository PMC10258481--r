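test_that("select_seeds returns the strongest binders with lexicographic ties", {
  df <- data.frame(id = paste0("s", 1:5),
                   sequence = c("CCC", "AAA", "BBB", "DDD", "EEE"),
                   rep1 = c(2, 1, 2, 5, NA), rep2 = c(2, 1, 2, 5, NA),
                   stringsAsFactors = FALSE)
  ds <- affinity_dataset(df)
  expect_identical(select_seeds(ds, 1L), "AAA")
  # tie at 2.0 between BBB and CCC: lexicographically smaller first
  expect_identical(select_seeds(ds, 3L), c("AAA", "BBB", "CCC"))
  expect_error(select_seeds(ds, 5L), class = "insufficient_data")
})

test_that("wright_fisher_probs is the exact softmax of fitness over beta", {
  expect_equal(wright_fisher_probs(rep(0.4, 5), beta = 0.2), rep(0.2, 5))
  p <- wright_fisher_probs(c(0, 1), beta = 1)
  expect_equal(p, c(1 / (1 + exp(1)), exp(1) / (1 + exp(1))))
  # log-probability differences equal (delta f) / beta to 1e-12
  set.seed(1)
  f <- runif(10); beta <- 0.37
  lp <- log(wright_fisher_probs(f, beta))
  expect_lt(max(abs(outer(lp, lp, "-") - outer(f, f, "-") / beta)), 1e-12)
  # large beta approaches uniform
  expect_lt(max(abs(wright_fisher_probs(runif(8), 1000) - 1 / 8)), 0.01)
  expect_error(wright_fisher_probs(c(1, NaN), 1), class = "invalid_fitness")
})

test_that("single-point crossover splices parents at one interior point", {
  expect_identical(single_point_crossover("AAAA", "AAAA", seed = 1L), "AAAA")
  set.seed(2)
  for (i in 1:50) {
    child <- single_point_crossover("AAAA", "CCCC")
    expect_match(child, "^A+C+$") # p1 prefix then p2 suffix, both non-empty
  }
  expect_identical(single_point_crossover("AAAA", "CCCC", seed = 7L),
                   single_point_crossover("AAAA", "CCCC", seed = 7L))
  expect_error(single_point_crossover("A", "C"), class = "invalid_config")
})

test_that("hill climb reaches the unique optimum of the distance oracle", {
  sp <- toy_space(L = 10L, nd = 6L, seed = 3L)
  target <- exact_k_mutant(sp, sp$template, k = 5L, seed = 4L)
  land <- target_landscape(target)
  tr <- hill_climb(land, sp, sp$template, neighborhood_size = 120L,
                   restarts = 10L, seed = 5L)
  terminals <- tr[tr$role == "terminal", ]
  expect_identical(nrow(terminals), 10L)
  expect_true(all(terminals$sequence == target))
  # no evaluated neighbour in a run strictly beats that run's terminal
  for (r in unique(tr$run)) {
    run_rows <- tr[tr$run == r, ]
    expect_gte(run_rows$fitness[run_rows$role == "terminal"][1],
               max(run_rows$fitness))
  }
  # seeded determinism and design-space validity of everything visited
  tr2 <- hill_climb(land, sp, sp$template, neighborhood_size = 120L,
                    restarts = 10L, seed = 5L)
  expect_identical(as.data.frame(tr), as.data.frame(tr2))
  expect_silent(validate_variant(sp, unique(tr$sequence)))
})

test_that("hill-climb neighbourhood is k=1 shell plus distinct k=2 fill", {
  sp <- toy_space(L = 40L, nd = 30L, seed = 6L)
  land <- target_landscape(sp$template)
  tr <- hill_climb(land, sp, sp$template, neighborhood_size = 1000L,
                   restarts = 1L, seed = 7L)
  nb <- tr$sequence[tr$role == "evaluated" & tr$step == 0]
  expect_length(nb, 1000L)
  expect_false(anyDuplicated(nb) > 0)
  d <- hamming_to(tr$sequence[tr$role == "visit" & tr$step == 0][1], nb)
  expect_identical(sum(d == 1L), 570L) # 30 x 19 single mutants
  expect_identical(sum(d == 2L), 430L) # random double-mutant fill
})

test_that("genetic algorithm terminates on convergence and is reproducible", {
  sp <- toy_space(L = 8L, nd = 4L, seed = 8L)
  land <- target_landscape(sp$template)
  # mutation disabled and an all-identical population: no new sequences can
  # appear after the first generation
  tr0 <- genetic_algorithm(land, sp, sp$template, child_expected_k = 0,
                           population_size = 10L, restarts = 1L,
                           max_generations = 50L, seed = 9L)
  expect_lte(max(tr0$step), 1L)
  tr1 <- genetic_algorithm(land, sp, sp$template, population_size = 20L,
                           restarts = 2L, max_generations = 10L, seed = 10L)
  tr2 <- genetic_algorithm(land, sp, sp$template, population_size = 20L,
                           restarts = 2L, max_generations = 10L, seed = 10L)
  expect_identical(as.data.frame(tr1), as.data.frame(tr2))
  expect_silent(validate_variant(sp, unique(tr1$sequence)))
})

test_that("GA search beats an equal budget of random mutants on the oracle", {
  sp <- toy_space(L = 14L, nd = 10L, seed = 11L)
  land_true <- synthetic_landscape(sp, n_epistatic = 10L, seed = 12L)
  fl <- function_landscape(function(s) -true_affinity(land_true, s))
  wins <- 0L
  for (rep_i in 1:10) {
    tr <- genetic_algorithm(fl, sp, sp$template, beta = 0.2,
                            population_size = 50L, restarts = 2L,
                            max_generations = 20L, seed = 100L + rep_i)
    budget <- nrow(tr)
    rand <- vapply(sample(1:3, budget, replace = TRUE),
                   function(k) exact_k_mutant(sp, sp$template, k), character(1))
    best_ga <- min(true_affinity(land_true, tr$sequence))
    best_rand <- min(true_affinity(land_true, rand))
    if (best_ga < best_rand) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("gibbs conditional is the exact softmax of gamma * fitness", {
  sp <- toy_space(L = 8L, nd = 4L, seed = 13L)
  land <- target_landscape(sp$template)
  p0 <- gibbs_conditional(land, sp, sp$template, sp$designable[1], gamma = 0)
  expect_equal(unname(p0), rep(1 / 20, 20))
  # two-letter alphabet, f-values {0, 1} at the mutated site
  bsp <- binary_space(3L)
  bland <- function_landscape(function(s) as.numeric(substr(s, 1, 1) == "C"))
  pb <- gibbs_conditional(bland, bsp, "AAA", 1L, gamma = 1)
  expect_equal(unname(pb), c(1 / (1 + exp(1)), exp(1) / (1 + exp(1))))
  # softmax shift invariance and exact log-probability differences
  shifted <- function_landscape(function(s) as.numeric(substr(s, 1, 1) == "C") + 5)
  expect_equal(gibbs_conditional(shifted, bsp, "AAA", 1L, gamma = 1), pb)
  g <- 2.3
  f <- c(0, 1)
  lp <- log(gibbs_conditional(bland, bsp, "AAA", 1L, gamma = g))
  expect_lt(max(abs(outer(lp, lp, "-") - g * outer(f, f, "-"))), 1e-12)
  expect_error(gibbs_conditional(land, sp, sp$template, sp$length, gamma = 1),
               class = "invalid_position")
})

test_that("gibbs sampling targets the Boltzmann law on an enumerable toy space", {
  # 2 positions x 4 letters = 16 states with a fixed random oracle fitness
  sp <- design_space("AA", 1:2, alphabet = c("A", "C", "D", "E"))
  states <- enumerate_space(sp)
  set.seed(14)
  fvals <- stats::setNames(runif(length(states)), states)
  land <- function_landscape(function(s) unname(fvals[s]))
  gamma <- 2
  tr <- gibbs_sample(land, sp, "AA", gammas = gamma, iterations = 30000L,
                     seed = 15L)
  emp <- table(factor(tr$sequence, levels = states)) / nrow(tr)
  boltz <- exp(gamma * fvals[states]) / sum(exp(gamma * fvals[states]))
  expect_lt(sum(abs(emp - boltz)) / 2, 0.05) # total-variation distance
  # recorded fitness equals the landscape's value at each visited state
  expect_equal(tr$fitness, unname(fvals[tr$sequence]))
  tr2 <- gibbs_sample(land, sp, "AA", gammas = gamma, iterations = 100L, seed = 16L)
  tr3 <- gibbs_sample(land, sp, "AA", gammas = gamma, iterations = 100L, seed = 16L)
  expect_identical(as.data.frame(tr2), as.data.frame(tr3))
})

test_that("multi-gamma gibbs pools one run per gamma with default 30000 iterations", {
  expect_identical(formals(gibbs_sample)$iterations, 30000L)
  bsp <- binary_space(3L)
  bland <- function_landscape(function(s) nchar(gsub("[^C]", "", s)) / 3)
  tr <- gibbs_sample(bland, bsp, "AAA", gammas = c(10, 3, 2), iterations = 50L,
                     seed = 17L)
  expect_identical(unique(tr$run), 1:3)
  expect_identical(unique(tr$gamma), c(10, 3, 2))
  expect_identical(nrow(tr), 150L)
})

test_that("fit_pssm matches the pseudocount formula and normalises rows", {
  sp <- design_space("AA", 1:2)
  df <- data.frame(id = c("q", "bad"), sequence = c("AC", "WW"),
                   rep1 = c(1, 9), rep2 = c(1, 9), stringsAsFactors = FALSE)
  ds <- affinity_dataset(df)
  m <- fit_pssm(ds, sp, threshold = 2, pseudocount = 0.1)
  expect_equal(m$matrix["1", "A"], 1.1 / 3.0)
  expect_equal(m$matrix["2", "C"], 1.1 / 3.0)
  expect_equal(m$matrix["1", "W"], 0.1 / 3.0)
  expect_equal(unname(rowSums(m$matrix)), c(1, 1), tolerance = 1e-9)
  # all 20 letters equally represented at a position -> uniform row at 0.05
  df20 <- data.frame(id = paste0("q", 1:20),
                     sequence = paste0(aa_alphabet(), "A"),
                     rep1 = 1, rep2 = 1, stringsAsFactors = FALSE)
  m20 <- fit_pssm(affinity_dataset(df20), sp, threshold = 2)
  expect_equal(unname(m20$matrix["1", ]), rep(0.05, 20))
  expect_error(fit_pssm(ds, sp, threshold = 0), class = "empty_model")
  # the qualifying rule is non-strict: a sequence exactly at the threshold counts
  m_eq <- fit_pssm(ds, sp, threshold = 1)
  expect_identical(m_eq$n_sequences, 1L)
})

test_that("sample_pssm draws positions independently from the matrix rows", {
  sp <- toy_space(L = 6L, nd = 3L, seed = 18L)
  A <- length(sp$alphabet)
  # degenerate matrix: all mass on the template letters
  tmpl <- strsplit(sp$template, "", fixed = TRUE)[[1]]
  mat <- matrix(0, 3, A, dimnames = list(sp$designable, sp$alphabet))
  for (i in 1:3) mat[i, tmpl[sp$designable[i]]] <- 1
  degen <- structure(list(matrix = mat, pseudocount = 0.1, space = sp,
                          n_sequences = 1L), class = "pssm_model")
  expect_true(all(sample_pssm(degen, 50L, seed = 19L) == sp$template))

  # empirical per-position frequencies match the rows (multinomial
  # goodness-of-fit aggregated over the 20 letters, alpha = 1e-3)
  set.seed(20)
  mat2 <- matrix(rgamma(3 * A, 5), 3, A, dimnames = list(sp$designable, sp$alphabet))
  mat2 <- mat2 / rowSums(mat2)
  pm <- structure(list(matrix = mat2, pseudocount = 0.1, space = sp,
                       n_sequences = 1L), class = "pssm_model")
  n <- 20000L
  draws <- sample_pssm(pm, n, seed = 21L)
  ch <- matrix(unlist(strsplit(draws, "")), ncol = sp$length, byrow = TRUE)
  for (i in 1:3) {
    cnt <- table(factor(ch[, sp$designable[i]], levels = sp$alphabet))
    x2 <- sum((cnt - n * mat2[i, ])^2 / (n * mat2[i, ]))
    expect_lt(x2, qchisq(1 - 1e-3, df = A - 1L))
  }
  expect_silent(validate_variant(sp, draws))
  expect_identical(sample_pssm(pm, 100L, seed = 22L),
                   sample_pssm(pm, 100L, seed = 22L))
})

test_that("random_mutant_library returns unique valid variants around the seeds", {
  sp <- toy_space(L = 10L, nd = 6L, seed = 23L)
  seeds <- c(sp$template, exact_k_mutant(sp, sp$template, 2L, seed = 24L))
  lib <- random_mutant_library(sp, seeds, expected_k = 2, n = 200L, seed = 25L)
  expect_length(lib, 200L)
  expect_false(anyDuplicated(lib) > 0)
  expect_silent(validate_variant(sp, lib))
  expect_identical(formals(random_mutant_library)$expected_k, 2)
  tiny <- design_space("AA", 1L, alphabet = c("A", "C"))
  expect_error(random_mutant_library(tiny, "AA", expected_k = 1, n = 5L),
               class = "capacity_error")
})
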