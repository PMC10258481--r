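# Shared fixtures: small design spaces, deterministic landscapes and a
# stub prediction model with fully controlled (mean, sd) outputs.

# binary-alphabet space used for exhaustive metric checks
binary_space <- function(L = 4L) {
  design_space(strrep("A", L), seq_len(L), alphabet = c("A", "C"))
}

# small canonical-alphabet space
toy_space <- function(L = 10L, nd = 5L, seed = 1L) {
  set.seed(seed)
  tmpl <- paste(sample(aa_alphabet(), L, replace = TRUE), collapse = "")
  design_space(tmpl, seq_len(nd))
}

# all sequences of a fully designable space (small alphabets only)
enumerate_space <- function(space) {
  grid <- do.call(expand.grid, c(rep(list(space$alphabet), space$length),
                                 stringsAsFactors = FALSE))
  apply(as.matrix(grid), 1L, paste, collapse = "")
}

# oracle landscape: fitness = -hamming(x, target)/L (unique optimum at target)
target_landscape <- function(target) {
  L <- nchar(target)
  function_landscape(function(seqs) -hamming_to(target, seqs) / L)
}

# prediction stub with controlled outputs, dispatchable through predict()
stub_model <- function(fn) structure(list(fn = fn), class = "stub_model")
predict.stub_model <- function(object, seqs, ...) object$fn(seqs)
registerS3method("predict", "stub_model", predict.stub_model,
                 envir = asNamespace("stats"))

# constant-(mu, s) stub landscape
const_landscape <- function(mu, s, sigma) {
  fitness_landscape(stub_model(function(seqs) {
    data.frame(mean = rep(mu, length(seqs)), sd = rep(s, length(seqs)))
  }), sigma)
}
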