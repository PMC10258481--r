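# Sequence encoders: exchangeable fixed-dimension featurisations of variants.
# Each encoder is an S3 object; encode() maps a character vector of sequences
# to a numeric matrix with one row per sequence. The same variant always
# encodes to the same vector and the dimension is fixed per design space.

#' Encode sequences as numeric feature matrices
#'
#' @param encoder An encoder created by [encoder_onehot()], [encoder_kmer()]
#'   or [encoder_physchem()].
#' @param seqs Character vector of sequences.
#' @return Numeric matrix, one row per sequence.
#' @export
encode <- function(encoder, seqs) UseMethod("encode")

#' One-hot sequence encoder
#'
#' Encodes each position as an indicator block over the alphabet: dimension
#' `L * |alphabet|`, exactly `L` ones per sequence. For one-hot vectors the
#' pairwise L1 distance equals twice the Hamming distance.
#'
#' @param space A [design_space()].
#' @return Encoder object of class `encoder_onehot`.
#' @export
encoder_onehot <- function(space) {
  structure(list(name = "onehot", space = space,
                 dim = space$length * length(space$alphabet)),
            class = c("encoder_onehot", "seq_encoder"))
}

#' @export
encode.encoder_onehot <- function(encoder, seqs) {
  sp <- encoder$space
  n <- length(seqs)
  A <- length(sp$alphabet)
  X <- matrix(0, n, encoder$dim)
  if (n == 0L) return(X)
  m <- seq_mat(seqs)
  for (j in seq_len(sp$length)) {
    code <- match(m[, j], sp$alphabet)
    X[cbind(seq_len(n), (j - 1L) * A + code)] <- 1
  }
  X
}

#' k-mer composition encoder
#'
#' Counts overlapping k-mers against a deterministic design-space vocabulary
#' (all template k-mers plus every k-mer reachable by a single designable
#' substitution). K-mers outside the vocabulary (from higher-order local
#' combinations) contribute nothing, keeping the dimension fixed.
#'
#' @param space A [design_space()].
#' @param k k-mer length (default 3).
#' @return Encoder object of class `encoder_kmer`.
#' @export
encoder_kmer <- function(space, k = 3L) {
  stopifnot(k >= 1L, k <= space$length)
  tmpl <- space$template
  L <- space$length
  starts <- seq_len(L - k + 1L)
  vocab <- substring(tmpl, starts, starts + k - 1L)
  for (p in space$designable) {
    win <- starts[starts <= p & starts + k - 1L >= p]
    for (s in win) {
      km <- substring(tmpl, s, s + k - 1L)
      off <- p - s + 1L
      for (a in space$alphabet) {
        substr(km, off, off) <- a
        vocab <- c(vocab, km)
      }
    }
  }
  vocab <- sort(unique(vocab))
  structure(list(name = paste0(k, "mer"), space = space, k = as.integer(k),
                 vocab = vocab, dim = length(vocab)),
            class = c("encoder_kmer", "seq_encoder"))
}

#' @export
encode.encoder_kmer <- function(encoder, seqs) {
  n <- length(seqs)
  X <- matrix(0, n, encoder$dim)
  if (n == 0L) return(X)
  k <- encoder$k
  L <- encoder$space$length
  starts <- seq_len(L - k + 1L)
  rows <- seq_len(n)
  for (s in starts) {
    idx <- match(substring(seqs, s, s + k - 1L), encoder$vocab)
    hit <- !is.na(idx)
    if (any(hit)) {
      ij <- cbind(rows[hit], idx[hit])
      X[ij] <- X[ij] + 1
    }
  }
  X
}

# per-residue physico-chemical descriptors (hydropathy: Kyte-Doolittle;
# volume: A.A. Zamyatnin, A^3; polarity: Grantham; charge at neutral pH;
# aromatic / H-bonding indicators)
physchem_table <- function() {
  t(vapply(list(
    A = c( 1.8,  88.6,  8.1,  0, 0, 0),
    C = c( 2.5, 108.5,  5.5,  0, 0, 1),
    D = c(-3.5, 111.1, 13.0, -1, 0, 1),
    E = c(-3.5, 138.4, 12.3, -1, 0, 1),
    F = c( 2.8, 189.9,  5.2,  0, 1, 0),
    G = c(-0.4,  60.1,  9.0,  0, 0, 0),
    H = c(-3.2, 153.2, 10.4,  0.1, 1, 1),
    I = c( 4.5, 166.7,  5.2,  0, 0, 0),
    K = c(-3.9, 168.6, 11.3,  1, 0, 1),
    L = c( 3.8, 166.7,  4.9,  0, 0, 0),
    M = c( 1.9, 162.9,  5.7,  0, 0, 0),
    N = c(-3.5, 114.1, 11.6,  0, 0, 1),
    P = c(-1.6, 112.7,  8.0,  0, 0, 0),
    Q = c(-3.5, 143.8, 10.5,  0, 0, 1),
    R = c(-4.5, 173.4, 10.5,  1, 0, 1),
    S = c(-0.8,  89.0,  9.2,  0, 0, 1),
    T = c(-0.7, 116.1,  8.6,  0, 0, 1),
    V = c( 4.2, 140.0,  5.9,  0, 0, 0),
    W = c(-0.9, 227.8,  5.4,  0, 1, 1),
    Y = c(-1.3, 193.6,  6.2,  0, 1, 1)
  ), identity, numeric(6)))
}

#' Physico-chemical per-residue encoder
#'
#' Each position contributes a block of standardised residue descriptors
#' (hydropathy, volume, polarity, charge, aromaticity, H-bonding capacity);
#' dimension `L * 6`.
#'
#' @param space A [design_space()] over the 20 canonical amino acids.
#' @return Encoder object of class `encoder_physchem`.
#' @export
encoder_physchem <- function(space) {
  tab <- physchem_table()
  if (!all(space$alphabet %in% rownames(tab))) {
    stop_scfv("physchem encoder requires the canonical amino-acid alphabet",
              class = "invalid_config")
  }
  tab <- scale(tab) # comparable scales across descriptors
  structure(list(name = "physchem", space = space, table = tab,
                 dim = space$length * ncol(tab)),
            class = c("encoder_physchem", "seq_encoder"))
}

#' @export
encode.encoder_physchem <- function(encoder, seqs) {
  n <- length(seqs)
  if (n == 0L) return(matrix(0, 0L, encoder$dim))
  m <- seq_mat(seqs)
  d <- ncol(encoder$table)
  X <- matrix(0, n, encoder$dim)
  for (j in seq_len(encoder$space$length)) {
    X[, ((j - 1L) * d + 1L):(j * d)] <- encoder$table[m[, j], , drop = FALSE]
  }
  X
}

#' Default encoder set for the surrogate ensemble
#'
#' One-hot, 3-mer composition and physico-chemical encoders; users may append
#' their own encoder objects (e.g. pretrained embedding lookups) as a fourth
#' family.
#'
#' @param space A [design_space()].
#' @return Named list of encoders.
#' @export
default_encoders <- function(space) {
  list(onehot = encoder_onehot(space),
       kmer3 = encoder_kmer(space, 3L),
       physchem = encoder_physchem(space))
}

#' One-hot encode sequences
#'
#' Convenience wrapper used for diversity embedding: dimension
#' `L * |alphabet|` with exactly `L` ones per row.
#'
#' @param space A [design_space()].
#' @param seqs Character vector of sequences.
#' @return Numeric 0/1 matrix.
#' @export
onehot_encode <- function(space, seqs) {
  encode(encoder_onehot(space), seqs)
}
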