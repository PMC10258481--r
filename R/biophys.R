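# Sequence-level developability descriptors of designed variants:
# isoelectric point from a pK table and mean Kyte-Doolittle hydropathy
# (GRAVY), computed on the design concatenated with its fixed partner chain.

#' Default pK table for isoelectric-point calculation
#'
#' pK values of the terminal groups and ionizable side chains (the EMBOSS
#' set), with the charge sign of each group. The table is an explicit,
#' swappable argument so results are self-contained and reproducible.
#'
#' @return Data frame with columns `group`, `pk`, `sign` (+1 basic,
#'   -1 acidic).
#' @export
pk_table_default <- function() {
  data.frame(
    group = c("Nterm", "Cterm", "C", "D", "E", "H", "K", "R", "Y"),
    pk    = c(8.6,     3.6,     8.5, 3.9, 4.1, 6.5, 10.8, 12.5, 10.1),
    sign  = c(1,       -1,      -1,  -1,  -1,  1,   1,    1,    -1),
    stringsAsFactors = FALSE
  )
}

#' Kyte-Doolittle hydropathy scale
#'
#' @return Named numeric vector over the 20 canonical amino acids.
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

#' Concatenate a designed chain with its fixed partner chain
#'
#' Heavy-chain designs are prepended to the fixed light chain
#' (design + partner); light-chain designs are appended to the fixed heavy
#' chain (partner + design), preserving the natural heavy-light order of the
#' scFv construct.
#'
#' @param design Designed chain sequence.
#' @param partner Fixed partner-chain sequence.
#' @param design_is_heavy Logical; is the design the heavy chain?
#' @return Concatenated amino-acid string.
#' @export
concat_with_partner <- function(design, partner, design_is_heavy = TRUE) {
  stopifnot(nchar(partner) >= 1L)
  if (design_is_heavy) paste0(design, partner) else paste0(partner, design)
}

#' Net charge of a protein sequence at a given pH
#'
#' Henderson-Hasselbalch sum over the terminal groups and ionizable side
#' chains: positive groups contribute `1/(1+10^(pH-pK))`, negative groups
#' `-1/(1+10^(pK-pH))`. Cysteines are treated as free (no disulfide
#' correction). Strictly decreasing in pH.
#'
#' @param seq Amino-acid string.
#' @param pH pH value (vectorised).
#' @param pk pK table (see [pk_table_default()]).
#' @return Net charge (elementary charges), one value per pH.
#' @export
net_charge <- function(seq, pH, pk = pk_table_default()) {
  stopifnot(nchar(seq) >= 1L)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  counts <- c(Nterm = 1, Cterm = 1, table(chars))
  total <- numeric(length(pH))
  for (i in seq_len(nrow(pk))) {
    g <- pk$group[i]
    n_g <- if (g %in% names(counts)) as.numeric(counts[[g]]) else 0
    if (n_g == 0) next
    total <- total + if (pk$sign[i] > 0) {
      n_g / (1 + 10^(pH - pk$pk[i]))
    } else {
      -n_g / (1 + 10^(pk$pk[i] - pH))
    }
  }
  total
}

#' Isoelectric point of a protein sequence
#'
#' The pH at which the net charge crosses zero, located by bisection on
#' `[0, 14]` to `|charge| < tol`. The charge curve is strictly decreasing in
#' pH, so the root is unique.
#'
#' @inheritParams net_charge
#' @param tol Charge tolerance at the root.
#' @return pI in `[0, 14]`.
#' @export
isoelectric_point <- function(seq, pk = pk_table_default(), tol = 1e-4) {
  lo <- 0; hi <- 14
  c_lo <- net_charge(seq, lo, pk)
  c_hi <- net_charge(seq, hi, pk)
  if (c_lo < 0) return(0)   # all-acidic edge cases
  if (c_hi > 0) return(14)
  # bisect to a narrow pH bracket; the charge there is far below `tol` even
  # where the titration curve is at its steepest
  repeat {
    mid <- (lo + hi) / 2
    cm <- net_charge(seq, mid, pk)
    if ((hi - lo) < 1e-6 && abs(cm) < tol) return(mid)
    if ((hi - lo) < 1e-12) return(mid)
    if (cm > 0) lo <- mid else hi <- mid
  }
}

#' Grand average of hydropathy (GRAVY)
#'
#' Arithmetic mean of per-residue hydropathy values over the sequence.
#'
#' @param seq Amino-acid string.
#' @param scale Named hydropathy scale (default [kyte_doolittle()]).
#' @return Mean hydropathy.
#' @export
gravy <- function(seq, scale = kyte_doolittle()) {
  stopifnot(nchar(seq) >= 1L)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  missing <- which(!(chars %in% names(scale)))
  if (length(missing)) {
    stop_scfv("residue '", chars[missing[1L]], "' at position ", missing[1L],
              " is not in the hydropathy scale", class = "invalid_residue")
  }
  mean(scale[chars])
}

#' Biophysical property table of a design library
#'
#' Computes the isoelectric point and GRAVY of every design concatenated
#' with its fixed partner chain.
#'
#' @param sequences Character vector of designed chain sequences.
#' @param partner Fixed partner-chain sequence.
#' @param design_is_heavy Logical; are the designs heavy chains?
#' @param ids Optional sequence ids.
#' @param pk pK table.
#' @param scale Hydropathy scale.
#' @return Data frame with `id`, `pI`, `gravy`.
#' @export
biophys_properties <- function(sequences, partner, design_is_heavy = TRUE,
                               ids = NULL, pk = pk_table_default(),
                               scale = kyte_doolittle()) {
  full <- vapply(sequences, concat_with_partner, character(1L),
                 partner = partner, design_is_heavy = design_is_heavy,
                 USE.NAMES = FALSE)
  data.frame(
    id = ids %||% sprintf("d%05d", seq_along(sequences)),
    pI = vapply(full, isoelectric_point, numeric(1L), pk = pk, USE.NAMES = FALSE),
    gravy = vapply(full, gravy, numeric(1L), scale = scale, USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}
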