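# Physicochemical residue properties used by the pseudo-amino-acid
# composition descriptors: hydrophobicity (Tanford scale as tabulated by
# Chou), hydrophilicity (Hopp-Woods) and side-chain mass. These are the
# canonical property triplet of type-1/type-2 PseAAC.

.RAW_PROPERTIES <- list(
  hydrophobicity = c(
    A =  0.62, C =  0.29, D = -0.90, E = -0.74, F =  1.19,
    G =  0.48, H = -0.40, I =  1.38, K = -1.50, L =  1.06,
    M =  0.64, N = -0.78, P =  0.12, Q = -0.85, R = -2.53,
    S = -0.18, T = -0.05, V =  1.08, W =  0.81, Y =  0.26),
  hydrophilicity = c(
    A = -0.5, C = -1.0, D =  3.0, E =  3.0, F = -2.5,
    G =  0.0, H = -0.5, I = -1.8, K =  3.0, L = -1.8,
    M = -1.3, N =  0.2, P =  0.0, Q =  0.2, R =  3.0,
    S =  0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3),
  side_chain_mass = c(
    A =  15.0, C =  47.0, D =  59.0, E =  73.0, F =  91.0,
    G =   1.0, H =  82.0, I =  57.0, K =  73.0, L =  57.0,
    M =  75.0, N =  58.0, P =  42.0, Q =  72.0, R = 101.0,
    S =  31.0, T =  45.0, V =  43.0, W = 130.0, Y = 107.0))

#' Standardized residue property table for PseAAC
#'
#' Returns the three-property table (hydrophobicity, hydrophilicity,
#' side-chain mass) with each property standardized to zero mean and unit
#' variance over the 20 standard residues — the normalisation PseAAC
#' requires before computing sequence-order correlation factors.
#'
#' @return A 20 x 3 numeric matrix, rows named by residue, columns
#'   `hydrophobicity`, `hydrophilicity`, `side_chain_mass`.
#' @export
pseaac_properties <- function() {
  std <- function(v) {
    v <- v[AA_ALPHABET]
    (v - mean(v)) / sqrt(sum((v - mean(v))^2) / length(v))
  }
  m <- vapply(.RAW_PROPERTIES, std, numeric(20))
  rownames(m) <- AA_ALPHABET
  m
}
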