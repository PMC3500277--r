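# Amino acid vocabulary and smoothed threshold transitions.

#' The 20 canonical amino acid three-letter codes
#' @export
AA_TYPES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
              "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
              "THR", "TRP", "TYR", "VAL")

# Approximate natural frequencies (Swiss-Prot composition), used by the
# synthetic sequence generator only.
.AA_FREQ <- c(ALA = 8.3, ARG = 5.5, ASN = 4.1, ASP = 5.5, CYS = 1.4,
              GLN = 3.9, GLU = 6.7, GLY = 7.1, HIS = 2.3, ILE = 5.9,
              LEU = 9.7, LYS = 5.8, MET = 2.4, PHE = 3.9, PRO = 4.7,
              SER = 6.6, THR = 5.3, TRP = 1.1, TYR = 2.9, VAL = 6.9)

#' Unordered amino acid pair key
#'
#' Canonical key ("ALA:VAL") for the 210 unordered type pairs.
#' @param a,b three-letter codes (vectorized).
#' @export
aa_pair_key <- function(a, b) {
  ifelse(a <= b, paste(a, b, sep = ":"), paste(b, a, sep = ":"))
}

#' Smoothed step-down transition
#'
#' Half-cosine transition used to smooth hard distance cutoffs: 1 at or
#' below `lo`, 0 at or beyond `hi`, half-cosine in between. Continuously
#' differentiable in `x`.
#'
#' @param x numeric vector (e.g. distances in Angstrom).
#' @param lo,hi lower/upper thresholds, `lo < hi`.
#' @return weights in `[0, 1]`.
#' @export
transition_down <- function(x, lo, hi) {
  stopifnot(lo < hi)
  w <- (cos(pi * (x - lo) / (hi - lo)) + 1) / 2
  w[x <= lo] <- 1
  w[x >= hi] <- 0
  w
}

#' Rebuild an ideal C-beta position from backbone atoms
#'
#' Places the side-chain anchor at the ideal tetrahedral C-beta position
#' given N, CA and C coordinates (bond length about 1.53 Angstrom,
#' L-configuration). For glycine the same direction is used with a 1.09
#' Angstrom C-H bond to approximate the H-alpha2 position.
#'
#' @param n,ca,c backbone coordinates (3-vectors).
#' @param length bond length from CA in Angstrom.
#' @return 3-vector anchor coordinate.
#' @export
reconstruct_cbeta <- function(n, ca, c, length = NULL) {
  b <- ca - n
  cvec <- c - ca
  a <- vcross(b, cvec)
  d <- -0.58273431 * a + 0.56802827 * b - 0.54067466 * cvec
  if (is.null(length)) ca + d else ca + length * vunit(d)
}

#' Amino acid alphabet of the synthetic fixture world
#'
#' Eight frequent residue types spanning the small/large hydrophobic,
#' aromatic, polar, charged and glycine classes. The fixture generator
#' samples sequences from this reduced alphabet (at natural relative
#' frequencies) so that the 210-type pair statistics are populated at
#' fixture-database scale; real training databases provide the full
#' 20-type diversity.
#' @export
FIXTURE_ALPHABET <- c("ALA", "GLY", "LEU", "VAL", "PHE", "SER", "GLU", "LYS")

# Draw a random sequence with natural relative composition over `alphabet`.
random_sequence <- function(n, alphabet = FIXTURE_ALPHABET) {
  sample(alphabet, n, replace = TRUE, prob = .AA_FREQ[alphabet])
}
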