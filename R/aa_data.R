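# Amino-acid lookup tables shared across modules.

AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

AA_ONE_TO_THREE <- structure(names(AA_THREE_TO_ONE), names = unname(AA_THREE_TO_ONE))

# Kyte & Doolittle hydropathy values
KD_SCALE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

# Five-way side-chain classification
SIDE_CHAIN_CLASS <- c(
  D = "negative", E = "negative",
  R = "positive", H = "positive", K = "positive",
  S = "polar-uncharged", T = "polar-uncharged", N = "polar-uncharged",
  Q = "polar-uncharged",
  A = "hydrophobic", V = "hydrophobic", I = "hydrophobic", L = "hydrophobic",
  M = "hydrophobic", F = "hydrophobic", Y = "hydrophobic", W = "hydrophobic",
  C = "special", G = "special", P = "special"
)

# Approximate CA -> side-chain-centroid distances (Angstrom) used to place
# the single side-chain pseudo-atom; Gly carries no pseudo-atom.
SC_CENTROID_DIST <- c(
  A = 1.5, R = 4.1, N = 2.5, D = 2.5, C = 2.1,
  Q = 3.1, E = 3.1, G = 0.0, H = 3.2, I = 2.3,
  L = 2.6, K = 3.5, M = 3.0, F = 3.4, P = 1.9,
  S = 1.9, T = 1.9, W = 3.9, Y = 3.8, V = 2.0
)

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Classify an amino acid by the chemical nature of its side chain
#'
#' Partitions the 20 standard amino acids into five classes: negatively
#' charged (D, E), positively charged (R, H, K), polar uncharged
#' (S, T, N, Q), hydrophobic (A, V, I, L, M, F, Y, W) and special cases
#' (C, G, P).
#'
#' @param residue Character vector of 1-letter amino-acid codes.
#' @return Character vector of class labels, one of `"negative"`,
#'   `"positive"`, `"polar-uncharged"`, `"hydrophobic"`, `"special"`.
#' @examples
#' classify_side_chain("D")
#' classify_side_chain(c("H", "G", "V"))
#' @export
classify_side_chain <- function(residue) {
  residue <- toupper(as.character(residue))
  bad <- setdiff(unique(residue), names(SIDE_CHAIN_CLASS))
  if (length(bad) > 0) {
    stop("non-standard amino acid code(s): ", paste(bad, collapse = ", "))
  }
  unname(SIDE_CHAIN_CLASS[residue])
}

# genetic code as a named vector codon -> 1-letter AA ('*' for stops)
genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}
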