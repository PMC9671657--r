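# Codon-family simulator with controlled dN/dS. Each taxon evolves
# independently from the root under uniform per-site nucleotide proposals;
# proposals creating a stop codon are rejected, non-synonymous proposals
# are accepted with probability omega, synonymous ones always. Uniform
# proposals are chosen (over a transition-biased kernel) because the
# NG86 estimator's equal-weight site counting assumes exactly that
# mutation process, so the simulator's omega is recoverable by
# construction.

#' Specification for a simulated codon family
#'
#' @param root Codon sequence (length divisible by 3, no stop codons).
#' @param n_taxa Number of taxa to evolve independently from the root.
#' @param branch_length Expected accepted substitutions per codon on each
#'   root-to-taxon branch.
#' @param omega Target dN/dS in `[0, 1]`: acceptance probability of
#'   non-synonymous proposals.
#' @param seed Integer seed.
#' @return Object of class `acr3_codon_spec`.
#' @export
codon_sim_spec <- function(root, n_taxa = 2, branch_length = 0.3,
                           omega = 0.13, seed = 1) {
  root <- toupper(gsub("\\s", "", root))
  if (nchar(root) %% 3 != 0) {
    stop("parameter error: root length must be divisible by 3")
  }
  codons <- substring(root, seq(1, nchar(root), 3), seq(3, nchar(root), 3))
  if (any(codons %in% STOP_CODONS)) {
    stop("parameter error: root contains stop codon(s)")
  }
  if (!all(strsplit(root, "")[[1]] %in% c("A", "C", "G", "T"))) {
    stop("parameter error: root must be an ACGT sequence")
  }
  if (omega < 0 || omega > 1) {
    stop("parameter error: omega must be in [0, 1]")
  }
  if (n_taxa < 1) stop("parameter error: n_taxa must be >= 1")
  if (branch_length < 0) stop("parameter error: branch_length must be >= 0")
  structure(list(root = root, n_taxa = as.integer(n_taxa),
                 branch_length = branch_length, omega = omega,
                 seed = as.integer(seed)),
            class = "acr3_codon_spec")
}

#' Draw a random stop-free coding sequence
#'
#' Convenience helper for building simulation roots.
#'
#' @param n_codons Number of codons.
#' @param seed Integer seed.
#' @return An ACGT string of length `3 * n_codons` with no stop codons.
#' @export
random_cds <- function(n_codons, seed = 1) {
  sense <- setdiff(names(genetic_code()), STOP_CODONS)
  with_seed(seed, paste(sample(sense, n_codons, replace = TRUE),
                        collapse = ""))
}

evolve_branch <- function(codons, n_target, omega) {
  gc <- genetic_code()
  nt <- c("A", "C", "G", "T")
  accepted <- 0L
  attempts <- 0L
  max_attempts <- max(1000L, 200L * n_target)
  while (accepted < n_target && attempts < max_attempts) {
    attempts <- attempts + 1L
    ci <- sample.int(length(codons), 1L)
    pos <- sample.int(3L, 1L)
    old <- codons[ci]
    base <- substr(old, pos, pos)
    new_base <- sample(setdiff(nt, base), 1L)
    new <- old
    substr(new, pos, pos) <- new_base
    if (new %in% STOP_CODONS) next
    if (gc[[new]] != gc[[old]]) {
      if (stats::runif(1) >= omega) next
    }
    codons[ci] <- new
    accepted <- accepted + 1L
  }
  codons
}

#' Simulate a codon family under purifying selection
#'
#' @param spec [codon_sim_spec()] object.
#' @return List of [seq_record()]s: the root (id `"root"`) followed by the
#'   evolved taxa (ids `"t1"`, `"t2"`, ...). Deterministic given the seed.
#' @export
simulate_codon_family <- function(spec) {
  stopifnot(inherits(spec, "acr3_codon_spec"))
  root_codons <- substring(spec$root, seq(1, nchar(spec$root), 3),
                           seq(3, nchar(spec$root), 3))
  n_codons <- length(root_codons)
  with_seed(spec$seed, {
    taxa <- vector("list", spec$n_taxa)
    for (t in seq_len(spec$n_taxa)) {
      n_target <- stats::rpois(1, spec$branch_length * n_codons)
      evolved <- evolve_branch(root_codons, n_target, spec$omega)
      taxa[[t]] <- seq_record(paste0("t", t), paste(evolved, collapse = ""))
    }
    c(list(seq_record("root", spec$root)), taxa)
  })
}
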