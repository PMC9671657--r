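# Multiple alignments, codon back-translation, and the variable-position
# (non-conserved residue) table.

#' Assemble records into a multiple alignment
#'
#' Records must already share a common gapped length (gap-free families,
#' e.g. from the codon simulator, qualify trivially).
#'
#' @param records List of >= 2 [seq_record()]s with equal gapped lengths.
#' @param alphabet `"protein"` or `"nucleotide"` (`NULL` to guess).
#' @return Object of class `acr3_alignment`: list with `records`,
#'   `alphabet`, `n_col`.
#' @export
as_alignment <- function(records, alphabet = NULL) {
  if (length(records) < 2) stop("input error: alignment needs >= 2 records")
  lens <- vapply(records, function(r) nchar(r$residues), 1L)
  if (length(unique(lens)) != 1) {
    stop("input error: records have unequal gapped lengths; align them first")
  }
  if (is.null(alphabet)) {
    alphabet <- guess_alphabet(records[[1]]$residues)
  }
  structure(list(records = records, alphabet = alphabet,
                 n_col = lens[[1]]),
            class = "acr3_alignment")
}

#' @export
print.acr3_alignment <- function(x, ...) {
  cat(sprintf("<acr3_alignment> %s: %d records x %d columns\n",
              x$alphabet, length(x$records), x$n_col))
  invisible(x)
}

#' Align protein sequences with MAFFT (if available)
#'
#' Sequences of equal length are stacked as-is; unequal-length sets are
#' aligned with the external `mafft` binary when it is on `PATH`.
#'
#' @param records List of [seq_record()]s.
#' @return [as_alignment()] object.
#' @export
align_proteins <- function(records) {
  lens <- vapply(records, function(r) nchar(r$residues), 1L)
  if (length(unique(lens)) == 1) return(as_alignment(records, "protein"))
  mafft <- Sys.which("mafft")
  if (!nzchar(mafft)) {
    stop("input error: unequal-length sequences and mafft not available")
  }
  fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".fa")
  write_fasta(records, fin)
  status <- system2(mafft, c("--auto", "--quiet", fin),
                    stdout = fout, stderr = FALSE)
  if (status != 0) stop("mafft failed with status ", status)
  as_alignment(read_fasta(fout), "protein")
}

translate_codons <- function(cds) {
  gc <- genetic_code()
  codons <- codon_split(cds)
  paste(gc[codons], collapse = "")
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each amino-acid column is expanded to its source codon; alignment gaps
#' expand to `---`, so gaps occur in whole-codon triplets. A trailing stop
#' codon on a CDS is stripped before checking that the CDS translates to
#' the ungapped protein under the standard code.
#'
#' @param protein_aln [as_alignment()] protein alignment.
#' @param cds Named list (or list of [seq_record()]s) mapping record id to
#'   its coding sequence.
#' @return Object of class `acr3_codon_alignment`: an `acr3_alignment`
#'   whose records are gapped CDS rows (column count divisible by 3).
#' @export
back_translate_alignment <- function(protein_aln, cds) {
  stopifnot(inherits(protein_aln, "acr3_alignment"))
  if (protein_aln$alphabet != "protein") {
    stop("input error: protein alignment required")
  }
  cds_idx <- if (is.list(cds) && !is.null(cds[[1]]$id)) seq_index(cds)
  else cds
  out <- vector("list", length(protein_aln$records))
  for (k in seq_along(protein_aln$records)) {
    rec <- protein_aln$records[[k]]
    if (!rec$id %in% names(cds_idx)) {
      stop("input error: no CDS for record '", rec$id, "'")
    }
    cdsk <- cds_idx[[rec$id]]
    if (inherits(cdsk, "acr3_seq")) cdsk <- cdsk$residues
    cdsk <- toupper(cdsk)
    prot <- gsub("-", "", rec$residues)
    codons <- codon_split(cdsk)
    if (length(codons) == nchar(prot) + 1 &&
        codons[length(codons)] %in% STOP_CODONS) {
      codons <- codons[-length(codons)]
    }
    if (length(codons) != nchar(prot)) {
      stop("input error: CDS length mismatch for record '", rec$id,
           "' (", 3 * length(codons), " nt vs ", nchar(prot), " aa)")
    }
    if (any(codons %in% STOP_CODONS)) {
      stop("input error: internal stop codon in CDS of '", rec$id, "'")
    }
    gc <- genetic_code()
    trans <- gc[codons]
    mism <- which(trans != strsplit(prot, "")[[1]])
    if (length(mism) > 0) {
      stop("input error: CDS of '", rec$id,
           "' does not translate to its protein at position ", mism[1])
    }
    cols <- strsplit(rec$residues, "")[[1]]
    expanded <- character(length(cols))
    ci <- 0L
    for (i in seq_along(cols)) {
      if (cols[i] == "-") expanded[i] <- "---"
      else {
        ci <- ci + 1L
        expanded[i] <- codons[ci]
      }
    }
    out[[k]] <- seq_record(rec$id, paste(expanded, collapse = ""),
                           rec$description)
  }
  aln <- as_alignment(out, "nucleotide")
  class(aln) <- c("acr3_codon_alignment", class(aln))
  attr(aln, "source_protein_alignment") <- protein_aln
  aln
}

#' Table of non-conserved (variable) alignment positions
#'
#' Returns every column with at least two distinct non-gap residues.
#' Positions are 1-based alignment coordinates (equal to sequence
#' coordinates for gap-free alignments). Each row carries the residue
#' observed in every record, the side-chain class of the consensus
#' (majority) residue, and, when a topology is supplied, the E/M/C
#' location of the position.
#'
#' @param aln [as_alignment()] protein alignment.
#' @param topology Optional `acr3_topology` (from [assign_compartments()])
#'   giving per-residue E/M/C locations in alignment coordinates.
#' @return data.frame with columns `position`, one column per record id,
#'   `consensus`, `side_chain_class` and `location` (NA without topology).
#' @export
variable_positions <- function(aln, topology = NULL) {
  stopifnot(inherits(aln, "acr3_alignment"))
  if (aln$alphabet != "protein") stop("input error: protein alignment required")
  ids <- vapply(aln$records, `[[`, "", "id")
  mat <- do.call(rbind, lapply(aln$records,
                               function(r) strsplit(r$residues, "")[[1]]))
  rows <- list()
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    states <- unique(col[col != "-"])
    if (length(states) < 2) next
    tab <- sort(table(col[col != "-"]), decreasing = TRUE)
    consensus <- names(tab)[1]
    cls <- if (consensus %in% names(SIDE_CHAIN_CLASS)) {
      classify_side_chain(consensus)
    } else NA_character_
    loc <- NA_character_
    if (!is.null(topology) && j <= length(topology$location)) {
      loc <- topology$location[j]
    }
    row <- as.list(col)
    names(row) <- ids
    rows[[length(rows) + 1]] <- c(list(position = j), row,
                                  list(consensus = consensus,
                                       side_chain_class = cls,
                                       location = loc))
  }
  if (length(rows) == 0) {
    out <- data.frame(position = integer(0))
    for (id in ids) out[[id]] <- character(0)
    out$consensus <- character(0)
    out$side_chain_class <- character(0)
    out$location <- character(0)
    return(out)
  }
  do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)
  }))
}
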