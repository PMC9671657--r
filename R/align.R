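# Pairwise global alignment and identity. The Needleman-Wunsch engine is
# Biostrings::pairwiseAlignment with fixed, reproducible scoring:
# BLOSUM62 / gap open 10 / extend 0.5 for protein, match +1 / mismatch 0 /
# same gaps for nucleotide.

guess_alphabet <- function(s) {
  letters <- unique(strsplit(gsub("-", "", toupper(s)), "")[[1]])
  if (all(letters %in% c("A", "C", "G", "T", "U", "N"))) "nucleotide"
  else "protein"
}

#' Global pairwise alignment
#'
#' @param a,b Sequences (strings or [seq_record()]s), ungapped.
#' @param alphabet `"protein"`, `"nucleotide"`, or `NULL` to guess.
#' @return List with gapped strings `a`, `b` and the alignment `score`.
#' @export
nw_align <- function(a, b, alphabet = NULL) {
  if (inherits(a, "acr3_seq")) a <- a$residues
  if (inherits(b, "acr3_seq")) b <- b$residues
  a <- toupper(a); b <- toupper(b)
  if (!nzchar(a) || !nzchar(b)) stop("input error: empty sequence")
  if (is.null(alphabet)) alphabet <- guess_alphabet(paste0(a, b))
  if (alphabet == "protein") {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5)
  } else {
    mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = 0, baseOnly = FALSE)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(gsub("U", "T", a)),
      Biostrings::DNAString(gsub("U", "T", b)),
      type = "global", substitutionMatrix = mat,
      gapOpening = 10, gapExtension = 0.5)
  }
  list(a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

#' Percent identity from global alignment
#'
#' Identity is the number of identical aligned columns divided by the
#' total number of alignment columns (pairwise global alignments contain
#' no dual-gap columns), times 100.
#'
#' @inheritParams nw_align
#' @return Percentage in `[0, 100]`.
#' @examples
#' pairwise_identity("ACGT", "ACGA")  # 75
#' @export
pairwise_identity <- function(a, b, alphabet = NULL) {
  al <- nw_align(a, b, alphabet)
  ca <- strsplit(al$a, "")[[1]]
  cb <- strsplit(al$b, "")[[1]]
  keep <- !(ca == "-" & cb == "-")
  100 * sum(ca[keep] == cb[keep]) / sum(keep)
}

#' All-vs-all identity distance matrix
#'
#' Computes pairwise global-alignment identity for every pair of records
#' and stores the result as a distance, `100 - identity`.
#'
#' @param records List of >= 2 [seq_record()]s sharing an alphabet.
#' @param alphabet Passed to [pairwise_identity()].
#' @return Object of class `acr3_dist`: list with `labels`, symmetric
#'   `values` matrix (zero diagonal) and `metric_name`.
#' @export
identity_matrix <- function(records, alphabet = NULL) {
  if (length(records) < 2) stop("input error: need >= 2 records")
  labels <- vapply(records, `[[`, "", "id")
  n <- length(records)
  v <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- 100 - pairwise_identity(records[[i]], records[[j]], alphabet)
      v[i, j] <- d
      v[j, i] <- d
    }
  }
  distance_matrix(labels, v, "100-identity")
}

#' Construct a labeled distance matrix
#'
#' @param labels Character vector of labels.
#' @param values Symmetric square matrix of non-negative finite values
#'   with zero diagonal.
#' @param metric_name Name of the metric.
#' @return Object of class `acr3_dist`.
#' @export
distance_matrix <- function(labels, values, metric_name = "distance") {
  values <- as.matrix(values)
  if (nrow(values) != length(labels) || ncol(values) != length(labels)) {
    stop("input error: values must be square with one row per label")
  }
  if (!all(is.finite(values))) stop("input error: non-finite distance")
  if (max(abs(values - t(values))) > 1e-8) {
    stop("input error: distance matrix not symmetric")
  }
  if (any(abs(diag(values)) > 1e-8)) {
    stop("input error: distance matrix diagonal must be zero")
  }
  dimnames(values) <- list(labels, labels)
  structure(list(labels = labels, values = values,
                 metric_name = metric_name),
            class = "acr3_dist")
}

#' @export
print.acr3_dist <- function(x, ...) {
  cat(sprintf("<acr3_dist> %s: %d labels\n", x$metric_name,
              length(x$labels)))
  print(round(x$values, 3))
  invisible(x)
}
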