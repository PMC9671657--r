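# Nei-Gojobori (1986) pairwise dN/dS with Jukes-Cantor correction.
#
# Conventions (documented in the methods vignette): mutations creating a
# stop codon count as non-synonymous in per-site counting; substitution
# pathways passing through a stop codon are excluded from the
# equal-weight pathway average (if every pathway is blocked, all are
# used). Codon pairs with a gap in either sequence are skipped pairwise.

.ng_cache <- new.env(parent = emptyenv())

nt_alphabet <- c("A", "C", "G", "T")

codon_split <- function(x) {
  substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
}

# per-codon synonymous site count (0..3); non-synonymous = 3 - syn
ng_syn_sites <- function() {
  if (!is.null(.ng_cache$syn_sites)) return(.ng_cache$syn_sites)
  gc <- genetic_code()
  sense <- setdiff(names(gc), STOP_CODONS)
  out <- stats::setNames(numeric(length(sense)), sense)
  for (cod in sense) {
    s <- 0
    for (pos in 1:3) {
      base <- substr(cod, pos, pos)
      for (b in setdiff(nt_alphabet, base)) {
        alt <- cod
        substr(alt, pos, pos) <- b
        # changes to stop codons count as non-synonymous
        if (!(alt %in% STOP_CODONS) && gc[[alt]] == gc[[cod]]) s <- s + 1 / 3
      }
    }
    out[[cod]] <- s
  }
  .ng_cache$syn_sites <- out
  out
}

# pathway-averaged (syn, nonsyn) observed differences for one codon pair
ng_pair_diff_single <- function(c1, c2, gc) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos)
  if (nd == 0) return(c(syn = 0, nonsyn = 0))
  perms <- switch(as.character(nd),
                  "1" = list(pos),
                  "2" = list(pos, rev(pos)),
                  "3" = {
                    p <- pos
                    list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
                         p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
                  })
  count_path <- function(order) {
    cur <- c1
    s <- 0; n <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (nxt %in% STOP_CODONS) return(NULL)
      if (gc[[nxt]] == gc[[cur]]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    c(s, n)
  }
  res <- lapply(perms, count_path)
  ok <- res[!vapply(res, is.null, TRUE)]
  if (length(ok) == 0) {
    # all pathways pass through stops; fall back to counting through them
    ok <- lapply(perms, function(order) {
      cur <- c1; s <- 0; n <- 0
      for (p in order) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (nxt %in% STOP_CODONS || gc[[nxt]] != gc[[cur]]) n <- n + 1
        else s <- s + 1
        cur <- nxt
      }
      c(s, n)
    })
  }
  m <- do.call(rbind, ok)
  c(syn = mean(m[, 1]), nonsyn = mean(m[, 2]))
}

# cached lookup tables: 61x61 matrices of pathway-averaged syn/nonsyn diffs
ng_pair_tables <- function() {
  if (!is.null(.ng_cache$pair_syn)) {
    return(list(syn = .ng_cache$pair_syn, nonsyn = .ng_cache$pair_nonsyn))
  }
  gc <- genetic_code()
  sense <- setdiff(names(gc), STOP_CODONS)
  k <- length(sense)
  syn <- matrix(0, k, k, dimnames = list(sense, sense))
  nonsyn <- syn
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      d <- ng_pair_diff_single(sense[i], sense[j], gc)
      syn[i, j] <- d[["syn"]]
      nonsyn[i, j] <- d[["nonsyn"]]
    }
  }
  .ng_cache$pair_syn <- syn
  .ng_cache$pair_nonsyn <- nonsyn
  list(syn = syn, nonsyn = nonsyn)
}

jukes_cantor <- function(p) {
  if (p >= 3 / 4) {
    stop("saturation error: proportion of differences ", signif(p, 4),
         " >= 3/4; Jukes-Cantor correction undefined")
  }
  -3 / 4 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori (1986) dN/dS between two codon sequences
#'
#' Synonymous and non-synonymous sites are counted per codon and averaged
#' over the two sequences; observed differences are averaged with equal
#' weight over all minimal substitution pathways (stop-passing pathways
#' excluded); the Jukes-Cantor correction
#' `d = -(3/4) log(1 - 4p/3)` is applied to both proportions.
#'
#' @param a,b Equal-length, in-frame codon sequences (strings or
#'   [seq_record()]s). Gapped alignment rows are accepted; codon pairs
#'   with a gap in either sequence are skipped.
#' @return Object of class `acr3_ng86`: list with `pair`, `dN`, `dS`,
#'   `ratio` (`NA` when `dS == 0`), site counts `N`, `S`, observed
#'   difference counts `Nd`, `Sd`, and `n_codons_compared`.
#' @examples
#' nei_gojobori("TTA", "TTG")  # synonymous Leu change: dN = 0
#' @export
nei_gojobori <- function(a, b) {
  ida <- "a"; idb <- "b"
  if (inherits(a, "acr3_seq")) { ida <- a$id; a <- a$residues }
  if (inherits(b, "acr3_seq")) { idb <- b$id; b <- b$residues }
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("input error: sequences differ in length")
  if (nchar(a) %% 3 != 0) stop("input error: length not divisible by 3")
  ca <- codon_split(a)
  cb <- codon_split(b)
  gap <- grepl("-", ca) | grepl("-", cb)
  ca <- ca[!gap]; cb <- cb[!gap]
  if (length(ca) == 0) stop("degenerate-input error: no comparable codons")
  if (any(ca %in% STOP_CODONS) || any(cb %in% STOP_CODONS)) {
    stop("input error: internal stop codon in compared codons")
  }
  sites <- ng_syn_sites()
  if (!all(c(ca, cb) %in% names(sites))) {
    stop("input error: non-ACGT codon encountered")
  }
  S <- (sum(sites[ca]) + sum(sites[cb])) / 2
  N <- 3 * length(ca) - S
  tabs <- ng_pair_tables()
  idx <- cbind(match(ca, rownames(tabs$syn)), match(cb, colnames(tabs$syn)))
  Sd <- sum(tabs$syn[idx])
  Nd <- sum(tabs$nonsyn[idx])
  if (S <= 0) stop("degenerate-input error: zero synonymous sites")
  dS <- jukes_cantor(Sd / S)
  dN <- jukes_cantor(Nd / N)
  structure(list(pair = c(ida, idb), dN = dN, dS = dS,
                 ratio = if (dS > 0) dN / dS else NA_real_,
                 N = N, S = S, Nd = Nd, Sd = Sd,
                 n_codons_compared = length(ca)),
            class = "acr3_ng86")
}

#' @export
print.acr3_ng86 <- function(x, ...) {
  cat(sprintf("<acr3_ng86> %s vs %s: dN = %.4f, dS = %.4f, dN/dS = %s\n",
              x$pair[1], x$pair[2], x$dN, x$dS,
              if (is.na(x$ratio)) "undefined" else sprintf("%.4f", x$ratio)))
  invisible(x)
}

#' Pairwise selection statistics against a reference sequence
#'
#' Runs [nei_gojobori()] for every record against `reference_id`.
#'
#' @param records List of codon-aligned [seq_record()]s.
#' @param reference_id Id of the reference record.
#' @return data.frame with one row per non-reference record: `id`, `dN`,
#'   `dS`, `ratio`.
#' @export
selection_vs_reference <- function(records, reference_id) {
  idx <- seq_index(records)
  if (!reference_id %in% names(idx)) {
    stop("input error: reference id '", reference_id, "' not found")
  }
  ref <- idx[[reference_id]]
  others <- idx[names(idx) != reference_id]
  rows <- lapply(others, function(r) {
    s <- nei_gojobori(r, ref)
    data.frame(id = r$id, dN = s$dN, dS = s$dS, ratio = s$ratio,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
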