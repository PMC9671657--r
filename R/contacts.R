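# Alpha-carbon contact maps and aligned contact-map differencing.

#' Build an alpha-carbon contact map
#'
#' Residue pair (i, j), i < j, is a contact iff the CA-CA distance is
#' less than or equal to `cutoff` (inclusive boundary). Sequence-neighbor
#' pairs (|i - j| = 1) are retained.
#'
#' @param model [structure_model()] object.
#' @param cutoff Contact distance cutoff in Angstrom (default 8.0).
#' @return Object of class `acr3_contact_map`: list with `model_id`,
#'   `contacts` (two-column matrix of residue index pairs, i < j),
#'   `distances`, `cutoff`, `n_residues`, `total` and the model
#'   `sequence`.
#' @export
build_contact_map <- function(model, cutoff = 8.0) {
  ca <- atom_coords(model, "CA")
  if (nrow(ca) != model$residue_count) {
    stop("structure error: residue(s) missing CA atom")
  }
  d <- as.matrix(stats::dist(ca))
  n <- nrow(d)
  sel <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  ord <- order(sel[, 1], sel[, 2])
  sel <- sel[ord, , drop = FALSE]
  contacts <- cbind(i = unname(sel[, 1]), j = unname(sel[, 2]))
  structure(list(model_id = model$model_id, contacts = contacts,
                 distances = d[sel], cutoff = cutoff, n_residues = n,
                 total = nrow(contacts), sequence = model$sequence),
            class = "acr3_contact_map")
}

#' @export
print.acr3_contact_map <- function(x, ...) {
  cat(sprintf("<acr3_contact_map> %s: %d contacts (CA, cutoff %.1f A, %d residues)\n",
              x$model_id, x$total, x$cutoff, x$n_residues))
  invisible(x)
}

contact_keys <- function(contacts) {
  if (nrow(contacts) == 0) return(character(0))
  paste(contacts[, 1], contacts[, 2], sep = "_")
}

#' Compare two contact maps through a sequence alignment
#'
#' Residues of the two models are matched by Needleman-Wunsch global
#' alignment of their sequences; a contact of one map is *common* when
#' both its residues align and the mapped pair is a contact of the other
#' map, and *unique* otherwise (contacts touching unaligned residues are
#' unique by definition). The partition identity
#' `|unique_a| + |common| = total_a` holds by construction.
#'
#' @param map_a,map_b [build_contact_map()] results with equal cutoffs.
#' @param seq_a,seq_b Optional sequences (default: the sequences stored in
#'   the maps).
#' @return Object of class `acr3_contact_diff`: counts (`total_a`,
#'   `total_b`, `n_unique_a`, `n_unique_b`, `n_common`), the contact sets
#'   (`unique_a`, `unique_b`, `common_a` in a-indices), and
#'   `residue_hotspots` (alignment-column positions ranked by count of
#'   differing contacts, ties broken by position).
#' @export
diff_contact_maps <- function(map_a, map_b, seq_a = NULL, seq_b = NULL) {
  if (!isTRUE(all.equal(map_a$cutoff, map_b$cutoff))) {
    stop("comparison error: contact maps built with different cutoffs")
  }
  if (is.null(seq_a)) seq_a <- map_a$sequence
  if (is.null(seq_b)) seq_b <- map_b$sequence
  al <- nw_align(seq_a, seq_b, "protein")
  ga <- strsplit(al$a, "")[[1]]
  gb <- strsplit(al$b, "")[[1]]
  # position maps: a-index -> b-index (NA if aligned to gap), and each ->
  # alignment column
  a_pos <- cumsum(ga != "-"); b_pos <- cumsum(gb != "-")
  a2b <- rep(NA_integer_, sum(ga != "-"))
  a2col <- rep(NA_integer_, sum(ga != "-"))
  b2col <- rep(NA_integer_, sum(gb != "-"))
  for (col in seq_along(ga)) {
    if (ga[col] != "-") {
      a2col[a_pos[col]] <- col
      if (gb[col] != "-") a2b[a_pos[col]] <- b_pos[col]
    }
    if (gb[col] != "-") b2col[b_pos[col]] <- col
  }
  keys_b <- contact_keys(map_b$contacts)
  ca <- map_a$contacts
  mapped_i <- a2b[ca[, 1]]
  mapped_j <- a2b[ca[, 2]]
  mappable <- !is.na(mapped_i) & !is.na(mapped_j)
  mapped_keys <- rep(NA_character_, nrow(ca))
  mapped_keys[mappable] <- paste(pmin(mapped_i[mappable], mapped_j[mappable]),
                                 pmax(mapped_i[mappable], mapped_j[mappable]),
                                 sep = "_")
  common_mask <- mappable & mapped_keys %in% keys_b
  common_a <- ca[common_mask, , drop = FALSE]
  unique_a <- ca[!common_mask, , drop = FALSE]
  # unique contacts of b: those not matched by any common a-contact
  common_keys_b <- mapped_keys[common_mask]
  cb <- map_b$contacts
  unique_b <- cb[!(contact_keys(cb) %in% common_keys_b), , drop = FALSE]
  # hotspots in alignment-column coordinates
  cols <- c(a2col[unique_a[, 1]], a2col[unique_a[, 2]],
            b2col[unique_b[, 1]], b2col[unique_b[, 2]])
  cols <- cols[!is.na(cols)]
  hot <- if (length(cols) > 0) {
    tab <- table(cols)
    df <- data.frame(position = as.integer(names(tab)),
                     n_differing = as.integer(tab))
    df[order(-df$n_differing, df$position), ]
  } else data.frame(position = integer(0), n_differing = integer(0))
  rownames(hot) <- NULL
  structure(list(
    model_ids = c(map_a$model_id, map_b$model_id),
    total_a = map_a$total, total_b = map_b$total,
    n_unique_a = nrow(unique_a), n_unique_b = nrow(unique_b),
    n_common = nrow(common_a),
    unique_a = unique_a, unique_b = unique_b, common_a = common_a,
    residue_hotspots = hot, cutoff = map_a$cutoff
  ), class = "acr3_contact_diff")
}

#' @export
print.acr3_contact_diff <- function(x, ...) {
  cat(sprintf(
    "<acr3_contact_diff> %s vs %s: totals %d/%d, unique %d/%d, common %d\n",
    x$model_ids[1], x$model_ids[2], x$total_a, x$total_b,
    x$n_unique_a, x$n_unique_b, x$n_common))
  invisible(x)
}
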