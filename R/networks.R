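# Residue interaction networks (radial neighborhoods) and geometric
# hydrogen-bond detection.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT", "H", "HA")

# side-chain donor/acceptor classification; covers both full-atom models
# (by atom name) and pseudo-atom models (single "SC" atom, by residue)
SC_DONOR_ATOM_NAMES <- c("NE", "NH1", "NH2", "ND1", "NE2", "NZ", "OG",
                         "OG1", "OH", "ND2", "SG", "NE1")
SC_ACCEPTOR_ATOM_NAMES <- c("OD1", "OD2", "OE1", "OE2", "OG", "OG1", "OH",
                            "ND1", "NE2", "SD")
SC_DONOR_RESIDUES <- c("SER", "THR", "TYR", "ASN", "GLN", "LYS", "ARG",
                       "HIS", "TRP", "CYS")
SC_ACCEPTOR_RESIDUES <- c("ASP", "GLU", "ASN", "GLN", "SER", "THR", "TYR",
                          "HIS")

#' Residues interacting within a radius of a focal residue
#'
#' Reports every other residue having at least one atom within `radius`
#' of the focal residue's selected atoms, with the minimal inter-atomic
#' distance. Sequence neighbors are included.
#'
#' @param model [structure_model()] object.
#' @param focal_residue 1-based residue index.
#' @param radius Neighborhood radius in Angstrom (default 5.0).
#' @param focal_atoms `"side_chain"` (default; falls back to CA for
#'   glycine, flagged), `"CA"`, or `"all"`.
#' @return Object of class `acr3_network`: list with `focal`,
#'   `partners` (data.frame `residue_index`, `residue_name`, `min_dist`),
#'   `radius`, `focal_atoms`, `ca_fallback`.
#' @export
interaction_network <- function(model, focal_residue, radius = 5.0,
                                focal_atoms = c("side_chain", "CA", "all")) {
  focal_atoms <- match.arg(focal_atoms)
  if (focal_residue < 1 || focal_residue > model$residue_count) {
    stop("input error: focal residue ", focal_residue, " out of range 1..",
         model$residue_count)
  }
  fa <- residue_atoms(model, focal_residue)
  ca_fallback <- FALSE
  sel <- switch(focal_atoms,
                all = fa,
                CA = fa[fa$atom_name == "CA", , drop = FALSE],
                side_chain = fa[!(fa$atom_name %in% BACKBONE_ATOMS) &
                                  !startsWith(fa$atom_name, "H"), ,
                                drop = FALSE])
  if (nrow(sel) == 0) {            # e.g. glycine side chain
    sel <- fa[fa$atom_name == "CA", , drop = FALSE]
    ca_fallback <- TRUE
  }
  fxyz <- as.matrix(sel[, c("x", "y", "z")])
  others <- model$atoms[model$atoms$residue_index != focal_residue, ,
                        drop = FALSE]
  oxyz <- as.matrix(others[, c("x", "y", "z")])
  # min distance from each other-atom to the focal set
  d2 <- matrix(Inf, nrow(oxyz), 1)
  mind <- rep(Inf, nrow(oxyz))
  for (k in seq_len(nrow(fxyz))) {
    dk <- sqrt(rowSums(sweep(oxyz, 2, fxyz[k, ])^2))
    mind <- pmin(mind, dk)
  }
  per_res <- tapply(mind, others$residue_index, min)
  keep <- per_res <= radius
  ridx <- as.integer(names(per_res))[keep]
  ord <- order(ridx)
  ridx <- ridx[ord]
  res_names <- model$atoms$residue_name[
    match(ridx, model$atoms$residue_index)]
  partners <- data.frame(residue_index = ridx, residue_name = res_names,
                         min_dist = as.numeric(per_res[keep])[ord])
  rownames(partners) <- NULL
  structure(list(focal = focal_residue, partners = partners,
                 radius = radius, focal_atoms = focal_atoms,
                 ca_fallback = ca_fallback),
            class = "acr3_network")
}

#' @export
print.acr3_network <- function(x, ...) {
  cat(sprintf("<acr3_network> residue %d: %d partner(s) within %.1f A%s\n",
              x$focal, nrow(x$partners), x$radius,
              if (x$ca_fallback) " (CA fallback)" else ""))
  invisible(x)
}

#' Detect intra-protein hydrogen bonds
#'
#' Geometric criterion in the spirit of VMD's defaults: a bond is called
#' when the donor-acceptor heavy-atom distance is at most `d_cutoff` and
#' the D-H...A angle deviates from linearity by at most `angle_cutoff`
#' degrees. Backbone amide hydrogens are reconstructed geometrically when
#' absent; side-chain donors without an explicit hydrogen fall back to a
#' heavy-atom-only distance criterion at `d_cutoff + 0.2` Angstrom
#' (flagged `"heavy-only"` in the output). Same-residue pairs are
#' excluded.
#'
#' @param model [structure_model()] object with backbone N, C, O atoms.
#' @param d_cutoff Donor-acceptor heavy-atom distance cutoff (Angstrom).
#' @param angle_cutoff Maximum deviation from a linear D-H...A geometry
#'   (degrees).
#' @return data.frame with one row per bond: `donor_res`, `donor_resname`,
#'   `donor_atom`, `acceptor_res`, `acceptor_resname`, `acceptor_atom`,
#'   `dist_da`, `dist_ha`, `angle`, `criterion`.
#' @export
detect_hbonds <- function(model, d_cutoff = 3.0, angle_cutoff = 20.0) {
  bb <- backbone_coords(model)
  n <- model$residue_count
  res_names <- model$atoms$residue_name[
    !duplicated(model$atoms$residue_index)]
  H <- reconstruct_amide_h(bb$N, bb$CA, bb$C, is_pro = res_names == "PRO")

  donors <- data.frame(res = seq_len(n), atom = "N",
                       x = bb$N[, 1], y = bb$N[, 2], z = bb$N[, 3],
                       hx = H[, 1], hy = H[, 2], hz = H[, 3],
                       stringsAsFactors = FALSE)
  donors <- donors[!is.na(donors$hx), , drop = FALSE]

  sc <- model$atoms[!(model$atoms$atom_name %in% BACKBONE_ATOMS) &
                      !startsWith(model$atoms$atom_name, "H"), ,
                    drop = FALSE]
  sc_donor <- sc[sc$atom_name %in% SC_DONOR_ATOM_NAMES |
                   (sc$atom_name == "SC" &
                      sc$residue_name %in% SC_DONOR_RESIDUES), ,
                 drop = FALSE]
  if (nrow(sc_donor) > 0) {
    donors <- rbind(donors, data.frame(
      res = sc_donor$residue_index, atom = sc_donor$atom_name,
      x = sc_donor$x, y = sc_donor$y, z = sc_donor$z,
      hx = NA_real_, hy = NA_real_, hz = NA_real_))
  }

  acceptors <- data.frame(res = seq_len(n), atom = "O",
                          x = bb$O[, 1], y = bb$O[, 2], z = bb$O[, 3],
                          stringsAsFactors = FALSE)
  sc_acc <- sc[sc$atom_name %in% SC_ACCEPTOR_ATOM_NAMES |
                 (sc$atom_name == "SC" &
                    sc$residue_name %in% SC_ACCEPTOR_RESIDUES), ,
               drop = FALSE]
  if (nrow(sc_acc) > 0) {
    acceptors <- rbind(acceptors, data.frame(
      res = sc_acc$residue_index, atom = sc_acc$atom_name,
      x = sc_acc$x, y = sc_acc$y, z = sc_acc$z))
  }

  out <- list()
  axyz <- as.matrix(acceptors[, c("x", "y", "z")])
  for (di in seq_len(nrow(donors))) {
    d <- donors[di, ]
    dxyz <- c(d$x, d$y, d$z)
    dist_da <- sqrt(rowSums(sweep(axyz, 2, dxyz)^2))
    has_h <- !is.na(d$hx)
    lim <- if (has_h) d_cutoff else d_cutoff + 0.2
    cand <- which(dist_da <= lim & acceptors$res != d$res)
    for (ai in cand) {
      a <- acceptors[ai, ]
      ang <- NA_real_
      dist_ha <- NA_real_
      if (has_h) {
        hxyz <- c(d$hx, d$hy, d$hz)
        ax <- c(a$x, a$y, a$z)
        ang <- angle_deg(dxyz, hxyz, ax)
        dist_ha <- vnorm(ax - hxyz)
        if (180 - ang > angle_cutoff) next
      }
      out[[length(out) + 1]] <- data.frame(
        donor_res = d$res, donor_resname = res_names[d$res],
        donor_atom = d$atom, acceptor_res = a$res,
        acceptor_resname = res_names[a$res], acceptor_atom = a$atom,
        dist_da = dist_da[ai], dist_ha = dist_ha, angle = ang,
        criterion = if (has_h) "geometric" else "heavy-only",
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(donor_res = integer(0), donor_resname = character(0),
                      donor_atom = character(0), acceptor_res = integer(0),
                      acceptor_resname = character(0),
                      acceptor_atom = character(0), dist_da = numeric(0),
                      dist_ha = numeric(0), angle = numeric(0),
                      criterion = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Hydrogen bonds in the neighborhood of a focal residue
#'
#' Subset of [detect_hbonds()] where the donor or the acceptor residue
#' has at least one atom within `radius` of any atom of the focal
#' residue (either-partner rule).
#'
#' @inheritParams detect_hbonds
#' @param focal_residue 1-based residue index.
#' @param radius Neighborhood radius (Angstrom).
#' @return data.frame as in [detect_hbonds()].
#' @export
hbonds_near_residue <- function(model, focal_residue, radius = 5.0,
                                d_cutoff = 3.0, angle_cutoff = 20.0) {
  if (focal_residue < 1 || focal_residue > model$residue_count) {
    stop("input error: focal residue out of range")
  }
  hb <- detect_hbonds(model, d_cutoff, angle_cutoff)
  if (nrow(hb) == 0) return(hb)
  fa <- residue_atoms(model, focal_residue)
  fxyz <- as.matrix(fa[, c("x", "y", "z")])
  others <- model$atoms
  mind <- rep(Inf, nrow(others))
  oxyz <- as.matrix(others[, c("x", "y", "z")])
  for (k in seq_len(nrow(fxyz))) {
    mind <- pmin(mind, sqrt(rowSums(sweep(oxyz, 2, fxyz[k, ])^2)))
  }
  near <- unique(others$residue_index[mind <= radius])
  hb[hb$donor_res %in% near | hb$acceptor_res %in% near, , drop = FALSE]
}
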