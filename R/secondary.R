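# Secondary structure from coordinates: Kabsch-Sander backbone H-bond
# energies with geometrically reconstructed amide hydrogens.

# amide H positions: on the bisector of the N-C(prev) and N-CA bonds at
# 1.01 Angstrom; residue 1 (and any Pro, which has no amide H) gets NA
reconstruct_amide_h <- function(N, CA, C, is_pro = NULL) {
  n <- nrow(N)
  H <- matrix(NA_real_, n, 3)
  if (n < 2) return(H)
  for (i in 2:n) {
    if (!is.null(is_pro) && is_pro[i]) next
    d <- unitv(unitv(N[i, ] - C[i - 1, ]) + unitv(N[i, ] - CA[i, ]))
    H[i, ] <- N[i, ] + 1.01 * d
  }
  H
}

backbone_coords <- function(model) {
  need <- c("N", "CA", "C", "O")
  out <- list()
  for (nm in need) {
    a <- model$atoms[model$atoms$atom_name == nm, , drop = FALSE]
    if (nrow(a) != model$residue_count) {
      miss <- setdiff(seq_len(model$residue_count), a$residue_index)
      stop("structure error: residue(s) missing backbone ", nm, " atom: ",
           paste(utils::head(miss, 5), collapse = ", "))
    }
    a <- a[order(a$residue_index), ]
    out[[nm]] <- as.matrix(a[, c("x", "y", "z")])
  }
  out
}

# Kabsch-Sander H-bond energy matrix: E[i, j] = energy of N(i)-H donating
# to C(j)=O acceptor, kcal/mol; NA where no H or |i-j| < 2
ks_energy_matrix <- function(model) {
  bb <- backbone_coords(model)
  n <- model$residue_count
  res_names <- model$atoms$residue_name[!duplicated(model$atoms$residue_index)]
  H <- reconstruct_amide_h(bb$N, bb$CA, bb$C, is_pro = res_names == "PRO")
  E <- matrix(NA_real_, n, n)
  q1q2f <- 0.084 * 332
  for (i in seq_len(n)) {
    if (any(is.na(H[i, ]))) next
    for (j in seq_len(n)) {
      if (abs(i - j) < 2) next
      r_on <- vnorm(bb$N[i, ] - bb$O[j, ])
      r_ch <- vnorm(H[i, ] - bb$C[j, ])
      r_oh <- vnorm(H[i, ] - bb$O[j, ])
      r_cn <- vnorm(bb$N[i, ] - bb$C[j, ])
      if (r_on > 7) next   # DSSP-style distance cutoff for speed
      E[i, j] <- q1q2f * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
    }
  }
  E
}

#' Assign secondary structure from backbone coordinates
#'
#' Simplified Kabsch-Sander assignment: amide hydrogens are reconstructed
#' geometrically, the electrostatic H-bond energy
#' `E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol is
#' evaluated for every donor-acceptor pair, and a bond is called when
#' `E < -0.5`. A residue is labeled `H` when it lies inside a run of
#' i -> i+4 turns, `E` when it participates in a reciprocal non-local
#' bridge, and `C` otherwise.
#'
#' @param model [structure_model()] with backbone N, CA, C, O for every
#'   residue.
#' @return Object of class `acr3_ss`: the per-residue label string with
#'   the H-bond matrix attached as attribute `"hbonds"` (logical matrix,
#'   donor row -> acceptor column).
#' @export
assign_secondary_structure <- function(model) {
  E <- ks_energy_matrix(model)
  n <- nrow(E)
  bond <- !is.na(E) & E < -0.5
  labels <- rep("C", n)
  # 4-turn at i: N(i+4) donates to O(i)
  turn4 <- rep(FALSE, n)
  for (i in seq_len(n - 4)) turn4[i] <- bond[i + 4, i]
  for (i in seq_len(max(0, n - 5))) {
    if (turn4[i] && turn4[i + 1]) labels[(i + 1):(i + 4)] <- "H"
  }
  # minimal bridge: reciprocal non-local bonds
  for (i in seq_len(n)) {
    if (labels[i] == "H") next
    js <- which(bond[i, ] & abs(seq_len(n) - i) >= 5)
    if (any(bond[cbind(js, i)])) labels[i] <- "E"
  }
  structure(paste(labels, collapse = ""), hbonds = bond, class = "acr3_ss")
}

#' @export
print.acr3_ss <- function(x, ...) {
  cat("<acr3_ss>", as.character(x), "\n")
  invisible(x)
}

#' @export
as.character.acr3_ss <- function(x, ...) unclass(x)[1]
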