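# Simplified single-snapshot MM-GBSA per-residue binding-energy
# decomposition: non-bonded molecular mechanics (Coulomb + LJ 12-6),
# Still pairwise generalized-Born polar solvation with intrinsic Born
# radii, and gamma * SASA non-polar solvation. Parameters come from a
# versioned simplified table bundled with the package (one pseudo-atom
# per side chain); absolute energies are decomposition-consistent, not
# force-field-accurate.

COULOMB_K <- 332.0636
GB_K <- 166.0

# backbone atom parameters: charge, LJ epsilon (kcal/mol), LJ rmin (A),
# GB radius (A); CA charge is adjusted per residue so charges sum to the
# residue's formal charge
BACKBONE_PARAMS <- data.frame(
  atom_name = c("N", "CA", "C", "O", "OXT"),
  charge = c(-0.40, 0.25, 0.55, -0.40, -0.40),
  eps = c(0.17, 0.1094, 0.086, 0.21, 0.21),
  rmin = c(1.824, 1.908, 1.908, 1.661, 1.661),
  gb_radius = c(1.55, 1.7, 1.7, 1.5, 1.5),
  stringsAsFactors = FALSE
)

ELEMENT_PARAMS <- data.frame(
  element = c("C", "N", "O", "S", "H"),
  eps = c(0.086, 0.17, 0.21, 0.25, 0.0157),
  rmin = c(1.908, 1.824, 1.661, 2.0, 0.6),
  gb_radius = c(1.7, 1.55, 1.5, 1.8, 1.2),
  stringsAsFactors = FALSE
)

#' Load the bundled simplified force-field parameter table
#'
#' @param path Optional path to an alternative table with the same
#'   columns (`residue`, `formal_charge`, `sc_eps`, `sc_rmin`,
#'   `sc_radius`).
#' @return Object of class `acr3_params`: list with `residues`
#'   (data.frame), `dielectric_in = 1`, `dielectric_out = 78.5`,
#'   `surface_tension = 0.0072` kcal/mol/A^2 and `probe_radius = 1.4` A.
#' @export
default_parameter_set <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "gb_params_v1.tsv", package = "acr3kit")
    if (!nzchar(path)) path <- file.path("inst", "extdata", "gb_params_v1.tsv")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(list(residues = tab, dielectric_in = 1, dielectric_out = 78.5,
                 surface_tension = 0.0072, probe_radius = 1.4,
                 version = basename(path)),
            class = "acr3_params")
}

#' Assign charges, LJ and GB parameters to a structure's atoms
#'
#' Backbone atoms receive fixed partial charges; the side-chain
#' pseudo-atom (or, for full-atom models, the side-chain heavy atoms in
#' equal shares) carries the residue's formal charge. After assignment
#' the CA charge of each residue is adjusted so that per-residue charges
#' sum exactly to the residue's formal charge.
#'
#' @param model [structure_model()] object.
#' @param params [default_parameter_set()] object.
#' @return The model with atom columns `charge`, `eps`, `rmin`,
#'   `gb_radius` added and the parameter set attached as attribute
#'   `"params"`.
#' @export
assign_parameters <- function(model, params = default_parameter_set()) {
  atoms <- model$atoms
  tab <- params$residues
  unknown <- setdiff(unique(atoms$residue_name), tab$residue)
  if (length(unknown) > 0) {
    stop("parameter error: residue(s) not in parameter table: ",
         paste(unknown, collapse = ", "))
  }
  n <- nrow(atoms)
  atoms$charge <- 0; atoms$eps <- 0.1; atoms$rmin <- 1.7
  atoms$gb_radius <- 1.7
  bbi <- match(atoms$atom_name, BACKBONE_PARAMS$atom_name)
  is_bb <- !is.na(bbi)
  atoms$charge[is_bb] <- BACKBONE_PARAMS$charge[bbi[is_bb]]
  atoms$eps[is_bb] <- BACKBONE_PARAMS$eps[bbi[is_bb]]
  atoms$rmin[is_bb] <- BACKBONE_PARAMS$rmin[bbi[is_bb]]
  atoms$gb_radius[is_bb] <- BACKBONE_PARAMS$gb_radius[bbi[is_bb]]
  is_h <- !is_bb & startsWith(atoms$atom_name, "H")
  if (any(is_h)) {
    atoms$charge[is_h] <- 0.1
    atoms$eps[is_h] <- 0.0157
    atoms$rmin[is_h] <- 0.6
    atoms$gb_radius[is_h] <- 1.2
  }
  ti <- match(atoms$residue_name, tab$residue)
  is_sc <- !is_bb & !is_h
  # pseudo-atom side chains take the table values directly
  is_pseudo <- is_sc & atoms$atom_name == "SC"
  atoms$charge[is_pseudo] <- tab$formal_charge[ti[is_pseudo]]
  atoms$eps[is_pseudo] <- tab$sc_eps[ti[is_pseudo]]
  atoms$rmin[is_pseudo] <- tab$sc_rmin[ti[is_pseudo]]
  atoms$gb_radius[is_pseudo] <- tab$sc_radius[ti[is_pseudo]]
  # full-atom side chains: element-based LJ/GB, equal charge shares
  is_full <- is_sc & atoms$atom_name != "SC"
  if (any(is_full)) {
    ei <- match(atoms$element[is_full], ELEMENT_PARAMS$element)
    ei[is.na(ei)] <- 1
    atoms$eps[is_full] <- ELEMENT_PARAMS$eps[ei]
    atoms$rmin[is_full] <- ELEMENT_PARAMS$rmin[ei]
    atoms$gb_radius[is_full] <- ELEMENT_PARAMS$gb_radius[ei]
    for (r in unique(atoms$residue_index[is_full])) {
      sel <- is_full & atoms$residue_index == r
      atoms$charge[sel] <- tab$formal_charge[ti[sel][1]] / sum(sel)
    }
  }
  # exact per-residue charge balance via the CA atom
  for (r in unique(atoms$residue_index)) {
    sel <- atoms$residue_index == r
    target <- tab$formal_charge[ti[sel][1]]
    excess <- sum(atoms$charge[sel]) - target
    ca_row <- which(sel & atoms$atom_name == "CA")[1]
    atoms$charge[ca_row] <- atoms$charge[ca_row] - excess
  }
  model$atoms <- atoms
  attr(model, "params") <- params
  model
}

as_atom_table <- function(x) {
  atoms <- if (inherits(x, "acr3_structure")) x$atoms else x
  if (nrow(atoms) == 0) stop("input error: zero atoms")
  if (is.null(atoms$gb_radius)) {
    stop("parameter error: parameters not assigned (run assign_parameters)")
  }
  atoms
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Sphere-point sampling with a deterministic golden-spiral point set.
#' Atom radii are the assigned GB radii; the solvent probe is added to
#' every radius.
#'
#' @param x Parameterized [structure_model()] or atom table.
#' @param probe Probe radius (Angstrom, default 1.4).
#' @param n_points Sample points per atom (default 960).
#' @return List with `total` (A^2), `per_atom`, and `per_residue`.
#' @export
compute_sasa <- function(x, probe = 1.4, n_points = 960) {
  atoms <- as_atom_table(x)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  r <- atoms$gb_radius + probe
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  per_atom <- numeric(n)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    surf <- sweep(pts * r[i], 2, xyz[i, ], `+`)
    if (length(nb) == 0) {
      acc <- n_points
    } else {
      buried <- rep(FALSE, n_points)
      for (j in nb) {
        dj <- sweep(surf, 2, xyz[j, ])
        dj2 <- rowSums(dj * dj)
        # strictly-inside points are buried; points exactly on the
        # neighbor surface (coincident spheres) go to the earlier atom
        buried <- buried | dj2 < r[j]^2 * (1 - 1e-9) |
          (abs(dj2 - r[j]^2) <= r[j]^2 * 1e-9 & j < i)
        if (all(buried)) break
      }
      acc <- sum(!buried)
    }
    per_atom[i] <- 4 * pi * r[i]^2 * acc / n_points
  }
  per_residue <- tapply(per_atom, atoms$residue_index, sum)
  list(total = sum(per_atom), per_atom = per_atom,
       per_residue = per_residue)
}

# pair exclusion mask: same residue, or peptide C(i)-N(i+1)
mm_excluded <- function(atoms) {
  n <- nrow(atoms)
  same_res <- outer(atoms$residue_index, atoms$residue_index, `==`)
  cn <- outer(atoms$atom_name == "C", atoms$atom_name == "N", `&`) &
    outer(atoms$residue_index, atoms$residue_index,
          function(a, b) b - a == 1)
  same_res | cn | t(cn)
}

#' Non-bonded molecular-mechanics energy of an atom group
#'
#' Coulomb (`332.0636 q_i q_j / (eps_in r)`) plus Lennard-Jones 12-6 over
#' all atom pairs in the group, excluding pairs within the same residue
#' and peptide-bonded C(i)-N(i+1) pairs of adjacent residues.
#'
#' @param x Parameterized model or atom table.
#' @param eps_in Internal dielectric constant (default 1).
#' @return `H_MM` in kcal/mol.
#' @export
mm_energy <- function(x, eps_in = 1) {
  atoms <- as_atom_table(x)
  n <- nrow(atoms)
  if (n < 2) return(0)
  d <- as.matrix(stats::dist(as.matrix(atoms[, c("x", "y", "z")])))
  excl <- mm_excluded(atoms)
  pair <- upper.tri(d) & !excl
  if (!any(pair)) return(0)
  if (any(d[pair] < 0.1)) {
    stop("clash error: atom pair closer than 0.1 Angstrom")
  }
  q <- atoms$charge
  coul <- COULOMB_K * outer(q, q) / (eps_in * d)
  epsij <- sqrt(outer(atoms$eps, atoms$eps))
  rminij <- outer(atoms$rmin, atoms$rmin, `+`)
  sr6 <- (rminij / d)^6
  lj <- epsij * (sr6^2 - 2 * sr6)
  sum(coul[pair]) + sum(lj[pair])
}

#' Generalized-Born polar solvation energy (Still pairwise form)
#'
#' `G = -166 (1/eps_in - 1/eps_out) sum_i sum_j q_i q_j / f_GB` with
#' `f_GB = sqrt(r^2 + R_i R_j exp(-r^2 / (4 R_i R_j)))`, self-terms
#' included (`f_GB = R_i` at `r = 0`). Effective Born radii are the
#' intrinsic GB radii (no descreening).
#'
#' @param x Parameterized model or atom table.
#' @param eps_in,eps_out Internal/solvent dielectric constants.
#' @return `G_polar` in kcal/mol.
#' @export
gb_energy <- function(x, eps_in = 1, eps_out = 78.5) {
  atoms <- as_atom_table(x)
  if (any(atoms$gb_radius <= 0 &
            !(atoms$atom_name == "SC" & atoms$residue_name == "GLY"))) {
    stop("parameter error: non-positive GB radius")
  }
  q <- atoms$charge
  R <- pmax(atoms$gb_radius, 1e-6)
  d <- as.matrix(stats::dist(as.matrix(atoms[, c("x", "y", "z")])))
  RR <- outer(R, R)
  f <- sqrt(d^2 + RR * exp(-d^2 / (4 * RR)))
  -GB_K * (1 / eps_in - 1 / eps_out) * sum(outer(q, q) / f)
}

#' Total single-snapshot energy of an atom group
#'
#' @param x Parameterized model or atom table.
#' @param params Parameter set (for dielectrics, surface tension, probe).
#' @param include_solvation Set `FALSE` to evaluate the pure non-bonded
#'   MM term (used by the pairwise-additivity oracle checks).
#' @param n_points SASA quadrature points.
#' @return Object of class `acr3_energy`: list `H_MM`, `G_polar`,
#'   `G_nonpolar`, `G_solv`, `G_TOTAL` (kcal/mol).
#' @export
energy_terms <- function(x, params = default_parameter_set(),
                         include_solvation = TRUE, n_points = 240) {
  atoms <- as_atom_table(x)
  h_mm <- mm_energy(atoms, eps_in = params$dielectric_in)
  if (include_solvation) {
    g_pol <- gb_energy(atoms, params$dielectric_in, params$dielectric_out)
    g_np <- params$surface_tension *
      compute_sasa(atoms, probe = params$probe_radius,
                   n_points = n_points)$total
  } else {
    g_pol <- 0; g_np <- 0
  }
  structure(list(H_MM = h_mm, G_polar = g_pol, G_nonpolar = g_np,
                 G_solv = g_pol + g_np, G_TOTAL = h_mm + g_pol + g_np),
            class = "acr3_energy")
}

#' @export
print.acr3_energy <- function(x, ...) {
  cat(sprintf(
    "<acr3_energy> H_MM %.3f + G_polar %.3f + G_nonpolar %.3f = G_TOTAL %.3f kcal/mol\n",
    x$H_MM, x$G_polar, x$G_nonpolar, x$G_TOTAL))
  invisible(x)
}

#' Per-residue MM-GBSA binding-energy decomposition
#'
#' Group A is the focal residue; group B holds every residue with at
#' least one atom within `radius` of A. On fixed coordinates
#' (single-snapshot approximation),
#' `delta_G_bind = G_TOTAL(AB) - G_TOTAL(A) - G_TOTAL(B)`.
#' An empty environment yields `delta_G_bind = 0` with a warning flag.
#'
#' @param model [structure_model()]; parameters are assigned on the fly
#'   when absent.
#' @param focal_residue 1-based residue index.
#' @param radius Environment radius (Angstrom, default 5.0).
#' @param params Parameter set.
#' @param include_solvation Set `FALSE` for the MM-only decomposition.
#' @param n_points SASA quadrature points.
#' @return Object of class `acr3_binding`: `focal`, `environment`
#'   (residue indices of B), `terms_AB`, `terms_A`, `terms_B`,
#'   `delta_G_bind`, `empty_environment` flag.
#' @export
binding_energy <- function(model, focal_residue, radius = 5.0,
                           params = default_parameter_set(),
                           include_solvation = TRUE, n_points = 240) {
  if (is.null(model$atoms$charge)) {
    model <- assign_parameters(model, params)
  }
  if (focal_residue < 1 || focal_residue > model$residue_count) {
    stop("input error: focal residue out of range")
  }
  net <- interaction_network(model, focal_residue, radius = radius,
                             focal_atoms = "all")
  env_res <- net$partners$residue_index
  a_atoms <- residue_atoms(model, focal_residue)
  if (length(env_res) == 0) {
    warning("empty environment for focal residue ", focal_residue)
    t_a <- energy_terms(a_atoms, params, include_solvation, n_points)
    return(structure(list(focal = focal_residue, environment = integer(0),
                          terms_AB = t_a, terms_A = t_a, terms_B = NULL,
                          delta_G_bind = 0, empty_environment = TRUE),
                     class = "acr3_binding"))
  }
  b_atoms <- model$atoms[model$atoms$residue_index %in% env_res, ,
                         drop = FALSE]
  ab_atoms <- model$atoms[model$atoms$residue_index %in%
                            c(focal_residue, env_res), , drop = FALSE]
  t_ab <- energy_terms(ab_atoms, params, include_solvation, n_points)
  t_a <- energy_terms(a_atoms, params, include_solvation, n_points)
  t_b <- energy_terms(b_atoms, params, include_solvation, n_points)
  structure(list(focal = focal_residue, environment = env_res,
                 terms_AB = t_ab, terms_A = t_a, terms_B = t_b,
                 delta_G_bind = t_ab$G_TOTAL - t_a$G_TOTAL - t_b$G_TOTAL,
                 empty_environment = FALSE),
            class = "acr3_binding")
}

#' @export
print.acr3_binding <- function(x, ...) {
  cat(sprintf(
    "<acr3_binding> residue %d vs %d environment residue(s): dGbind = %.3f kcal/mol\n",
    x$focal, length(x$environment), x$delta_G_bind))
  invisible(x)
}
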