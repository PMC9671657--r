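# Synthetic helix-bundle generator: antiparallel ideal alpha-helices on a
# ring, extended-connector loops, and a single side-chain pseudo-atom per
# residue. These fixtures stand in for predicted transporter models so the
# geometric and energetic stages can be tested against known ground truth.

# run expr with a private RNG stream, restoring global state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Specification for a synthetic helix bundle
#'
#' @param n_helices Number of transmembrane-like helices (>= 1);
#'   default 10, the canonical Acr3-family architecture.
#' @param residues_per_helix Residues per helix (>= 5).
#' @param loop_length Residues per inter-helix connector.
#' @param ring_radius Radius (Angstrom) of the circle on which helix axes
#'   sit; default spaces adjacent helices ~10 Angstrom apart.
#' @param sequence Optional full amino-acid sequence (length must equal the
#'   total residue count); by default a hydrophobic-core/polar-loop sequence
#'   is drawn deterministically from `seed`.
#' @param seed Integer seed; all randomness in the generator flows from it.
#' @return Object of class `acr3_bundle_spec`.
#' @export
bundle_spec <- function(n_helices = 10, residues_per_helix = 25,
                        loop_length = 4, ring_radius = NULL,
                        sequence = NULL, seed = 1) {
  if (n_helices < 1) stop("parameter error: n_helices must be >= 1")
  if (residues_per_helix < 5) {
    stop("parameter error: residues_per_helix must be >= 5")
  }
  if (loop_length < 0) stop("parameter error: loop_length must be >= 0")
  if (is.null(ring_radius)) {
    ring_radius <- if (n_helices == 1) 0 else max(8, 10 * n_helices / (2 * pi))
  }
  if (n_helices > 1 && ring_radius <= 4) {
    stop("parameter error: ring_radius must exceed the helix packing radius")
  }
  n_total <- n_helices * residues_per_helix +
    (n_helices - 1) * loop_length
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (nchar(sequence) != n_total) {
      stop("parameter error: sequence length ", nchar(sequence),
           " != total residue count ", n_total)
    }
    if (!all(strsplit(sequence, "")[[1]] %in% names(AA_ONE_TO_THREE))) {
      stop("parameter error: sequence contains non-standard residues")
    }
  }
  structure(list(n_helices = n_helices,
                 residues_per_helix = residues_per_helix,
                 loop_length = loop_length, ring_radius = ring_radius,
                 sequence = sequence, seed = as.integer(seed),
                 n_total = n_total),
            class = "acr3_bundle_spec")
}

# ideal alpha-helix backbone (N, CA, C, O per residue) via NeRF;
# phi = -57, psi = -47, omega = 180
ideal_helix_backbone <- function(n_res, phi = -57, psi = -47) {
  N <- matrix(0, n_res, 3); CA <- N; C <- N; O <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  th <- (180 - 111.2) * pi / 180
  C[1, ] <- CA[1, ] + 1.525 * c(cos(th), sin(th), 0)
  for (i in seq_len(n_res)) {
    if (i > 1) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           1.329, 116.2, psi)
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            1.458, 121.7, 180)
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                           1.525, 111.2, phi)
    }
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.231, 120.8, psi + 180)
  }
  list(N = N, CA = CA, C = C, O = O)
}

# interior CA positions (n_res rows) of a quadratic Bezier arc from p0
# to p1 bulging along out_dir, with the bulge height solved so that the
# per-residue step approaches target_step (capped at a 12 A bulge)
loop_arc <- function(p0, p1, out_dir, n_res, target_step = 3.6) {
  wanted <- target_step * (n_res + 1)
  bez <- function(h) {
    ctrl <- (p0 + p1) / 2 + h * out_dir
    tt <- seq(0, 1, length.out = 200)
    pts <- outer((1 - tt)^2, p0) + outer(2 * tt * (1 - tt), ctrl) +
      outer(tt^2, p1)
    pts
  }
  arc_len <- function(pts) sum(sqrt(rowSums(diff(pts)^2)))
  lo <- 0; hi <- 12
  if (arc_len(bez(hi)) > wanted) {
    for (it in 1:40) {
      midh <- (lo + hi) / 2
      if (arc_len(bez(midh)) < wanted) lo <- midh else hi <- midh
    }
  } else lo <- hi
  pts <- bez(lo)
  # equal arc-length stations for the interior residues
  seglen <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  total <- seglen[length(seglen)]
  stations <- total * seq_len(n_res) / (n_res + 1)
  t(vapply(stations, function(s) {
    i <- findInterval(s, seglen, all.inside = TRUE)
    f <- (s - seglen[i]) / max(seglen[i + 1] - seglen[i], 1e-12)
    pts[i, ] + f * (pts[i + 1, ] - pts[i, ])
  }, numeric(3)))
}

# side-chain pseudo-atom position from a backbone frame
sc_position <- function(n, ca, c, dist) {
  u1 <- unitv(n - ca)
  u2 <- unitv(c - ca)
  perp <- unitv(cross3(u2, u1))
  ca + dist * unitv(perp - u1 - u2)
}

#' Generate a synthetic antiparallel helix-bundle structure
#'
#' Backbone atoms (N, CA, C, O) are placed on ideal alpha-helix geometry
#' (phi = -57, psi = -47; 1.5 Angstrom rise, ~100 degrees per residue) for
#' each helix; helices alternate direction on a ring of radius
#' `ring_radius`; loops are extended connectors. Each non-glycine residue
#' carries a single side-chain pseudo-atom (`SC`) in the C-beta direction
#' at a residue-type-specific distance. Deterministic given the spec seed.
#'
#' @param spec [bundle_spec()] object.
#' @return [structure_model()] object; helix residue ranges are attached as
#'   attribute `"helix_ranges"` (data.frame start/end).
#' @export
generate_helix_bundle <- function(spec) {
  stopifnot(inherits(spec, "acr3_bundle_spec"))
  nh <- spec$n_helices
  nr <- spec$residues_per_helix
  nl <- spec$loop_length
  seq1 <- spec$sequence
  if (is.null(seq1)) {
    helix_pool <- c("I", "L", "V", "A", "F", "M")
    loop_pool <- c("G", "S", "T", "N", "Q", "K", "R", "D", "E", "P")
    seq1 <- with_seed(spec$seed, {
      parts <- character(0)
      for (h in seq_len(nh)) {
        parts <- c(parts, sample(helix_pool, nr, replace = TRUE))
        if (h < nh && nl > 0) {
          parts <- c(parts, sample(loop_pool, nl, replace = TRUE))
        }
      }
      paste(parts, collapse = "")
    })
  }
  aa <- strsplit(seq1, "")[[1]]

  template <- ideal_helix_backbone(nr)
  # helix axis from PCA of template CA coordinates
  ca0 <- template$CA
  cen0 <- colMeans(ca0)
  ax <- prcomp(ca0, center = TRUE)$rotation[, 1]
  if (sum(ax * (ca0[nr, ] - ca0[1, ])) < 0) ax <- -ax

  res_list <- list()
  helix_ranges <- data.frame(start = integer(0), end = integer(0))
  res_counter <- 0L
  prev_helix_end <- NULL   # coords of last-placed helix (for loops)

  place_helix <- function(h) {
    theta <- 2 * pi * (h - 1) / max(nh, 1)
    center <- c(spec$ring_radius * cos(theta),
                spec$ring_radius * sin(theta), 0)
    dirn <- if (h %% 2 == 1) c(0, 0, 1) else c(0, 0, -1)
    R <- rotation_between(ax, dirn)
    tf <- function(m) sweep(m, 2, cen0) %*% t(R) +
      matrix(center, nrow(m), 3, byrow = TRUE)
    list(N = tf(template$N), CA = tf(template$CA),
         C = tf(template$C), O = tf(template$O))
  }

  helices <- lapply(seq_len(nh), place_helix)

  add_residue <- function(n, ca, c, o) {
    code <- aa[res_counter + 1L]
    res_counter <<- res_counter + 1L
    rows <- data.frame(
      atom_name = c("N", "CA", "C", "O"),
      residue_name = AA_ONE_TO_THREE[[code]],
      residue_index = res_counter,
      x = c(n[1], ca[1], c[1], o[1]),
      y = c(n[2], ca[2], c[2], o[2]),
      z = c(n[3], ca[3], c[3], o[3]),
      element = c("N", "C", "C", "O"),
      stringsAsFactors = FALSE
    )
    d <- SC_CENTROID_DIST[[code]]
    if (d > 0) {
      sc <- sc_position(n, ca, c, d)
      rows <- rbind(rows, data.frame(
        atom_name = "SC", residue_name = AA_ONE_TO_THREE[[code]],
        residue_index = res_counter, x = sc[1], y = sc[2], z = sc[3],
        element = "C", stringsAsFactors = FALSE))
    }
    res_list[[length(res_list) + 1L]] <<- rows
  }

  for (h in seq_len(nh)) {
    hx <- helices[[h]]
    helix_ranges <- rbind(helix_ranges,
                          data.frame(start = res_counter + 1L,
                                     end = res_counter + nr))
    for (i in seq_len(nr)) {
      add_residue(hx$N[i, ], hx$CA[i, ], hx$C[i, ], hx$O[i, ])
    }
    if (h < nh && nl > 0) {
      # extended connector: CAs on an outward-bulging arc with ~3.6 A
      # virtual bonds (extended-chain spacing), so loop backbones do not
      # collide the way a straight-line interpolation at short chords
      # would
      p0 <- hx$CA[nr, ]
      p1 <- helices[[h + 1]]$CA[1, ]
      mid <- (p0 + p1) / 2
      out_dir <- mid - c(0, 0, mid[3])          # radially out from axis
      out_dir <- if (vnorm(out_dir) < 1e-6) c(1, 0, 0) else unitv(out_dir)
      cas <- loop_arc(p0, p1, out_dir, nl, target_step = 3.6)
      for (k in seq_len(nl)) {
        ca <- cas[k, ]
        nxt <- if (k < nl) cas[k + 1, ] else p1
        prv <- if (k > 1) cas[k - 1, ] else p0
        u <- unitv(nxt - prv)
        w0 <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
        w <- unitv(cross3(u, w0))
        n <- ca - 1.2 * u + 0.4 * w
        c_at <- ca + 1.2 * u + 0.4 * w
        o <- c_at + 1.23 * w
        add_residue(n, ca, c_at, o)
      }
    }
  }

  atoms <- do.call(rbind, res_list)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$chain_id <- "A"
  atoms$orig_residue_index <- atoms$residue_index
  model <- structure_model(sprintf("bundle_h%d_r%d_s%d", nh, nr, spec$seed),
                           atoms)
  attr(model, "helix_ranges") <- helix_ranges
  model
}

normalize_mutations <- function(mutations) {
  if (is.data.frame(mutations)) {
    data.frame(position = as.integer(mutations[[1]]),
               new_residue = toupper(as.character(mutations[[2]])),
               stringsAsFactors = FALSE)
  } else {
    data.frame(
      position = vapply(mutations, function(m) as.integer(m[[1]]), 1L),
      new_residue = vapply(mutations,
                           function(m) toupper(as.character(m[[2]])), ""),
      stringsAsFactors = FALSE)
  }
}

#' Apply point mutations to a structure model
#'
#' Residue identities (and the side-chain pseudo-atom, when present) are
#' updated; backbone atoms are untouched, so the mutant is a fixture with
#' sequence changes at exactly the stated positions.
#'
#' @param model [structure_model()] object.
#' @param mutations data.frame of `(position, new_residue)` (1-letter
#'   codes), or a list of 2-element vectors. Empty input returns the model
#'   unchanged.
#' @return Mutated [structure_model()].
#' @export
apply_mutations <- function(model, mutations) {
  mut <- if (length(mutations) == 0) {
    data.frame(position = integer(0), new_residue = character(0))
  } else normalize_mutations(mutations)
  if (nrow(mut) == 0) return(model)
  if (any(mut$position < 1 | mut$position > model$residue_count)) {
    stop("parameter error: mutation position out of range 1..",
         model$residue_count)
  }
  if (!all(mut$new_residue %in% names(AA_ONE_TO_THREE))) {
    stop("parameter error: new_residue must be a standard amino acid")
  }
  atoms <- model$atoms
  for (r in seq_len(nrow(mut))) {
    pos <- mut$position[r]
    code <- mut$new_residue[r]
    sel <- atoms$residue_index == pos
    atoms$residue_name[sel] <- AA_ONE_TO_THREE[[code]]
    d <- SC_CENTROID_DIST[[code]]
    sc_row <- which(sel & atoms$atom_name == "SC")
    if (d == 0) {
      if (length(sc_row) > 0) atoms <- atoms[-sc_row, , drop = FALSE]
    } else {
      bb <- atoms[atoms$residue_index == pos, , drop = FALSE]
      n <- unlist(bb[bb$atom_name == "N", c("x", "y", "z")])
      ca <- unlist(bb[bb$atom_name == "CA", c("x", "y", "z")])
      cc <- unlist(bb[bb$atom_name == "C", c("x", "y", "z")])
      sc <- sc_position(n, ca, cc, d)
      if (length(sc_row) > 0) {
        atoms[sc_row, c("x", "y", "z")] <- as.list(sc)
      } else {
        new_row <- atoms[which(sel & atoms$atom_name == "CA"), , drop = FALSE]
        new_row$atom_name <- "SC"; new_row$element <- "C"
        new_row[, c("x", "y", "z")] <- as.list(sc)
        # insert after the residue's last atom to keep residues contiguous
        last_of_res <- max(which(atoms$residue_index == pos))
        atoms <- rbind(atoms[seq_len(last_of_res), , drop = FALSE],
                       new_row,
                       if (last_of_res < nrow(atoms))
                         atoms[(last_of_res + 1):nrow(atoms), , drop = FALSE])
      }
    }
  }
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  out <- structure_model(model$model_id, atoms)
  attr(out, "helix_ranges") <- attr(model, "helix_ranges")
  out
}

#' Add Gaussian coordinate noise to a structure
#'
#' @param model [structure_model()] object.
#' @param sigma Standard deviation (Angstrom) of the i.i.d. displacement
#'   added to every atom coordinate; `sigma = 0` returns an identical copy.
#' @param seed Integer seed.
#' @return Perturbed [structure_model()].
#' @export
perturb_structure <- function(model, sigma, seed = 1) {
  if (sigma < 0) stop("parameter error: sigma must be >= 0")
  if (sigma == 0) return(model)
  atoms <- model$atoms
  n <- nrow(atoms)
  noise <- with_seed(seed, matrix(stats::rnorm(3 * n, 0, sigma), n, 3))
  atoms$x <- atoms$x + noise[, 1]
  atoms$y <- atoms$y + noise[, 2]
  atoms$z <- atoms$z + noise[, 3]
  out <- structure_model(model$model_id, atoms)
  attr(out, "helix_ranges") <- attr(model, "helix_ranges")
  out
}
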