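# Independent brute-force oracles. These share no code with the package
# implementations they check: everything is recomputed from first
# principles with plain loops.

GC_TABLE <- as.character(Biostrings::GENETIC_CODE)
names(GC_TABLE) <- names(Biostrings::GENETIC_CODE)
STOPS <- c("TAA", "TAG", "TGA")

split_codons <- function(s) {
  substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
}

# --- NG86 oracle: direct enumeration, loop-based -----------------------
oracle_ng86 <- function(a, b) {
  ca <- split_codons(a)
  cb <- split_codons(b)
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  syn_sites_one <- function(cod) {
    s <- 0
    for (pos in 1:3) {
      for (nt in c("A", "C", "G", "T")) {
        if (nt == substr(cod, pos, pos)) next
        alt <- cod
        substr(alt, pos, pos) <- nt
        if (!(alt %in% STOPS) && GC_TABLE[[alt]] == GC_TABLE[[cod]]) {
          s <- s + 1 / 3
        }
      }
    }
    s
  }
  all_perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  for (k in seq_along(ca)) {
    S <- S + (syn_sites_one(ca[k]) + syn_sites_one(cb[k])) / 2
    N <- N + 3 - (syn_sites_one(ca[k]) + syn_sites_one(cb[k])) / 2
    pos <- which(strsplit(ca[k], "")[[1]] != strsplit(cb[k], "")[[1]])
    if (length(pos) == 0) next
    path_counts <- list()
    for (ord in all_perms(pos)) {
      cur <- ca[k]; s <- 0; n <- 0; blocked <- FALSE
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(cb[k], p, p)
        if (nxt %in% STOPS) { blocked <- TRUE; break }
        if (GC_TABLE[[nxt]] == GC_TABLE[[cur]]) s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      if (!blocked) path_counts[[length(path_counts) + 1]] <- c(s, n)
    }
    if (length(path_counts) == 0) {
      for (ord in all_perms(pos)) {
        cur <- ca[k]; s <- 0; n <- 0
        for (p in ord) {
          nxt <- cur
          substr(nxt, p, p) <- substr(cb[k], p, p)
          if (nxt %in% STOPS || GC_TABLE[[nxt]] != GC_TABLE[[cur]]) {
            n <- n + 1
          } else s <- s + 1
          cur <- nxt
        }
        path_counts[[length(path_counts) + 1]] <- c(s, n)
      }
    }
    m <- do.call(rbind, path_counts)
    Sd <- Sd + mean(m[, 1])
    Nd <- Nd + mean(m[, 2])
  }
  jc <- function(p) -3 / 4 * log(1 - 4 * p / 3)
  list(dN = jc(Nd / N), dS = jc(Sd / S), N = N, S = S, Nd = Nd, Sd = Sd)
}

# random stop-free codon sequence (test-local, independent of random_cds)
rand_codons <- function(n) {
  sense <- setdiff(names(GC_TABLE), STOPS)
  paste(sample(sense, n, replace = TRUE), collapse = "")
}

# --- geometry oracles --------------------------------------------------
oracle_contact_map <- function(model, cutoff) {
  ca <- model$atoms[model$atoms$atom_name == "CA", ]
  ca <- ca[order(ca$residue_index), ]
  out <- NULL
  n <- nrow(ca)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt((ca$x[i] - ca$x[j])^2 + (ca$y[i] - ca$y[j])^2 +
                  (ca$z[i] - ca$z[j])^2)
      if (d <= cutoff) out <- rbind(out, c(i, j))
    }
  }
  out
}

oracle_network <- function(model, focal, radius, use_ca_fallback = TRUE) {
  at <- model$atoms
  fa <- at[at$residue_index == focal, ]
  sel <- fa[!(fa$atom_name %in% c("N", "CA", "C", "O", "OXT")) &
              substr(fa$atom_name, 1, 1) != "H", ]
  if (nrow(sel) == 0 && use_ca_fallback) sel <- fa[fa$atom_name == "CA", ]
  partners <- integer(0)
  for (r in setdiff(unique(at$residue_index), focal)) {
    ra <- at[at$residue_index == r, ]
    mind <- Inf
    for (i in seq_len(nrow(sel))) {
      for (j in seq_len(nrow(ra))) {
        d <- sqrt((sel$x[i] - ra$x[j])^2 + (sel$y[i] - ra$y[j])^2 +
                    (sel$z[i] - ra$z[j])^2)
        mind <- min(mind, d)
      }
    }
    if (mind <= radius) partners <- c(partners, r)
  }
  sort(partners)
}

oracle_hydropathy <- function(seq, window) {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  aa <- strsplit(seq, "")[[1]]
  half <- (window - 1) / 2
  out <- numeric(length(aa))
  for (i in seq_along(aa)) {
    idx <- max(1, i - half):min(length(aa), i + half)
    out[i] <- mean(kd[aa[idx]])
  }
  out
}

# Horn's quaternion method for optimal-superposition RMSD
oracle_rmsd_quaternion <- function(A, B) {
  A0 <- sweep(A, 2, colMeans(A))
  B0 <- sweep(B, 2, colMeans(B))
  M <- t(A0) %*% B0
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  ss <- sum(A0^2) + sum(B0^2)
  msd <- max(0, (ss - 2 * lam) / nrow(A))
  sqrt(msd)
}

# analytic SASA of two intersecting spheres (radii include the probe)
oracle_two_sphere_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * (r1^2 + r2^2))
  if (d <= abs(r1 - r2)) return(4 * pi * max(r1, r2)^2)
  # spherical cap heights buried on each sphere
  h1 <- (r2^2 - (d - r1)^2) / (2 * d)
  h2 <- (r1^2 - (d - r2)^2) / (2 * d)
  4 * pi * (r1^2 + r2^2) - 2 * pi * (r1 * h1 + r2 * h2)
}

# random rigid transform
random_rigid <- function(X) {
  th <- runif(3, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]),
                 0, sin(th[1]), cos(th[1])), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(th[2]), 0, sin(th[2]), 0, 1, 0,
                 -sin(th[2]), 0, cos(th[2])), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(th[3]), -sin(th[3]), 0, sin(th[3]), cos(th[3]), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  R <- Rx %*% Ry %*% Rz
  sweep(X %*% t(R), 2, runif(3, -20, 20), `+`)
}

# --- independent H-bond oracle ----------------------------------------
# plain-loop re-derivation: backbone N-H donors (H on the bisector of
# N-C(prev) and N-CA at 1.01 A), backbone O acceptors plus side-chain
# pseudo-atom donors/acceptors by residue identity
oracle_hbonds <- function(model, d_cutoff, angle_cutoff) {
  at <- model$atoms
  nres <- max(at$residue_index)
  get1 <- function(r, nm) {
    row <- at[at$residue_index == r & at$atom_name == nm, ]
    if (nrow(row) == 0) return(NULL)
    c(row$x[1], row$y[1], row$z[1])
  }
  resname <- function(r) at$residue_name[at$residue_index == r][1]
  sc_don <- c("SER", "THR", "TYR", "ASN", "GLN", "LYS", "ARG", "HIS",
              "TRP", "CYS")
  sc_acc <- c("ASP", "GLU", "ASN", "GLN", "SER", "THR", "TYR", "HIS")
  # acceptors: (res, atom, xyz)
  acc <- list()
  for (r in seq_len(nres)) {
    acc[[length(acc) + 1]] <- list(res = r, atom = "O", xyz = get1(r, "O"))
    if (!is.null(get1(r, "SC")) && resname(r) %in% sc_acc) {
      acc[[length(acc) + 1]] <- list(res = r, atom = "SC",
                                     xyz = get1(r, "SC"))
    }
  }
  found <- NULL
  norm1 <- function(v) v / sqrt(sum(v^2))
  for (r in seq_len(nres)) {
    # backbone donor with reconstructed H (none for residue 1 / proline)
    hpos <- NULL
    if (r > 1 && resname(r) != "PRO") {
      n <- get1(r, "N"); ca <- get1(r, "CA"); cprev <- get1(r - 1, "C")
      hpos <- n + 1.01 * norm1(norm1(n - cprev) + norm1(n - ca))
    }
    donors <- list()
    if (!is.null(hpos)) {
      donors[[1]] <- list(res = r, atom = "N", xyz = get1(r, "N"),
                          h = hpos)
    }
    if (!is.null(get1(r, "SC")) && resname(r) %in% sc_don) {
      donors[[length(donors) + 1]] <- list(res = r, atom = "SC",
                                           xyz = get1(r, "SC"), h = NULL)
    }
    for (d in donors) {
      for (a in acc) {
        if (a$res == d$res) next
        dda <- sqrt(sum((d$xyz - a$xyz)^2))
        if (is.null(d$h)) {
          if (dda <= d_cutoff + 0.2) {
            found <- rbind(found, data.frame(donor_res = d$res,
                                             donor_atom = d$atom,
                                             acceptor_res = a$res,
                                             acceptor_atom = a$atom))
          }
        } else if (dda <= d_cutoff) {
          v1 <- d$xyz - d$h; v2 <- a$xyz - d$h
          ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                    sqrt(sum(v1^2) * sum(v2^2))))) *
            180 / pi
          if (180 - ang <= angle_cutoff) {
            found <- rbind(found, data.frame(donor_res = d$res,
                                             donor_atom = d$atom,
                                             acceptor_res = a$res,
                                             acceptor_atom = a$atom))
          }
        }
      }
    }
  }
  found
}
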