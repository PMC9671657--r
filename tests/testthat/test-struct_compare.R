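# Contact maps, contact-map differencing, Kabsch superposition,
# structural clustering, interaction networks and hydrogen bonds.

test_that("contact boundary is inclusive at the cutoff", {
  expect_equal(build_contact_map(two_residue_model(7.9))$total, 1)
  expect_equal(build_contact_map(two_residue_model(8.1))$total, 0)
  expect_equal(build_contact_map(two_residue_model(8.0))$total, 1)
})

test_that("contact maps equal the brute-force distance scan", {
  for (seed in 1:5) {
    m <- small_bundle(seed = seed, n_helices = 3, residues_per_helix = 10)
    m <- perturb_structure(m, 0.4, seed = seed + 50)
    cm <- build_contact_map(m, cutoff = 8)
    want <- oracle_contact_map(m, 8)
    expect_equal(unname(cm$contacts), unname(want))
  }
})

test_that("contact diff of a map with itself is all-common", {
  m <- small_bundle(seed = 2)
  cm <- build_contact_map(m)
  d <- diff_contact_maps(cm, cm)
  expect_equal(d$n_unique_a, 0)
  expect_equal(d$n_unique_b, 0)
  expect_equal(d$n_common, cm$total)
  cm2 <- build_contact_map(m, cutoff = 7)
  expect_error(diff_contact_maps(cm, cm2), "cutoff")
})

test_that("contact-diff partition identity and mirror symmetry hold", {
  for (seed in 1:6) {
    base <- small_bundle(seed = seed, n_helices = 2,
                         residues_per_helix = 11)
    a <- perturb_structure(base, 0.5, seed = seed + 10)
    b <- perturb_structure(base, 0.5, seed = seed + 20)
    ma <- build_contact_map(a); mb <- build_contact_map(b)
    d <- diff_contact_maps(ma, mb)
    expect_equal(d$n_unique_a + d$n_common, ma$total)
    expect_equal(d$n_unique_b + d$n_common, mb$total)
    rev <- diff_contact_maps(mb, ma)
    expect_equal(rev$n_unique_a, d$n_unique_b)
    expect_equal(rev$n_unique_b, d$n_unique_a)
    expect_equal(rev$n_common, d$n_common)
  }
})

test_that("kabsch superposition: identity, rigid invariance, oracle", {
  m <- small_bundle(seed = 7)
  X <- as.matrix(m$atoms[m$atoms$atom_name == "CA", c("x", "y", "z")])
  self <- kabsch_superpose(X, X)
  expect_equal(self$rmsd, 0, tolerance = 1e-12)
  expect_equal(det(self$rotation), 1, tolerance = 1e-9)
  set.seed(77)
  for (rep in 1:5) {
    Y <- random_rigid(X)
    sp <- kabsch_superpose(X, Y)
    expect_lt(sp$rmsd, 1e-9)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
    # noisy pairs against the quaternion oracle
    Z <- Y + matrix(rnorm(length(Y), 0, 0.5), nrow(Y), 3)
    expect_equal(kabsch_superpose(X, Z)$rmsd, oracle_rmsd_quaternion(X, Z),
                 tolerance = 1e-9)
  }
  expect_error(kabsch_superpose(X[1:2, ], X[1:2, ]), ">= 3")
})

test_that("collinear point sets are flagged but keep a proper rotation", {
  X <- cbind(0:5, 0, 0)
  sp <- kabsch_superpose(X, X + 1)
  expect_true(sp$degenerate)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
})

test_that("identical copies cluster into one group", {
  m <- small_bundle(seed = 1)
  copies <- lapply(1:3, function(i) {
    x <- m; x$model_id <- paste0("c", i); x
  })
  cl <- cluster_structures(copies)
  expect_equal(cl$k, 1)
  expect_length(unique(cl$labels), 1)
})

test_that("three perturbation groups are recovered exactly", {
  base <- small_bundle(seed = 10, n_helices = 3, residues_per_helix = 10)
  parents <- lapply(1:3, function(g) {
    perturb_structure(base, 2.0, seed = 300 + g)
  })
  models <- list()
  truth <- integer(0)
  for (g in 1:3) for (i in 1:3) {
    x <- perturb_structure(parents[[g]], 0.15, seed = 400 + 10 * g + i)
    x$model_id <- sprintf("g%d_%d", g, i)
    models[[x$model_id]] <- x
    truth <- c(truth, g)
  }
  cl <- cluster_structures(models)
  expect_equal(cl$k, 3)
  # perfect partition agreement up to label permutation
  expect_equal(length(unique(paste(cl$labels, truth))), 3)
})

test_that("interaction network boundary and brute-force equivalence", {
  m <- small_bundle(seed = 4, n_helices = 2, residues_per_helix = 10)
  for (focal in c(1, 5, 12)) {
    net <- interaction_network(m, focal, radius = 5)
    expect_equal(net$partners$residue_index,
                 oracle_network(m, focal, 5))
    expect_true(all(net$partners$min_dist <= 5))
    expect_false(focal %in% net$partners$residue_index)
  }
  expect_error(interaction_network(m, 999), "out of range")
  # boundary: nearest atom of the other residue (its N, at x0 - 1.3)
  # just inside / just outside the 5 A radius from the focal CA
  net_in <- interaction_network(two_residue_model(6.2), 1, radius = 5,
                                focal_atoms = "CA")
  expect_equal(nrow(net_in$partners), 1)
  net_out <- interaction_network(two_residue_model(6.4), 1, radius = 5,
                                 focal_atoms = "CA")
  expect_equal(nrow(net_out$partners), 0)
})

test_that("glycine focal side chain falls back to CA with a flag", {
  m <- small_bundle(seed = 5)
  g <- apply_mutations(m, data.frame(position = 6, new_residue = "G"))
  net <- interaction_network(g, 6, radius = 5)
  expect_true(net$ca_fallback)
  expect_equal(net$partners$residue_index,
               oracle_network(g, 6, 5, use_ca_fallback = TRUE))
})

test_that("textbook N-H...O geometry is detected, far atoms are not", {
  # donor backbone N with previous-residue C so H reconstruction works;
  # acceptor O placed 2.95 A from N along the N->H direction (linear)
  atoms <- data.frame(
    serial = 1:8,
    atom_name = c("N", "CA", "C", "O", "N", "CA", "C", "O"),
    residue_name = "ALA",
    chain_id = "A",
    residue_index = c(1, 1, 1, 1, 2, 2, 2, 2),
    orig_residue_index = c(1, 1, 1, 1, 2, 2, 2, 2),
    x = c(0, 1.458, 2.009, 1.251, 3.332, 4.023, 5.531, 6.021),
    y = c(0, 0, 1.42, 2.39, 1.536, 2.813, 2.613, 3.74),
    z = 0, element = c("N", "C", "C", "O", "N", "C", "C", "O"))
  m <- structure_model("hb", atoms)
  # compute where the reconstructed H of residue 2 points, then place an
  # acceptor O (residue 3) on that ray
  bb <- acr3kit:::backbone_coords(m)
  H <- acr3kit:::reconstruct_amide_h(bb$N, bb$CA, bb$C)
  dirv <- (H[2, ] - bb$N[2, ]) / sqrt(sum((H[2, ] - bb$N[2, ])^2))
  o_pos <- bb$N[2, ] + 2.95 * dirv
  far_c <- o_pos + c(10, 0, 0)
  atoms3 <- rbind(atoms, data.frame(
    serial = 8:11,
    atom_name = c("N", "CA", "C", "O"),
    residue_name = "ALA", chain_id = "A",
    residue_index = 3, orig_residue_index = 3,
    x = c(far_c[1] + 1, far_c[1] + 2, far_c[1], o_pos[1]),
    y = c(far_c[2], far_c[2], far_c[2], o_pos[2]),
    z = c(far_c[3], far_c[3], far_c[3], o_pos[3]),
    element = c("N", "C", "C", "O")))
  m3 <- structure_model("hb3", atoms3)
  hb <- detect_hbonds(m3, d_cutoff = 3.0, angle_cutoff = 20)
  hit <- hb[hb$donor_res == 2 & hb$acceptor_res == 3 &
              hb$acceptor_atom == "O", ]
  expect_equal(nrow(hit), 1)
  expect_gt(hit$angle, 160)
  # atoms 5 A apart: no bond
  expect_equal(nrow(detect_hbonds(two_residue_model(5))), 0)
})

test_that("ideal helix backbone bonds are i -> i-4 (i -> i-3 at ends)", {
  m <- generate_helix_bundle(bundle_spec(1, 16, seed = 6))
  # fixture geometry has N...O(i-4) = 3.09 A, so widen the distance
  # cutoff past it; the angle criterion still applies
  hb <- detect_hbonds(m, d_cutoff = 3.2, angle_cutoff = 20)
  bb <- hb[hb$donor_atom == "N" & hb$acceptor_atom == "O", ]
  expect_gt(nrow(bb), 5)
  offs <- bb$donor_res - bb$acceptor_res
  expect_true(all(offs %in% c(3, 4)))
  expect_true(sum(offs == 4) >= nrow(bb) - 2)
})

test_that("hbonds_near_residue is a subset under the either-partner rule", {
  m <- generate_helix_bundle(bundle_spec(2, 14, seed = 8))
  all_hb <- detect_hbonds(m, d_cutoff = 3.2)
  near <- hbonds_near_residue(m, 7, radius = 5, d_cutoff = 3.2)
  expect_lte(nrow(near), nrow(all_hb))
  key <- function(df) paste(df$donor_res, df$donor_atom, df$acceptor_res,
                            df$acceptor_atom)
  expect_true(all(key(near) %in% key(all_hb)))
  # an isolated focal far from everything yields nothing
  far <- two_residue_model(30)
  expect_equal(nrow(hbonds_near_residue(far, 1, radius = 5)), 0)
})
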