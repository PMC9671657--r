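# Parameter assignment, SASA, molecular-mechanics and generalized-Born
# energies, and the binding-energy decomposition.

param_atom <- function(x = 0, y = 0, z = 0, charge = 0, eps = 0,
                       rmin = 1.7, gb_radius = 2, residue_index = 1,
                       atom_name = "CA", residue_name = "ALA") {
  data.frame(serial = 1, atom_name = atom_name,
             residue_name = residue_name, chain_id = "A",
             residue_index = residue_index,
             orig_residue_index = residue_index,
             x = x, y = y, z = z, element = "C", charge = charge,
             eps = eps, rmin = rmin, gb_radius = gb_radius)
}

test_that("per-residue charges sum to the formal charge for all 20", {
  aas <- names(acr3kit:::AA_ONE_TO_THREE)
  m <- generate_helix_bundle(bundle_spec(
    1, 20, sequence = paste(aas, collapse = ""), seed = 1))
  pm <- assign_parameters(m)
  sums <- tapply(pm$atoms$charge, pm$atoms$residue_index, sum)
  tab <- default_parameter_set()$residues
  want <- tab$formal_charge[match(
    acr3kit:::AA_ONE_TO_THREE[aas], tab$residue)]
  expect_equal(as.numeric(sums), want, tolerance = 1e-6)
  # chemistry-forced signs
  expect_equal(as.numeric(sums[aas == "D"]), -1, tolerance = 1e-6)
  expect_equal(as.numeric(sums[aas == "K"]), 1, tolerance = 1e-6)
  expect_equal(as.numeric(sums[aas == "G"]), 0, tolerance = 1e-6)
})

test_that("unknown residues are rejected by name", {
  m <- small_bundle(seed = 2)
  m$atoms$residue_name[1:4] <- "XYZ"
  expect_error(assign_parameters(m), "XYZ")
})

test_that("single-atom SASA matches the analytic sphere", {
  a <- param_atom(gb_radius = 1.6)
  s <- compute_sasa(a, probe = 1.4, n_points = 960)
  expect_equal(s$total, 4 * pi * 3^2, tolerance = 0.005)
  # two fully overlapping identical atoms expose one sphere in total
  b <- rbind(a, a)
  b$serial <- 1:2
  expect_equal(compute_sasa(b, n_points = 960)$total, 4 * pi * 3^2,
               tolerance = 0.005)
  expect_error(compute_sasa(a[0, ]), "zero atoms")
})

test_that("two partially overlapping spheres match the cap formula", {
  for (d in c(2, 3, 4.5)) {
    a <- param_atom(gb_radius = 1.6)
    b <- param_atom(x = d, gb_radius = 1.2, residue_index = 2)
    got <- compute_sasa(rbind(a, b), probe = 1.4, n_points = 1920)$total
    want <- oracle_two_sphere_area(3.0, 2.6, d)
    expect_equal(got, want, tolerance = 0.01 * want)
  }
})

test_that("SASA never increases when neighbors are added", {
  m <- assign_parameters(small_bundle(seed = 3))
  at <- m$atoms
  s_half <- compute_sasa(at[at$residue_index <= 6, ], n_points = 240)
  s_full <- compute_sasa(at, n_points = 240)
  expect_lte(s_full$per_atom[1], s_half$per_atom[1] + 1e-9)
  first6 <- at$residue_index <= 6
  expect_lte(sum(s_full$per_atom[first6]), s_half$total + 1e-9)
})

test_that("mm_energy closed forms: zero charges, two unit charges, clash", {
  a <- param_atom(charge = 0, eps = 0)
  b <- param_atom(x = 50, charge = 0, eps = 0, residue_index = 2)
  expect_equal(mm_energy(rbind(a, b)), 0)
  r <- 3.7
  b2 <- param_atom(x = r, charge = 1, eps = 0, residue_index = 2)
  a2 <- param_atom(charge = 1, eps = 0)
  expect_equal(mm_energy(rbind(a2, b2)), 332.0636 / r, tolerance = 1e-12)
  expect_equal(mm_energy(rbind(a2, b2), eps_in = 4), 332.0636 / (4 * r),
               tolerance = 1e-12)
  b3 <- param_atom(x = 0.05, charge = 1, residue_index = 2)
  expect_error(mm_energy(rbind(a2, b3)), "clash")
})

test_that("mm_energy equals a brute-force double loop with exclusions", {
  pm <- assign_parameters(small_bundle(seed = 6, n_helices = 1,
                                       residues_per_helix = 8))
  at <- pm$atoms
  tot <- 0
  for (i in seq_len(nrow(at) - 1)) {
    for (j in (i + 1):nrow(at)) {
      ri <- at$residue_index[i]; rj <- at$residue_index[j]
      if (ri == rj) next
      if (abs(ri - rj) == 1) {
        lo <- which.min(c(ri, rj)); hi <- 3 - lo
        nm <- c(at$atom_name[i], at$atom_name[j])
        if (nm[lo] == "C" && nm[hi] == "N") next
      }
      r <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                  (at$z[i] - at$z[j])^2)
      sr6 <- ((at$rmin[i] + at$rmin[j]) / r)^6
      tot <- tot + 332.0636 * at$charge[i] * at$charge[j] / r +
        sqrt(at$eps[i] * at$eps[j]) * (sr6^2 - 2 * sr6)
    }
  }
  expect_equal(mm_energy(at), tot, tolerance = 1e-9)
})

test_that("gb_energy reduces to the Born formula and Still two-charge form", {
  one <- param_atom(charge = 1, gb_radius = 2)
  expect_equal(gb_energy(one), -166 * (1 - 1 / 78.5) / 2, tolerance = 1e-12)
  # all charges zero
  zero <- rbind(param_atom(), param_atom(x = 3, residue_index = 2))
  expect_equal(gb_energy(zero), 0)
  # hand-evaluated Still formula for two charges
  q1 <- 0.5; q2 <- -1; R1 <- 1.5; R2 <- 2.5; r <- 4
  two <- rbind(param_atom(charge = q1, gb_radius = R1),
               param_atom(x = r, charge = q2, gb_radius = R2,
                          residue_index = 2))
  f12 <- sqrt(r^2 + R1 * R2 * exp(-r^2 / (4 * R1 * R2)))
  want <- -166 * (1 - 1 / 78.5) *
    (q1^2 / R1 + q2^2 / R2 + 2 * q1 * q2 / f12)
  expect_equal(gb_energy(two), want, tolerance = 1e-10)
  bad <- param_atom(charge = 1, gb_radius = -1)
  expect_error(gb_energy(bad), "radius")
})

test_that("binding energy: empty environment gives exactly zero", {
  # two residues far apart: no environment within 5 A
  m <- assign_parameters(two_residue_model(40))
  expect_warning(be <- binding_energy(m, 1, radius = 5), "empty")
  expect_equal(be$delta_G_bind, 0)
  expect_true(be$empty_environment)
})

test_that("MM-only binding energy equals the inter-group pairwise sum", {
  pm <- assign_parameters(small_bundle(seed = 11))
  for (focal in c(4, 9, 15)) {
    be <- binding_energy(pm, focal, include_solvation = FALSE)
    a_at <- pm$atoms[pm$atoms$residue_index == focal, ]
    b_at <- pm$atoms[pm$atoms$residue_index %in% be$environment, ]
    tot <- 0
    for (i in seq_len(nrow(a_at))) {
      for (j in seq_len(nrow(b_at))) {
        ri <- a_at$residue_index[i]; rj <- b_at$residue_index[j]
        if (rj - ri == 1 && a_at$atom_name[i] == "C" &&
              b_at$atom_name[j] == "N") next
        if (ri - rj == 1 && a_at$atom_name[i] == "N" &&
              b_at$atom_name[j] == "C") next
        r <- sqrt((a_at$x[i] - b_at$x[j])^2 + (a_at$y[i] - b_at$y[j])^2 +
                    (a_at$z[i] - b_at$z[j])^2)
        sr6 <- ((a_at$rmin[i] + b_at$rmin[j]) / r)^6
        tot <- tot + 332.0636 * a_at$charge[i] * b_at$charge[j] / r +
          sqrt(a_at$eps[i] * b_at$eps[j]) * (sr6^2 - 2 * sr6)
      }
    }
    expect_equal(be$delta_G_bind, tot, tolerance = 1e-9)
  }
})

test_that("the decomposition identity is exact by reconstruction", {
  pm <- assign_parameters(small_bundle(seed = 12))
  be <- binding_energy(pm, 6, n_points = 120)
  expect_equal(be$delta_G_bind,
               be$terms_AB$G_TOTAL - be$terms_A$G_TOTAL -
                 be$terms_B$G_TOTAL, tolerance = 1e-12)
  expect_true(is.finite(be$delta_G_bind))
  # terms reported separately and consistent
  for (t in list(be$terms_AB, be$terms_A, be$terms_B)) {
    expect_equal(t$G_TOTAL, t$H_MM + t$G_solv, tolerance = 1e-12)
    expect_equal(t$G_solv, t$G_polar + t$G_nonpolar, tolerance = 1e-12)
  }
})
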