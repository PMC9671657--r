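# Hydropathy profiles, transmembrane segment prediction, compartment
# assignment, secondary structure and discontinuous-helix motifs.

test_that("hydropathy of constant sequences is the scale value", {
  expect_equal(as.numeric(hydropathy_profile(strrep("I", 30))),
               rep(4.5, 30))
  expect_equal(as.numeric(hydropathy_profile(strrep("R", 25))),
               rep(-4.5, 25))
  expect_error(hydropathy_profile("AXA"), "non-standard")
  expect_error(hydropathy_profile("AAAA", window = 4), "odd")
})

test_that("hydropathy matches the brute-force windowed mean", {
  set.seed(9)
  for (w in c(7, 19)) {
    s <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 120,
                      replace = TRUE), collapse = "")
    expect_equal(as.numeric(hydropathy_profile(s, w)),
                 oracle_hydropathy(s, w), tolerance = 1e-12)
  }
})

test_that("TM segment prediction finds constructed stretches", {
  all_k <- hydropathy_profile(strrep("K", 80))
  expect_equal(nrow(predict_tm_segments(all_k)$segments), 0)
  s <- paste0(strrep("R", 8), strrep("I", 21), strrep("R", 10),
              strrep("I", 21), strrep("R", 10), strrep("I", 21),
              strrep("R", 8))
  topo <- predict_tm_segments(hydropathy_profile(s, window = 7),
                              min_len = 15)
  expect_equal(nrow(topo$segments), 3)
  # each constructed Ile block is covered by one predicted segment
  blocks <- list(9:29, 40:60, 71:91)
  for (i in 1:3) {
    expect_lte(abs(topo$segments$start[i] - blocks[[i]][1]), 3)
    expect_lte(abs(topo$segments$end[i] - blocks[[i]][21]), 3)
  }
  expect_true(all(strsplit(paste(topo$location[10:28], collapse = ""),
                           "")[[1]] == "M"))
})

test_that("over-long hydrophobic runs are split at the internal minimum", {
  s <- paste0(strrep("I", 20), "G", strrep("I", 20))
  topo <- predict_tm_segments(hydropathy_profile(s, window = 5))
  expect_gte(nrow(topo$segments), 2)
  expect_true(all(topo$segments$end - topo$segments$start + 1 <= 35))
})

test_that("positive-inside rule orients the N-terminus", {
  # all Lys before the single TM segment: N-side must be cytoplasmic
  s <- paste0(strrep("K", 12), strrep("I", 21), strrep("S", 12))
  topo <- predict_tm_segments(hydropathy_profile(s, window = 7))
  expect_equal(nrow(topo$segments), 1)
  topo <- assign_compartments(topo)
  expect_equal(topo$n_terminus_side, "C")
  expect_equal(topo$location[1], "C")
  expect_equal(topo$location[length(topo$location)], "E")
  # mirrored charge: N-side extracellular
  s2 <- paste0(strrep("S", 12), strrep("I", 21), strrep("K", 12))
  topo2 <- assign_compartments(
    predict_tm_segments(hydropathy_profile(s2, window = 7)))
  expect_equal(topo2$n_terminus_side, "E")
})

test_that("loop labels alternate and cover every residue", {
  set.seed(6)
  for (rep in 1:5) {
    n_seg <- sample(2:5, 1)
    parts <- character(0)
    for (k in seq_len(n_seg)) {
      parts <- c(parts, paste(sample(c("K", "R", "S", "T", "G"), 8,
                                     replace = TRUE), collapse = ""),
                 strrep("I", 21))
    }
    s <- paste0(paste(parts, collapse = ""), strrep("S", 8))
    topo <- assign_compartments(
      predict_tm_segments(hydropathy_profile(s, window = 7)))
    expect_false(any(is.na(topo$location)))
    seg <- topo$segments
    loop_labels <- character(0)
    prev_end <- 0
    for (i in seq_len(nrow(seg))) {
      if (seg$start[i] > prev_end + 1) {
        loop_labels <- c(loop_labels, topo$location[prev_end + 1])
      }
      prev_end <- seg$end[i]
    }
    loop_labels <- c(loop_labels, topo$location[length(topo$location)])
    expect_true(all(loop_labels[-1] != loop_labels[-length(loop_labels)]))
  }
})

test_that("secondary structure: helix mostly H, extended chain has no H", {
  m <- generate_helix_bundle(bundle_spec(1, 20, seed = 3))
  ss <- as.character(assign_secondary_structure(m))
  expect_gte(mean(strsplit(ss, "")[[1]] == "H"), 0.9)
  expect_identical(ss, as.character(assign_secondary_structure(m)))
  # fully extended chain (phi = psi = 180)
  ext <- acr3kit:::ideal_helix_backbone(15, phi = 180, psi = 180)
  atoms <- do.call(rbind, lapply(1:15, function(i) {
    data.frame(serial = 4 * (i - 1) + 1:4,
               atom_name = c("N", "CA", "C", "O"), residue_name = "ALA",
               chain_id = "A", residue_index = i, orig_residue_index = i,
               x = c(ext$N[i, 1], ext$CA[i, 1], ext$C[i, 1], ext$O[i, 1]),
               y = c(ext$N[i, 2], ext$CA[i, 2], ext$C[i, 2], ext$O[i, 2]),
               z = c(ext$N[i, 3], ext$CA[i, 3], ext$C[i, 3], ext$O[i, 3]),
               element = c("N", "C", "C", "O"))
  }))
  ssx <- as.character(assign_secondary_structure(
    structure_model("ext", atoms)))
  expect_false(grepl("H", ssx))
})

test_that("discontinuous-helix motifs are reported within segments", {
  ss <- "HHHHHHCCHHHHHH"
  topo <- structure(list(
    segments = data.frame(start = 1, end = 14),
    location = rep("M", 14), n_terminus_side = "C",
    sequence = strrep("I", 14)), class = "acr3_topology")
  mot <- detect_discontinuous_helices(ss, topo)
  expect_equal(nrow(mot), 1)
  expect_equal(mot$arm1_start, 1)
  expect_equal(mot$arm1_end, 6)
  expect_equal(mot$break_start, 7)
  expect_equal(mot$break_end, 8)
  expect_equal(mot$arm2_start, 9)
  expect_equal(mot$arm2_end, 14)
  # continuous helix: no motif
  topo$segments <- data.frame(start = 1, end = 14)
  expect_equal(nrow(detect_discontinuous_helices(strrep("H", 14), topo)), 0)
  # break longer than max_break: no motif
  ss2 <- paste0(strrep("H", 5), strrep("C", 7), strrep("H", 5))
  topo2 <- topo
  topo2$segments <- data.frame(start = 1, end = 17)
  topo2$location <- rep("M", 17)
  topo2$sequence <- strrep("I", 17)
  expect_equal(nrow(detect_discontinuous_helices(ss2, topo2,
                                                 max_break = 6)), 0)
})

test_that("a built discontinuity in a bundle helix is detected", {
  # two helices joined by a short extended linker inside one 'segment'
  m <- generate_helix_bundle(bundle_spec(2, 12, loop_length = 3, seed = 2))
  ss <- as.character(assign_secondary_structure(m))
  n <- m$residue_count
  topo <- structure(list(
    segments = data.frame(start = 1, end = n),
    location = rep("M", n), n_terminus_side = "C",
    sequence = m$sequence), class = "acr3_topology")
  mot <- detect_discontinuous_helices(ss, topo, min_arm = 4, max_break = 6)
  expect_gte(nrow(mot), 1)
  expect_true(any(mot$break_start >= 12 & mot$break_end <= 17))
})
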