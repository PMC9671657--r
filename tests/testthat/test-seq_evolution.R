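# Codon alignment, NG86 selection statistics, identity, ordination, NJ
# trees and variant tables.

test_that("back_translate_alignment expands gaps to whole codons", {
  aln <- as_alignment(list(seq_record("a", "M-A"),
                           seq_record("b", "MCA")), "protein")
  cds <- list(seq_record("a", "ATGGCT"),
              seq_record("b", "ATGTGTGCT"))
  ca <- back_translate_alignment(aln, cds)
  expect_equal(ca$records[[1]]$residues, "ATG---GCT")
  expect_equal(ca$records[[2]]$residues, "ATGTGTGCT")
  expect_equal(ca$n_col %% 3, 0)
})

test_that("back_translate_alignment strips stops and validates input", {
  aln <- as_alignment(list(seq_record("a", "MA"),
                           seq_record("b", "MA")), "protein")
  ok <- back_translate_alignment(aln, list(seq_record("a", "ATGGCTTAA"),
                                           seq_record("b", "ATGGCT")))
  expect_equal(ok$records[[1]]$residues, "ATGGCT")
  expect_error(
    back_translate_alignment(aln, list(seq_record("a", "ATGGCTGCT"),
                                       seq_record("b", "ATGGCT"))),
    "length mismatch|CDS length")
  expect_error(
    back_translate_alignment(aln, list(seq_record("a", "ATGATT"),
                                       seq_record("b", "ATGGCT"))),
    "position 2")
  expect_error(
    back_translate_alignment(aln, list(seq_record("b", "ATGGCT"))),
    "no CDS for record 'a'")
})

test_that("back-translation round-trips a simulated family", {
  fam <- simulate_codon_family(codon_sim_spec(random_cds(60, seed = 2),
                                              n_taxa = 4, seed = 5))
  prots <- lapply(fam, function(r) {
    seq_record(r$id, paste(GC_TABLE[split_codons(r$residues)],
                           collapse = ""))
  })
  aln <- as_alignment(prots, "protein")
  ca <- back_translate_alignment(aln, fam)
  for (k in seq_along(fam)) {
    expect_equal(gsub("-", "", ca$records[[k]]$residues),
                 fam[[k]]$residues)
  }
})

test_that("NG86 basics: identical pair, pure synonymous, symmetry", {
  a <- random_cds(40, seed = 3)
  s0 <- nei_gojobori(a, a)
  expect_equal(s0$dN, 0)
  expect_equal(s0$dS, 0)
  expect_true(is.na(s0$ratio))
  s1 <- nei_gojobori("TTATTATTA", "TTATTATTG")
  expect_equal(s1$dN, 0)
  expect_gt(s1$dS, 0)
  expect_equal(s1$ratio, 0)
  b <- simulate_codon_family(codon_sim_spec(a, 1, 0.2, 0.5, seed = 8))[[2]]
  sab <- nei_gojobori(a, b$residues)
  sba <- nei_gojobori(b$residues, a)
  expect_equal(sab$dN, sba$dN)
  expect_equal(sab$dS, sba$dS)
})

test_that("NG86 skips gapped codon pairs and rejects bad input", {
  s <- nei_gojobori("ATG---GCTTTATTATTA", "ATGTTT---TTGTTATTA")
  expect_equal(s$n_codons_compared, 4)
  expect_error(nei_gojobori("ATG", "ATGGCT"), "length")
  expect_error(nei_gojobori("ATGTAA", "ATGTAA"), "stop")
  expect_error(nei_gojobori("TTA", "TTG"), "saturation")
})

test_that("NG86 matches the pathway-enumeration oracle on random pairs", {
  set.seed(17)
  for (rep in 1:30) {
    a <- rand_codons(30)
    fam <- simulate_codon_family(codon_sim_spec(a, 1, 0.5, 0.6,
                                                seed = rep))
    b <- fam[[2]]$residues
    got <- nei_gojobori(a, b)
    want <- oracle_ng86(a, b)
    expect_equal(got$dN, want$dN, tolerance = 1e-12)
    expect_equal(got$dS, want$dS, tolerance = 1e-12)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-12)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-12)
  }
})

test_that("pairwise identity: identical, single mismatch, empty input", {
  expect_equal(pairwise_identity("ACGT", "ACGT"), 100)
  expect_equal(pairwise_identity("ACGT", "ACGA"), 75)
  expect_equal(pairwise_identity("MKVLW", "MKVLW"), 100)
  expect_error(pairwise_identity("", "ACGT"), "empty")
})

test_that("identity matrix is symmetric with zero diagonal", {
  fam <- simulate_codon_family(codon_sim_spec(random_cds(50, seed = 9),
                                              n_taxa = 4, seed = 2))
  D <- identity_matrix(fam, "nucleotide")
  expect_equal(D$values, t(D$values))
  expect_equal(diag(D$values), rep(0, 5), ignore_attr = TRUE)
  expect_true(all(D$values >= 0))
  expect_error(identity_matrix(fam[1]), ">= 2")
})

test_that("classical MDS embeds a 3-4-5 triangle exactly", {
  D <- distance_matrix(c("a", "b", "c"),
                       matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3))
  X <- classical_mds(D, 2)
  got <- as.matrix(dist(X))
  expect_equal(got, D$values, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(classical_mds(D, 3), "dimension error")
})

test_that("classical MDS recovers planar configurations up to rigidity", {
  set.seed(23)
  for (rep in 1:5) {
    P <- matrix(runif(16, -10, 10), 8, 2)
    D <- as.matrix(dist(P))
    rownames(D) <- colnames(D) <- paste0("p", 1:8)
    X <- classical_mds(D, 2)
    pr <- vegan::procrustes(P, X, symmetric = FALSE)
    expect_lt(sqrt(mean(stats::residuals(pr)^2)), 1e-8)
    # sign convention makes the embedding reproducible
    expect_identical(X, classical_mds(D, 2))
  }
})

test_that("classical MDS agrees with cmdscale on embeddable matrices", {
  set.seed(4)
  P <- matrix(rnorm(30), 10, 3)
  D <- as.matrix(dist(P))
  rownames(D) <- colnames(D) <- letters[1:10]
  X <- classical_mds(D, 3)
  Y <- stats::cmdscale(D, k = 3)
  # same embedding up to per-axis sign
  for (j in 1:3) {
    expect_true(max(abs(X[, j] - Y[, j])) < 1e-8 ||
                  max(abs(X[, j] + Y[, j])) < 1e-8)
  }
})

test_that("NJ recovers an additive 4-taxon tree with exact branch lengths", {
  # additive matrix of tree ((A:2,B:1):3,(C:2,D:3))
  M <- matrix(c(0, 3, 7, 8,
                3, 0, 6, 7,
                7, 6, 0, 5,
                8, 7, 5, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(distance_matrix(LETTERS[1:4], M))
  expect_true(is_monophyletic_clade(tr, c("A", "B")))
  expect_true(is_monophyletic_clade(tr, c("C", "D")))
  # additive matrix: patristic distances reproduce the input exactly
  pat <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(pat, M, tolerance = 1e-9)
  tip_edges <- tr$edge[, 2] <= 4
  lens <- tr$edge.length[tip_edges][order(tr$edge[tip_edges, 2])]
  expect_equal(lens, c(2, 1, 2, 3))
})

test_that("NJ on 3 taxa solves the three-equation system exactly", {
  M <- matrix(c(0, 5, 9, 5, 0, 8, 9, 8, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- nj_tree(distance_matrix(c("x", "y", "z"), M))
  pat <- ape::cophenetic.phylo(tr)[c("x", "y", "z"), c("x", "y", "z")]
  expect_equal(pat, M, tolerance = 1e-9)
  expect_error(nj_tree(distance_matrix(c("x", "y"),
                                       matrix(c(0, 1, 1, 0), 2, 2))),
               ">= 3")
})

test_that("NJ recovers random additive topologies (four-point oracle)", {
  set.seed(12)
  for (rep in 1:10) {
    tr0 <- ape::rtree(6)
    tr0$edge.length <- runif(nrow(tr0$edge), 0.5, 3)
    M <- ape::cophenetic.phylo(tr0)
    labs <- rownames(M)
    tr <- nj_tree(distance_matrix(labs, M))
    expect_equal(ape::dist.topo(ape::unroot(tr0), ape::unroot(tr)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("variable_positions on identical and simple inputs", {
  aln0 <- as_alignment(list(seq_record("a", "MKV"),
                            seq_record("b", "MKV")), "protein")
  expect_equal(nrow(variable_positions(aln0)), 0)
  aln1 <- as_alignment(list(seq_record("a", "ACD"),
                            seq_record("b", "ACE")), "protein")
  vt <- variable_positions(aln1)
  expect_equal(vt$position, 3)
  expect_setequal(c(vt$a, vt$b), c("D", "E"))
  expect_equal(vt$side_chain_class, "negative")
})

test_that("side-chain classification is the five-way partition", {
  expect_equal(classify_side_chain("D"), "negative")
  expect_equal(classify_side_chain("H"), "positive")
  all20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  cls <- classify_side_chain(all20)
  expect_setequal(unique(cls), c("negative", "positive", "polar-uncharged",
                                 "hydrophobic", "special"))
  expect_equal(sort(all20[cls == "negative"]), c("D", "E"))
  expect_equal(sort(all20[cls == "positive"]), c("H", "K", "R"))
  expect_equal(sort(all20[cls == "polar-uncharged"]), c("N", "Q", "S", "T"))
  expect_equal(sort(all20[cls == "special"]), c("C", "G", "P"))
  expect_length(all20[cls == "hydrophobic"], 8)
  expect_error(classify_side_chain("B"), "non-standard")
})
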