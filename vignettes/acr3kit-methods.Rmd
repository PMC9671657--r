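---
title: "acr3kit: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{acr3kit: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`acr3kit` characterizes a family of closely related membrane-transporter
homologs — developed around the Acr3 arsenite-efflux permease — at three
levels: codon-level selection, sequence/structure clustering, and
residue-level interactions (contacts, hydrogen bonds, binding
energies). This vignette records the models implemented, the tunable
parameters and their defaults, what the synthetic-data generators do and
do not emulate, and the design decisions taken where the problem was
genuinely open. It states no empirical result that the test suite does
not itself compute.

## Selection statistics: Nei–Gojobori with Jukes–Cantor correction

`nei_gojobori()` implements the 1986 counting method. For each codon,
each of the nine possible single-nucleotide changes is classified as
synonymous or non-synonymous under the standard code; the synonymous
fraction (out of 3 per position) accumulates into the site counts `S`
and `N = 3L - S`, averaged over the two sequences. Observed differences
at codons differing in 1–3 positions are averaged with equal weight over
all minimal substitution pathways (2 or 6 orderings). Proportions
`pS = Sd/S` and `pN = Nd/N` receive the Jukes–Cantor correction
`d = -(3/4) ln(1 - 4p/3)`; `p >= 3/4` is a saturation error. The ratio
`dN/dS` is undefined (`NA`) when `dS = 0`.

Conventions the method leaves open were fixed as follows and are shared
by the independent enumeration oracle in the test suite:

* changes *to* a stop codon count as non-synonymous in site counting;
* pathways passing *through* a stop codon are excluded from the average
  (if all are blocked, all are used);
* codon pairs with an alignment gap in either sequence are skipped
  pairwise, not list-wise.

The estimator choice itself was open — the upstream toolchain named only
alignment preparation, not the dN/dS method — and NG86 was selected
because it is deterministic, closed-form, and admits an exact
brute-force oracle. Codon-model maximum-likelihood ω estimation is a
non-goal.

Two caveats discovered while testing, both properties of NG86 rather
than bugs: (i) on a *single* codon pair a purely synonymous change can
already saturate (`pS >= 3/4`), so the minimal "synonymous change gives
`dS > 0`" illustration needs a few codons of context; (ii) under pure
purifying evolution (ω = 0) the estimator's `dN` is exactly 0 only
while every substituted codon carries a single hit — with multiple hits
in one codon, pathway averaging introduces non-synonymous
*intermediates* even though every accepted substitution was synonymous.

## Back-translation and identity

`back_translate_alignment()` expands each amino-acid column of a
protein alignment to its source codon (`-` becomes `---`), after
verifying that each CDS (optionally carrying one trailing stop)
translates exactly to its ungapped protein.

`pairwise_identity()` is global Needleman–Wunsch identity: matches
divided by alignment columns, times 100. Scoring is fixed for
reproducibility: BLOSUM62 with gap open 10 / extend 0.5 for protein;
match +1 / mismatch 0 with the same gaps for nucleotide. The original
study computed gene identities with a genome-ANI tool that is
ill-specified at single-gene scale; global-alignment identity is the
documented approximation, stored as distance `100 - identity` in
`identity_matrix()`.

## Ordination and trees

`classical_mds()` is Torgerson scaling: double-center the squared
distance matrix, eigendecompose, keep the top-k positive-eigenvalue
axes scaled by the square roots of the eigenvalues. Requesting an axis
beyond the positive-eigenvalue rank is an error that reports the usable
rank. The sign of each axis is normalized so its first nonzero loading
is positive, making embeddings byte-reproducible; the test suite
cross-checks against `stats::cmdscale` and recovers planar point sets
to Procrustes error < 1e-8.

`nj_tree()` wraps `ape::nj` (Saitou–Nei). Negative branch-length
estimates are clamped to zero and counted in an attribute. Tree
inference by maximum likelihood was deliberately replaced by
neighbor-joining on the package's own distance matrices: only
topology-level statements (e.g. monophyly, via
`is_monophyletic_clade()`) are asserted, never likelihood-based
supports.

## Transmembrane topology

`hydropathy_profile()` computes the Kyte–Doolittle windowed mean
(window 19, truncated at the termini). `predict_tm_segments()` calls
maximal runs above threshold 1.6, merges runs separated by ≤ 3
residues, drops runs shorter than 17, and splits runs longer than 35 at
their internal minimum. These are standard Kyte–Doolittle practice
values, exposed in the configuration; the heuristic replaces external
HMM/neural predictors, so per-residue agreement with such tools is not
claimed — segment *counts* and charge sidedness are the testable
outputs.

`assign_compartments()` orients the topology by the positive-inside
rule: of the two alternating C/E loop labelings, the one maximizing
Arg+Lys on cytoplasmic loops wins; ties put the N-terminus inside. The
rule (rather than an assumed N-in) was chosen because the family
evidence for orientation is precisely the intracellular excess of
positively charged residues.

`assign_secondary_structure()` is a reduced Kabsch–Sander: amide
hydrogens are reconstructed on the bisector of N–C(prev) and N–CA at
1.01 Å (prolines and the N-terminus have none), the electrostatic
H-bond energy `E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)`
kcal/mol is thresholded at −0.5, helices are runs of consecutive
i → i+4 turns, and strands use a minimal reciprocal-bridge criterion
(full DSSP ladder bookkeeping is out of scope; the fixtures exercised
here are helical).

`detect_discontinuous_helices()` reports, inside each TM segment, a
helix arm of ≥ 4 residues, a break of 1–6 non-helix residues, and a
second arm of ≥ 4. The arm/break thresholds are not stated anywhere
authoritative; 4/6 admit the "extended peptide" breaks typical of
ion-transporter discontinuous helices while rejecting single-residue
kinks.

## Contact maps and structural comparison

`build_contact_map()`: residues i < j are in contact iff their Cα–Cα
distance is ≤ 8.0 Å. The boundary is inclusive and sequence neighbors
(|i−j| = 1) are retained — upstream tooling conventions are unstated, so
both choices are documented and all assertions use boundary-insensitive
invariants. `diff_contact_maps()` matches residues through a
Needleman–Wunsch alignment of the two sequences; a contact is *common*
when both endpoints align and the mapped pair is a contact of the other
map, otherwise *unique* (contacts touching unaligned residues are
unique by definition). `|unique_A| + |common| = total_A` therefore
holds exactly, and mirrored comparisons swap the unique sets. Hotspots
rank alignment columns by the number of differing contacts they touch,
ties broken by position; the exact criterion by which a published
figure promotes "greatest variation" positions is not stated, so the
ranking is exposed but not asserted against any external list.

`kabsch_superpose()` computes the optimal proper rotation by SVD with
reflection correction; degenerate (collinear) point sets are flagged
but still produce det = +1. `cluster_structures()` feeds the all-vs-all
matched-Cα RMSD matrix to average-linkage hierarchical clustering, cut
at a configured k or at the largest gap between merge heights.
Multiple structural alignment was replaced by sequence matching +
Kabsch: at > 90 % identity, sequence alignment is a faithful residue
correspondence.

## Interaction networks and hydrogen bonds

`interaction_network()` reports every residue with any atom within
5 Å of the focal residue's side-chain atoms (Cα fallback for glycine,
flagged). `detect_hbonds()` adopts VMD-like defaults: donor–acceptor
heavy-atom distance ≤ 3.0 Å and D–H···A within 20° of linear. When the
model carries no hydrogens (both bare and protonated inputs are
accepted), backbone amide hydrogens are reconstructed geometrically and
side-chain donors fall back to a heavy-atom-only distance rule at
3.2 Å, flagged `"heavy-only"`. Same-residue pairs are excluded.
`hbonds_near_residue()` keeps bonds where *either* partner has an atom
within the radius of the focal residue (the either-partner rule is what
makes published per-residue H-bond tables internally consistent). Note
one geometric fact used by the tests: an ideal α-helix built at
φ = −57°, ψ = −47° has N···O(i−4) = 3.09 Å, just outside the 3.0 Å
default, so helix-backbone demonstrations pass an explicit 3.2 Å
cutoff; the default remains 3.0.

## Energetics: simplified single-snapshot MM-GBSA

`binding_energy()` decomposes, on fixed coordinates,

`ΔG_bind = G_TOTAL(AB) − G_TOTAL(A) − G_TOTAL(B)`,

with A the focal residue's atoms, B all residues with any atom within
5 Å of A, and `G_TOTAL = H_MM + G_polar + G_nonpolar`:

* `H_MM` — non-bonded terms only: Coulomb `332.0636 q_i q_j/(ε_in r)`
  plus Lennard-Jones 12-6, excluding same-residue pairs and the
  peptide-bonded C(i)–N(i+1) pair. Bonded terms (bonds, angles) cancel
  in the decomposition except across the A/B boundary peptide bond,
  which is excluded — the "non-bonded decomposition" approximation.
* `G_polar` — Still pairwise generalized Born,
  `−166 (1/ε_in − 1/ε_out) ΣΣ q_i q_j / f_GB`,
  `f_GB = sqrt(r² + R_i R_j exp(−r²/4R_iR_j))`, self-terms included.
  Effective Born radii are the intrinsic radii (no HCT/OBC
  descreening); the Born single-charge limit anchors correctness.
* `G_nonpolar = γ·SASA` with γ = 0.0072 kcal/mol/Å², probe 1.4 Å,
  Shrake–Rupley sampling on a deterministic golden-spiral point set
  (960 points full-precision; 240 inside the pipeline for speed).
  A surface point exactly on a coincident neighbor's sphere is
  attributed to the earlier atom, so duplicated atoms expose one
  surface.

Defaults `ε_in = 1`, `ε_out = 78.5` are exposed in the parameter set.
Parameters come from a versioned, deliberately simplified table
(`inst/extdata/gb_params_v1.tsv`): fixed backbone partial charges, one
side-chain pseudo-atom carrying the residue's formal charge and a
size-dependent LJ/GB radius, and an exact per-residue charge balance
enforced through the Cα atom. Absolute energies are therefore
*decomposition-consistent, not force-field-accurate*: no absolute
kcal/mol value is asserted anywhere, only closed-form anchors,
pairwise-additivity oracles, and the exact ΔG identity. Snapshot
handling was an open question (the source workflow does not state
single-structure vs ensemble); the single-snapshot choice is this
package's documented decision, not an inference about the original
intent.

## Synthetic data: the stated world

`generate_helix_bundle()` places ideal α-helices (φ = −57°, ψ = −47°,
1.5 Å rise) antiparallel on a ring (default ten helices — the family's
architecture), connects them with extended arcs at ~3.6 Å per residue,
and attaches one side-chain pseudo-atom per non-glycine residue in the
Cβ direction at a residue-type-specific centroid distance.
`apply_mutations()` changes residue identities (and pseudo-atom
lengths) without touching the backbone; `perturb_structure()` adds
i.i.d. Gaussian noise. `simulate_codon_family()` evolves taxa
independently from a root by uniform single-nucleotide proposals,
rejecting stops and accepting non-synonymous changes with probability
ω. Uniform proposals (rather than a transition-biased kernel) were
chosen *a priori* because NG86's equal-weight site counting assumes
exactly that mutation process, making ω recoverable by construction;
defaults (ω = 0.13, branch 0.3) mirror the purifying regime of the
motivating family, and `generate_demo_dataset()` stitches the pieces
into a coherent strain family whose proteins, CDS and structures agree.

What the generators do **not** emulate — hence what a green test does
not establish: membrane embedding and lipid contacts; side-chain
rotamers (a centroid pseudo-atom cannot reproduce real packing, and on
this unrelaxed geometry the MM term at loop junctions is dominated by
short-range repulsion, so absolute ΔG_bind magnitudes on fixtures are
large and physically meaningless even though every identity holds);
indels (the codon simulator is substitution-only, so synthetic
alignments are gap-free); and transition/transversion or codon-usage
bias. Green tests establish that the *operations* are correct against
independent oracles and that ground-truth constructions (mutation
positions, cluster memberships, ω) are recovered — not that any
biological number is reproduced.

## Determinism and degenerate inputs

Every generator is a pure function of (spec, seed); a private RNG
stream is used and global state restored. The pipeline
(`run_full_analysis()`) echoes its full configuration into the report,
fails before any stage on missing inputs, records per-stage errors
without aborting independent stages, and skips individual focal
residues whose energetics raise a steric clash error (< 0.1 Å pair).
Degenerate cases have defined behavior throughout: empty interaction
environments yield ΔG_bind = 0 with a flag; zero TM segments are legal
(orientation then undefined); saturated codon pairs and rank-deficient
MDS requests raise informative errors; negative NJ branch lengths are
clamped and counted.

## Known limitations

* The hydropathy heuristic is not an HMM; boundary placement can shift
  by a few residues and the ten-segment count is parameter-dependent.
* Strand (E) assignment is minimal; only helices are first-class.
* GB radii are intrinsic (no descreening): polar solvation is
  systematically shallow for buried atoms.
* Identity on genes approximates an ANI-style measure with global
  alignment; per-pair values are method-dependent even when ranges
  agree.
* The CLI is a thin wrapper; orchestration logic lives in the exported
  functions and is tested there.
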