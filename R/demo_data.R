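# Coherent synthetic dataset: a codon family whose translated proteins
# are mutations of a helix-bundle sequence, with matching mutant/perturbed
# structure models. Every downstream stage of the pipeline can run on it
# with known ground truth.

reverse_translate <- function(protein, seed = 1) {
  gc <- genetic_code()
  by_aa <- split(names(gc), gc)
  aa <- strsplit(toupper(protein), "")[[1]]
  with_seed(seed, {
    paste(vapply(aa, function(a) {
      cands <- setdiff(by_aa[[a]], STOP_CODONS)
      cands[sample.int(length(cands), 1)]
    }, ""), collapse = "")
  })
}

#' Generate a complete synthetic strain family on disk
#'
#' Builds a helix-bundle reference structure, evolves a codon family from
#' the reverse-translated reference sequence under purifying selection
#' (`omega`), translates each taxon back to a protein, applies the
#' implied point mutations to the reference structure, and perturbs the
#' mutant structures in `n_clusters` groups (large parent displacement,
#' small within-group jitter) so that structural clustering has a known
#' answer. Writes protein FASTA, CDS FASTA, one PDB per strain and a
#' key-value config file.
#'
#' @param dir Output directory (created).
#' @param seed Integer seed driving every random choice.
#' @param n_strains Number of evolved strains (the reference is extra).
#' @param n_clusters Number of structural groups.
#' @param n_helices,residues_per_helix,loop_length Bundle architecture.
#' @param branch_length Expected substitutions/codon per strain.
#' @param omega Target dN/dS of the codon process.
#' @param parent_sigma,child_sigma Structural perturbation scales
#'   (Angstrom) between and within clusters.
#' @return The [analysis_config()] for the generated dataset (also written
#'   to `config.txt` in `dir`).
#' @export
generate_demo_dataset <- function(dir, seed = 1, n_strains = 6,
                                  n_clusters = 3, n_helices = 6,
                                  residues_per_helix = 18, loop_length = 3,
                                  branch_length = 0.15, omega = 0.13,
                                  parent_sigma = 0.8, child_sigma = 0.1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base_spec <- bundle_spec(n_helices = n_helices,
                           residues_per_helix = residues_per_helix,
                           loop_length = loop_length, seed = seed)
  base <- generate_helix_bundle(base_spec)
  root_cds <- reverse_translate(base$sequence, seed = seed + 1)
  fam <- simulate_codon_family(codon_sim_spec(
    root_cds, n_taxa = n_strains, branch_length = branch_length,
    omega = omega, seed = seed + 2))
  ids <- c("ref", paste0("strain", seq_len(n_strains)))
  cds_records <- lapply(seq_along(fam), function(k) {
    seq_record(ids[k], fam[[k]]$residues)
  })
  prot_records <- lapply(cds_records, function(r) {
    seq_record(r$id, translate_codons(r$residues))
  })
  base_aa <- strsplit(base$sequence, "")[[1]]
  models <- list(ref = base)
  models$ref$model_id <- "ref"
  # structural clusters: one shared parent displacement of the *base*
  # backbone per group (so group members share it exactly), strain
  # mutations applied on top, then a small per-member jitter; the
  # reference stays unperturbed
  group_of <- rep(seq_len(n_clusters), length.out = n_strains)
  parents <- lapply(seq_len(n_clusters), function(g) {
    perturb_structure(base, parent_sigma, seed = seed + 100 + g)
  })
  for (k in seq_len(n_strains)) {
    aa_k <- strsplit(prot_records[[k + 1]]$residues, "")[[1]]
    diffs <- which(aa_k != base_aa)
    mut <- if (length(diffs) > 0) {
      data.frame(position = diffs, new_residue = aa_k[diffs])
    } else list()
    m <- apply_mutations(parents[[group_of[k]]], mut)
    m <- perturb_structure(m, child_sigma, seed = seed + 200 + k)
    m$model_id <- ids[k + 1]
    models[[ids[k + 1]]] <- m
  }
  prot_path <- file.path(dir, "proteins.fasta")
  cds_path <- file.path(dir, "cds.fasta")
  write_fasta(prot_records, prot_path)
  write_fasta(cds_records, cds_path)
  struct_paths <- list()
  for (id in names(models)) {
    p <- file.path(dir, paste0(id, ".pdb"))
    write_structure(models[[id]], p)
    struct_paths[[id]] <- p
  }
  cfg <- analysis_config(structures = struct_paths, proteins = prot_path,
                         cds = cds_path, reference_id = "ref",
                         cluster_k = n_clusters, seed = seed,
                         key_residues = c(107, 294))
  cfg_lines <- c(
    sprintf("proteins: %s", prot_path),
    sprintf("cds: %s", cds_path),
    vapply(names(struct_paths), function(id) {
      sprintf("structures.%s: %s", id, struct_paths[[id]])
    }, ""),
    "reference_id: ref",
    sprintf("cluster_k: %d", n_clusters),
    sprintf("seed: %d", seed),
    "key_residues: 107, 294"
  )
  writeLines(cfg_lines, file.path(dir, "config.txt"))
  attr(cfg, "true_clusters") <- stats::setNames(group_of,
                                                ids[-1])
  cfg
}
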