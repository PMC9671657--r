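# Report emission: every analysis section to a standard text format
# (FASTA / Newick / TSV / JSON) plus a JSON manifest with checksums.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  path
}

dist_to_df <- function(D) {
  df <- data.frame(label = D$labels, stringsAsFactors = FALSE,
                   check.names = FALSE)
  cbind(df, as.data.frame(D$values, check.names = FALSE))
}

# "Thr-18 - Leu-14" style pair labels (Table-style H-bond layout)
hbond_pair_labels <- function(hb) {
  cap <- function(x) paste0(substr(x, 1, 1), tolower(substr(x, 2, 3)))
  sprintf("%s-%d - %s-%d", cap(hb$donor_resname), hb$donor_res,
          cap(hb$acceptor_resname), hb$acceptor_res)
}

topology_df <- function(topo) {
  data.frame(residue = seq_along(topo$location),
             aa = strsplit(topo$sequence, "")[[1]],
             location = topo$location, stringsAsFactors = FALSE)
}

#' Write an analysis bundle to a directory with a checksum manifest
#'
#' Emits one file per populated section of the bundle (gapped FASTA for
#' alignments, Newick for trees, TSV for tables, JSON for metadata) plus
#' `manifest.json` listing every file with its MD5 checksum.
#'
#' @param bundle An `acr3_report` from [run_full_analysis()], or any list
#'   with a compatible subset of sections.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest as a data.frame (`file`, `md5`).
#' @export
write_outputs <- function(bundle, out_dir) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("I/O error: cannot create ", out_dir)
  probe <- file.path(out_dir, ".write_test")
  tryCatch({ writeLines("x", probe); file.remove(probe) },
           error = function(e) stop("I/O error: ", out_dir, " not writable"))
  s <- if (!is.null(bundle$sections)) bundle$sections else bundle
  files <- character(0)
  emit <- function(path) files <<- c(files, path)

  if (!is.null(s$protein_alignment)) {
    emit(write_fasta(s$protein_alignment$records,
                     file.path(out_dir, "protein_alignment.fasta")))
  }
  if (!is.null(s$codon_alignment)) {
    emit(write_fasta(s$codon_alignment$records,
                     file.path(out_dir, "codon_alignment.fasta")))
  }
  if (!is.null(s$selection)) {
    emit(write_tsv(s$selection, file.path(out_dir, "selection_stats.tsv")))
  }
  for (nm in c("gene_distance", "protein_distance")) {
    if (!is.null(s[[nm]])) {
      emit(write_tsv(dist_to_df(s[[nm]]),
                     file.path(out_dir, paste0(nm, ".tsv"))))
    }
  }
  if (!is.null(s$mds)) {
    df <- data.frame(label = rownames(s$mds), s$mds, check.names = FALSE)
    emit(write_tsv(df, file.path(out_dir, "mds_coordinates.tsv")))
  }
  if (!is.null(s$tree)) {
    p <- file.path(out_dir, "nj_tree.nwk")
    ape::write.tree(s$tree, p)
    emit(p)
  }
  if (!is.null(s$variants)) {
    emit(write_tsv(s$variants, file.path(out_dir, "variant_table.tsv")))
  }
  for (id in names(s$topologies)) {
    topo <- s$topologies[[id]]
    emit(write_tsv(topo$segments,
                   file.path(out_dir, sprintf("tm_segments_%s.tsv", id))))
    emit(write_tsv(topology_df(topo),
                   file.path(out_dir, sprintf("topology_%s.tsv", id))))
  }
  for (id in names(s$contact_maps)) {
    cm <- s$contact_maps[[id]]
    df <- data.frame(i = cm$contacts[, 1], j = cm$contacts[, 2],
                     distance = round(cm$distances, 3))
    emit(write_tsv(df, file.path(out_dir, sprintf("contacts_%s.tsv", id))))
  }
  if (length(s$contact_diffs) > 0) {
    rows <- lapply(s$contact_diffs, function(d) {
      data.frame(model_a = d$model_ids[1], model_b = d$model_ids[2],
                 total_a = d$total_a, total_b = d$total_b,
                 unique_a = d$n_unique_a, unique_b = d$n_unique_b,
                 common = d$n_common, stringsAsFactors = FALSE)
    })
    emit(write_tsv(do.call(rbind, rows),
                   file.path(out_dir, "contact_diff_summary.tsv")))
  }
  if (length(s$networks) > 0) {
    rows <- lapply(names(s$networks), function(key) {
      net <- s$networks[[key]]
      if (nrow(net$partners) == 0) return(NULL)
      data.frame(model = sub("_res[0-9]+$", "", key),
                 focal = net$focal, net$partners, stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (length(rows) > 0) {
      emit(write_tsv(do.call(rbind, rows),
                     file.path(out_dir, "interaction_networks.tsv")))
    }
  }
  if (length(s$hbond_tables) > 0) {
    rows <- lapply(names(s$hbond_tables), function(key) {
      hb <- s$hbond_tables[[key]]
      if (nrow(hb) == 0) return(NULL)
      data.frame(model = sub("_res[0-9]+$", "", key),
                 focal = as.integer(sub("^.*_res", "", key)),
                 pair = hbond_pair_labels(hb),
                 hb, stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (length(rows) > 0) {
      emit(write_tsv(do.call(rbind, rows),
                     file.path(out_dir, "hbond_tables.tsv")))
    }
  }
  if (length(s$energies) > 0) {
    rows <- lapply(names(s$energies), function(key) {
      e <- s$energies[[key]]
      data.frame(model = sub("_res[0-9]+$", "", key), focal = e$focal,
                 G_TOTAL_AB = e$terms_AB$G_TOTAL,
                 G_TOTAL_A = e$terms_A$G_TOTAL,
                 G_TOTAL_B = if (is.null(e$terms_B)) NA_real_
                 else e$terms_B$G_TOTAL,
                 delta_G_bind = e$delta_G_bind,
                 n_environment = length(e$environment),
                 stringsAsFactors = FALSE)
    })
    emit(write_tsv(do.call(rbind, rows),
                   file.path(out_dir, "binding_energies.tsv")))
  }
  if (!is.null(s$clusters)) {
    df <- data.frame(model_id = names(s$clusters$labels),
                     cluster = as.integer(s$clusters$labels),
                     stringsAsFactors = FALSE)
    emit(write_tsv(df, file.path(out_dir, "structure_clusters.tsv")))
    emit(write_tsv(dist_to_df(s$clusters$rmsd),
                   file.path(out_dir, "rmsd_matrix.tsv")))
  }
  meta <- list(
    package = "acr3kit",
    version = as.character(utils::packageVersion("acr3kit")),
    config = bundle$config,
    errors = bundle$errors,
    sections_present = names(Filter(Negate(is.null), s))
  )
  meta_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  emit(meta_path)

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, dataframe = "rows")
  invisible(manifest)
}
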