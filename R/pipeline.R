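# Config-driven orchestration: sequences -> alignment -> selection /
# identity / ordination / tree -> variants -> topology -> per-structure
# contacts and secondary structure -> pairwise contact diffs -> clusters
# -> networks / H-bonds -> per-residue binding energies. Stages fail
# independently; errors are recorded and dependent stages skipped.

pipeline_log <- function(verbose, ...) {
  if (verbose) message(format(Sys.time(), "%H:%M:%S "), sprintf(...))
}

#' Run the full comparative analysis
#'
#' @param config [analysis_config()] object (or plain list / path to a
#'   [read_config()] file).
#' @param verbose Log stage progress to stderr.
#' @return Object of class `acr3_report`: list with `sections` (see
#'   [write_outputs()] for the section names), `errors` (named list of
#'   stage error messages) and `config` (the echoed configuration,
#'   sufficient to re-run the analysis). Fully deterministic given
#'   config + seed.
#' @export
run_full_analysis <- function(config, verbose = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- read_config(config)
  }
  config <- as_analysis_config(config)
  # fail before any stage on missing inputs
  for (field in c("proteins", "cds")) {
    v <- config[[field]]
    if (is.character(v) && !file.exists(v)) {
      stop("config error: ", field, " file not found: ", v)
    }
  }
  for (id in names(config$structures)) {
    v <- config$structures[[id]]
    if (is.character(v) && !file.exists(v)) {
      stop("config error: structure file not found for '", id, "': ", v)
    }
  }
  sections <- list()
  errors <- list()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      pipeline_log(verbose, "stage %s FAILED: %s", name,
                   conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      sections[[name]] <<- res
      pipeline_log(verbose, "stage %s done", name)
    }
    res
  }

  proteins <- NULL
  if (!is.null(config$proteins)) {
    proteins <- stage("proteins_raw", {
      if (is.character(config$proteins)) read_fasta(config$proteins)
      else config$proteins
    })
    sections$proteins_raw <- NULL
  }
  cds <- NULL
  if (!is.null(config$cds)) {
    cds <- if (is.character(config$cds)) {
      tryCatch(read_fasta(config$cds),
               error = function(e) { errors$cds <<- conditionMessage(e); NULL })
    } else config$cds
  }

  aln <- NULL
  if (!is.null(proteins)) {
    aln <- stage("protein_alignment", align_proteins(proteins))
  }
  codon_aln <- NULL
  if (!is.null(aln) && !is.null(cds)) {
    codon_aln <- stage("codon_alignment",
                       back_translate_alignment(aln, cds))
  }
  if (!is.null(codon_aln) && !is.null(config$reference_id)) {
    stage("selection",
          selection_vs_reference(codon_aln$records, config$reference_id))
  }
  if (!is.null(cds)) {
    gene_dist <- stage("gene_distance", identity_matrix(cds, "nucleotide"))
    if (!is.null(gene_dist)) {
      if (length(gene_dist$labels) > 3) {
        stage("mds", classical_mds(gene_dist, 2))
      }
      if (length(gene_dist$labels) >= 3) {
        stage("tree", nj_tree(gene_dist))
      }
    }
  }
  if (!is.null(proteins)) {
    stage("protein_distance", identity_matrix(proteins, "protein"))
  }

  # topology of every protein; reference topology feeds the variant table
  topologies <- NULL
  if (!is.null(proteins)) {
    topologies <- stage("topologies", {
      out <- list()
      for (r in proteins) {
        prof <- hydropathy_profile(r, window = config$tm_window)
        topo <- predict_tm_segments(prof, threshold = config$tm_threshold,
                                    min_len = config$tm_min_len,
                                    merge_gap = config$tm_merge_gap)
        if (nrow(topo$segments) > 0) topo <- assign_compartments(topo)
        out[[r$id]] <- topo
      }
      out
    })
  }
  variants <- NULL
  if (!is.null(aln)) {
    variants <- stage("variants", {
      ref_topo <- NULL
      if (!is.null(topologies)) {
        ref_id <- if (!is.null(config$reference_id) &&
                        config$reference_id %in% names(topologies)) {
          config$reference_id
        } else names(topologies)[1]
        ref_topo <- topologies[[ref_id]]
        if (nrow(ref_topo$segments) == 0) ref_topo <- NULL
      }
      variable_positions(aln, topology = ref_topo)
    })
  }

  models <- NULL
  if (length(config$structures) > 0) {
    models <- stage("models", {
      out <- list()
      for (id in names(config$structures)) {
        v <- config$structures[[id]]
        out[[id]] <- if (inherits(v, "acr3_structure")) v
        else read_structure(v, model_id = id)
      }
      out
    })
    sections$models <- NULL
  }

  if (!is.null(models)) {
    stage("contact_maps", {
      lapply(models, build_contact_map, cutoff = config$contact_cutoff)
    })
    stage("secondary_structure", lapply(models, function(m) {
      as.character(assign_secondary_structure(m))
    }))
    if (!is.null(sections$contact_maps) && length(models) > 1) {
      stage("contact_diffs", {
        ids <- names(models)
        out <- list()
        for (i in seq_len(length(ids) - 1)) {
          for (j in (i + 1):length(ids)) {
            key <- paste(ids[i], ids[j], sep = "__")
            out[[key]] <- diff_contact_maps(
              sections$contact_maps[[ids[i]]],
              sections$contact_maps[[ids[j]]])
          }
        }
        out
      })
    }
    if (length(models) > 1) {
      stage("clusters", cluster_structures(models, k = config$cluster_k))
    }
    # focal residues: configured key residues plus variable positions
    focal <- sort(unique(c(
      config$key_residues,
      if (!is.null(variants)) variants$position
    )))
    if (length(focal) > 0) {
      stage("networks", {
        out <- list()
        for (id in names(models)) {
          m <- models[[id]]
          for (p in focal[focal <= m$residue_count]) {
            out[[sprintf("%s_res%d", id, p)]] <-
              interaction_network(m, p, radius = config$network_radius)
          }
        }
        out
      })
      stage("hbond_tables", {
        out <- list()
        for (id in names(models)) {
          m <- models[[id]]
          for (p in focal[focal <= m$residue_count]) {
            out[[sprintf("%s_res%d", id, p)]] <-
              hbonds_near_residue(m, p, radius = config$network_radius,
                                  d_cutoff = config$hbond_d_cutoff,
                                  angle_cutoff = config$hbond_angle_cutoff)
          }
        }
        out
      })
      energy_focal <- sort(unique(c(
        config$key_residues,
        if (!is.null(variants)) {
          utils::head(variants$position,
                      min(length(variants$position),
                          config$energy_max_positions))
        }
      )))
      stage("energies", {
        params <- default_parameter_set()
        out <- list()
        skipped <- character(0)
        for (id in names(models)) {
          pm <- assign_parameters(models[[id]], params)
          for (p in energy_focal[energy_focal <= pm$residue_count]) {
            key <- sprintf("%s_res%d", id, p)
            # a steric clash at one focal residue (possible on unrelaxed
            # inputs) must not take down the whole stage
            res <- tryCatch(
              suppressWarnings(
                binding_energy(pm, p, radius = config$network_radius,
                               params = params)),
              error = function(e) NULL)
            if (is.null(res)) skipped <- c(skipped, key)
            else out[[key]] <- res
          }
        }
        attr(out, "skipped") <- skipped
        out
      })
    }
  }

  report <- structure(list(sections = sections, errors = errors,
                           config = config_echo(config)),
                      class = "acr3_report")
  if (!is.null(config$out_dir)) {
    write_outputs(report, config$out_dir)
  }
  report
}

# JSON-serializable echo of the configuration
config_echo <- function(config) {
  cfg <- unclass(config)
  cfg$structures <- lapply(cfg$structures, function(v) {
    if (inherits(v, "acr3_structure")) paste0("<in-memory:", v$model_id, ">")
    else v
  })
  for (nm in c("proteins", "cds")) {
    if (!is.null(cfg[[nm]]) && !is.character(cfg[[nm]])) {
      cfg[[nm]] <- sprintf("<in-memory:%d records>", length(cfg[[nm]]))
    }
  }
  cfg$energy_max_positions <-
    if (is.infinite(cfg$energy_max_positions)) "all"
  else cfg$energy_max_positions
  cfg
}

#' @export
print.acr3_report <- function(x, ...) {
  cat("<acr3_report>\n  sections:",
      paste(names(x$sections), collapse = ", "), "\n")
  if (length(x$errors) > 0) {
    cat("  errors:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}
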