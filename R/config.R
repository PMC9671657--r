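# Flat key-value configuration files. The format is a minimal YAML
# subset -- one `key: value` pair per line, `#` comments, comma-separated
# lists -- parsed in-repo because no YAML reader ships with the
# environment's R stack.

coerce_value <- function(v) {
  v <- trimws(v)
  if (grepl(",", v)) {
    return(unlist(lapply(strsplit(v, ",")[[1]], coerce_value)))
  }
  if (v %in% c("true", "TRUE", "yes")) return(TRUE)
  if (v %in% c("false", "FALSE", "no")) return(FALSE)
  if (v %in% c("null", "NULL", "~", "")) return(NULL)
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) return(num)
  v
}

#' Read a flat key-value configuration file
#'
#' Schema: one `key: value` per line; `#` starts a comment; commas make
#' vectors; numbers and true/false are coerced. Keys with a
#' `structures.` prefix collect into the named `structures` list
#' (`structures.<id>: <pdb path>`).
#'
#' @param path Configuration file path.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config error: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (l in lines) {
    if (!grepl(":", l)) stop("config error: line without ':': ", l)
    key <- trimws(sub(":.*$", "", l))
    val <- coerce_value(sub("^[^:]*:", "", l))
    if (startsWith(key, "structures.")) {
      id <- sub("^structures\\.", "", key)
      out$structures[[id]] <- val
    } else {
      out[[key]] <- val
    }
  }
  out
}

#' Build a validated analysis configuration
#'
#' @param structures Named list/vector mapping model id to PDB path (or
#'   directly to [structure_model()] objects).
#' @param proteins Path to a protein FASTA (or list of records).
#' @param cds Path to a CDS FASTA (or list of records).
#' @param reference_id Reference sequence id for selection statistics
#'   (e.g. an outgroup strain).
#' @param contact_cutoff CA contact cutoff, Angstrom.
#' @param network_radius Interaction-network / H-bond / energetics
#'   neighborhood radius, Angstrom.
#' @param key_residues Focal positions for interaction networks; defaults
#'   to the catalytic cysteine/glutamate positions 107 and 294 of the
#'   Acr3 family.
#' @param tm_window,tm_threshold,tm_min_len,tm_merge_gap Hydropathy
#'   topology parameters.
#' @param hbond_d_cutoff,hbond_angle_cutoff H-bond geometry parameters.
#' @param cluster_k Number of structural clusters (`NULL` = largest
#'   linkage gap).
#' @param energy_max_positions Cap on the number of variable positions
#'   sent to the binding-energy stage (cost control; `Inf` = all).
#' @param seed Integer seed echoed into the report.
#' @param out_dir Optional output directory for [write_outputs()].
#' @return Named list of class `acr3_config`.
#' @export
analysis_config <- function(structures = NULL, proteins = NULL, cds = NULL,
                            reference_id = NULL, contact_cutoff = 8.0,
                            network_radius = 5.0,
                            key_residues = c(107, 294),
                            tm_window = 19, tm_threshold = 1.6,
                            tm_min_len = 17, tm_merge_gap = 3,
                            hbond_d_cutoff = 3.0, hbond_angle_cutoff = 20,
                            cluster_k = NULL, energy_max_positions = Inf,
                            seed = 1, out_dir = NULL) {
  if (contact_cutoff <= 0 || network_radius <= 0) {
    stop("config error: cutoffs must be positive")
  }
  cfg <- list(structures = structures, proteins = proteins, cds = cds,
              reference_id = reference_id, contact_cutoff = contact_cutoff,
              network_radius = network_radius, key_residues = key_residues,
              tm_window = tm_window, tm_threshold = tm_threshold,
              tm_min_len = tm_min_len, tm_merge_gap = tm_merge_gap,
              hbond_d_cutoff = hbond_d_cutoff,
              hbond_angle_cutoff = hbond_angle_cutoff,
              cluster_k = cluster_k,
              energy_max_positions = energy_max_positions,
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "acr3_config"
  cfg
}

as_analysis_config <- function(x) {
  if (inherits(x, "acr3_config")) return(x)
  known <- names(formals(analysis_config))
  do.call(analysis_config, x[intersect(names(x), known)])
}
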