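# PDB structure I/O. Fixed-column PDB 3.3 ATOM parsing; predicted-model
# PDBs are often minimal, so the element column may be absent and is then
# inferred from the atom name. Only ATOM records of one chain are kept;
# alternate locations beyond the first are dropped.

#' Construct a structure model from an atom table
#'
#' @param model_id Identifier for the model.
#' @param atoms data.frame with columns `serial`, `atom_name`,
#'   `residue_name`, `chain_id`, `residue_index` (1-based consecutive),
#'   `orig_residue_index`, `x`, `y`, `z`, `element`.
#' @return An object of class `acr3_structure` with fields `model_id`,
#'   `atoms`, `sequence` (derived 1-letter string, `X` for non-standard
#'   residues) and `residue_count`.
#' @export
structure_model <- function(model_id, atoms) {
  req <- c("serial", "atom_name", "residue_name", "chain_id",
           "residue_index", "orig_residue_index", "x", "y", "z", "element")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0) stop("structure error: no atoms")
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    stop("structure error: non-finite coordinates")
  }
  ridx <- atoms$residue_index
  if (any(ridx < 1)) stop("structure error: residue_index must be >= 1")
  # residues must be contiguous blocks
  blocks <- rle(ridx)$values
  if (anyDuplicated(blocks)) {
    stop("structure error: atoms of a residue are not contiguous")
  }
  res_ids <- as.integer(unique(ridx))
  if (!identical(res_ids, seq_along(res_ids))) {
    stop("structure error: residue indices must be consecutive from 1")
  }
  ca <- atoms$atom_name == "CA"
  no_ca <- setdiff(res_ids, unique(ridx[ca]))
  if (length(no_ca) > 0) {
    stop("structure error: residue(s) missing CA atom: ",
         paste(no_ca, collapse = ", "))
  }
  first_of_res <- !duplicated(ridx)
  res_names <- atoms$residue_name[first_of_res]
  one <- AA_THREE_TO_ONE[res_names]
  one[is.na(one)] <- "X"
  structure(list(
    model_id = model_id,
    atoms = atoms,
    sequence = paste(one, collapse = ""),
    residue_count = length(res_ids)
  ), class = "acr3_structure")
}

#' @export
print.acr3_structure <- function(x, ...) {
  cat(sprintf("<acr3_structure> %s: %d residues, %d atoms\n",
              x$model_id, x$residue_count, nrow(x$atoms)))
  invisible(x)
}

infer_element <- function(atom_name) {
  first <- substr(gsub("[0-9 ]", "", atom_name), 1, 1)
  ifelse(first %in% c("C", "N", "O", "S", "H", "P"), first, "C")
}

#' Read a single-chain protein model from a PDB file
#'
#' Keeps only `ATOM` records of the selected chain; `HETATM`, waters and
#' alternate locations other than the first are discarded. Residues are
#' renumbered 1..N consecutively while the source numbering is retained
#' in `orig_residue_index`.
#'
#' @param path PDB file path.
#' @param chain Chain identifier; default is the first chain encountered.
#' @param model_id Model identifier; defaults to the file base name.
#' @return [structure_model()] object.
#' @export
read_structure <- function(path, chain = NULL, model_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(model_id)) model_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  atom_lines <- lines[startsWith(lines, "ATOM")]
  if (length(atom_lines) == 0) {
    stop("PDB format error: no ATOM records in ", path)
  }
  fx <- function(l, a, b) substr(l, a, b)
  df <- data.frame(
    serial = as.integer(fx(atom_lines, 7, 11)),
    atom_name = trimws(fx(atom_lines, 13, 16)),
    alt_loc = fx(atom_lines, 17, 17),
    residue_name = trimws(fx(atom_lines, 18, 20)),
    chain_id = fx(atom_lines, 22, 22),
    orig_residue_index = as.integer(fx(atom_lines, 23, 26)),
    x = as.numeric(fx(atom_lines, 31, 38)),
    y = as.numeric(fx(atom_lines, 39, 46)),
    z = as.numeric(fx(atom_lines, 47, 54)),
    element = trimws(fx(atom_lines, 77, 78)),
    stringsAsFactors = FALSE
  )
  if (is.null(chain)) chain <- df$chain_id[1]
  df <- df[df$chain_id == chain, , drop = FALSE]
  if (nrow(df) == 0) stop("PDB format error: chain '", chain, "' not found")
  # alternate locations: keep the first conformer per (residue, atom)
  keep <- !duplicated(paste(df$orig_residue_index, df$atom_name))
  df <- df[keep, , drop = FALSE]
  df$alt_loc <- NULL
  no_elem <- !nzchar(df$element)
  df$element[no_elem] <- infer_element(df$atom_name[no_elem])
  # renumber: consecutive 1..N in order of appearance
  df$residue_index <- match(df$orig_residue_index,
                            unique(df$orig_residue_index))
  rownames(df) <- NULL
  structure_model(model_id, df)
}

#' Write a structure model to a PDB file
#'
#' @param model [structure_model()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  name_fmt <- ifelse(nchar(a$atom_name) < 4,
                     sprintf(" %-3s", a$atom_name),
                     a$atom_name)
  lines <- sprintf(
    "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$serial %% 100000L, name_fmt, a$residue_name, a$chain_id,
    a$residue_index %% 10000L, a$x, a$y, a$z, 1, 0, a$element
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# n x 3 coordinate matrix of one atom type, ordered by residue_index
atom_coords <- function(model, atom_name = "CA") {
  a <- model$atoms[model$atoms$atom_name == atom_name, , drop = FALSE]
  a <- a[order(a$residue_index), , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$residue_index
  m
}

# atoms data.frame subset for one residue index
residue_atoms <- function(model, residue_index) {
  model$atoms[model$atoms$residue_index == residue_index, , drop = FALSE]
}
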