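# FASTA reading/writing. Deliberately minimal and order-preserving:
# records come back in file order, sequence whitespace is stripped, and
# empty records are a format error rather than a silent zero-length string.

#' Create a sequence record
#'
#' @param id Non-empty identifier.
#' @param residues Non-empty residue string (amino acid or nucleotide;
#'   `-` gap characters are allowed for alignment rows).
#' @param description Free-text description (may be empty).
#' @return An object of class `acr3_seq` with fields `id`, `description`
#'   and `residues`.
#' @export
seq_record <- function(id, residues, description = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("sequence id must be a non-empty string")
  }
  residues <- toupper(gsub("\\s", "", as.character(residues)))
  if (length(residues) != 1L || !nzchar(residues)) {
    stop("record '", id, "' has an empty sequence")
  }
  structure(list(id = id, description = description, residues = residues),
            class = "acr3_seq")
}

#' @export
print.acr3_seq <- function(x, ...) {
  n <- nchar(x$residues)
  head <- substr(x$residues, 1, 40)
  cat(sprintf("<acr3_seq> %s (%d residues)\n  %s%s\n", x$id, n, head,
              if (n > 40) "..." else ""))
  invisible(x)
}

#' Read a FASTA file
#'
#' @param path Path to a FASTA file. Gapped alignment FASTA is accepted.
#' @return List of [seq_record()] objects in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("FASTA format error: empty file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("FASTA format error: file does not start with '>': ", path)
  grp <- cumsum(hdr)
  records <- vector("list", sum(hdr))
  heads <- lines[hdr]
  for (k in seq_along(records)) {
    body <- lines[grp == k & !hdr]
    header <- sub("^>", "", heads[k])
    id <- sub("\\s.*$", "", header)
    desc <- ifelse(grepl("\\s", header), sub("^\\S+\\s+", "", header), "")
    if (length(body) == 0) {
      stop("FASTA format error: empty sequence for record '", id, "'")
    }
    records[[k]] <- seq_record(id, paste(body, collapse = ""), desc)
  }
  records
}

#' Write sequence records to FASTA
#'
#' @param records List of [seq_record()] objects (or a single record).
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  if (inherits(records, "acr3_seq")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    header <- if (nzchar(r$description)) paste(r$id, r$description) else r$id
    writeLines(paste0(">", header), con)
    s <- r$residues
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

# named list id -> record
seq_index <- function(records) {
  stats::setNames(records, vapply(records, `[[`, "", "id"))
}
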