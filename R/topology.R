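# Transmembrane topology from hydropathy, compartment assignment by the
# positive-inside rule, and discontinuous-helix detection.

#' Kyte-Doolittle hydropathy profile
#'
#' Sliding-window mean of per-residue Kyte-Doolittle hydropathy values.
#' Terminal half-windows are computed on the truncated window.
#'
#' @param seq Protein sequence (string or [seq_record()]).
#' @param window Odd window length; 19 is the classic choice for
#'   transmembrane-helix scanning.
#' @return Numeric vector (length = sequence length) with attributes
#'   `window` and `sequence`, class `acr3_hydropathy`.
#' @export
hydropathy_profile <- function(seq, window = 19) {
  if (inherits(seq, "acr3_seq")) seq <- seq$residues
  seq <- toupper(seq)
  if (window %% 2 != 1 || window < 1) stop("input error: window must be odd")
  aa <- strsplit(seq, "")[[1]]
  bad <- setdiff(unique(aa), names(KD_SCALE))
  if (length(bad) > 0) {
    stop("input error: non-standard residue(s): ", paste(bad, collapse = ","))
  }
  vals <- KD_SCALE[aa]
  n <- length(vals)
  half <- (window - 1) / 2
  cs <- c(0, cumsum(vals))
  lo <- pmax(1, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  prof <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  structure(unname(prof), window = window, sequence = seq,
            class = "acr3_hydropathy")
}

#' Predict transmembrane segments from a hydropathy profile
#'
#' Maximal runs of the profile above `threshold` are candidate segments;
#' runs separated by gaps of at most `merge_gap` residues are merged, runs
#' shorter than `min_len` are discarded, and runs longer than 35 residues
#' are split at their internal hydropathy minimum.
#'
#' @param profile [hydropathy_profile()] object.
#' @param threshold Hydropathy threshold (default 1.6, Kyte-Doolittle
#'   practice for membrane-spanning segments).
#' @param min_len Minimum segment length (default 17).
#' @param merge_gap Maximum below-threshold gap merged into a run.
#' @return Object of class `acr3_topology`: list with `segments`
#'   (data.frame `start`/`end`, 1-based inclusive), per-residue `location`
#'   (`"M"` inside segments, `NA` until [assign_compartments()]),
#'   `n_terminus_side` (`NA` until oriented) and the source `sequence`.
#' @export
predict_tm_segments <- function(profile, threshold = 1.6, min_len = 17,
                                merge_gap = 3) {
  stopifnot(inherits(profile, "acr3_hydropathy"))
  vals <- as.numeric(profile)
  n <- length(vals)
  above <- vals > threshold
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  seg <- data.frame(start = starts[runs$values],
                    end = ends[runs$values])
  # merge runs separated by small gaps
  if (nrow(seg) > 1) {
    merged <- seg[1, , drop = FALSE]
    for (i in 2:nrow(seg)) {
      gap <- seg$start[i] - merged$end[nrow(merged)] - 1
      if (gap <= merge_gap) {
        merged$end[nrow(merged)] <- seg$end[i]
      } else {
        merged <- rbind(merged, seg[i, ])
      }
    }
    seg <- merged
  }
  seg <- seg[seg$end - seg$start + 1 >= min_len, , drop = FALSE]
  # split over-long runs at the internal minimum
  out <- data.frame(start = integer(0), end = integer(0))
  queue <- seg
  while (nrow(queue) > 0) {
    s <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
    len <- s$end - s$start + 1
    if (len <= 35) {
      out <- rbind(out, s)
    } else {
      interior <- (s$start + 1):(s$end - 1)
      m <- interior[which.min(vals[interior])]
      parts <- data.frame(start = c(s$start, m + 1), end = c(m - 1, s$end))
      parts <- parts[parts$end - parts$start + 1 >= min_len, , drop = FALSE]
      queue <- rbind(parts, queue)
    }
  }
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  location <- rep(NA_character_, n)
  for (i in seq_len(nrow(out))) location[out$start[i]:out$end[i]] <- "M"
  structure(list(segments = out, location = location,
                 n_terminus_side = NA_character_,
                 sequence = attr(profile, "sequence")),
            class = "acr3_topology")
}

#' @export
print.acr3_topology <- function(x, ...) {
  cat(sprintf("<acr3_topology> %d TM segment(s), N-terminus: %s\n",
              nrow(x$segments),
              if (is.na(x$n_terminus_side)) "unoriented"
              else x$n_terminus_side))
  if (nrow(x$segments) > 0) print(x$segments)
  invisible(x)
}

#' Assign E/M/C compartments by the positive-inside rule
#'
#' Loops between transmembrane segments alternate between cytoplasmic
#' (`C`) and extracellular (`E`); the orientation chosen is the one
#' maximizing the count of Arg+Lys residues on C-side loops (ties:
#' N-terminus cytoplasmic).
#'
#' @param topology `acr3_topology` from [predict_tm_segments()] with
#'   >= 1 segment.
#' @param seq Optional protein sequence (defaults to the profile's).
#' @return The topology with `location` fully assigned and
#'   `n_terminus_side` set.
#' @export
assign_compartments <- function(topology, seq = NULL) {
  stopifnot(inherits(topology, "acr3_topology"))
  if (nrow(topology$segments) < 1) {
    stop("input error: need >= 1 transmembrane segment to orient")
  }
  if (is.null(seq)) seq <- topology$sequence
  if (inherits(seq, "acr3_seq")) seq <- seq$residues
  aa <- strsplit(toupper(seq), "")[[1]]
  n <- length(aa)
  seg <- topology$segments
  loop_of <- function(first_side) {
    loc <- rep(NA_character_, n)
    side <- first_side
    prev_end <- 0
    for (i in seq_len(nrow(seg))) {
      if (seg$start[i] > prev_end + 1) {
        loc[(prev_end + 1):(seg$start[i] - 1)] <- side
      }
      loc[seg$start[i]:seg$end[i]] <- "M"
      prev_end <- seg$end[i]
      side <- if (side == "C") "E" else "C"
    }
    if (prev_end < n) loc[(prev_end + 1):n] <- side
    loc
  }
  score <- function(loc) sum(aa[which(loc == "C")] %in% c("R", "K"))
  loc_c <- loop_of("C")
  loc_e <- loop_of("E")
  if (score(loc_e) > score(loc_c)) {
    topology$location <- loc_e
    topology$n_terminus_side <- "E"
  } else {
    topology$location <- loc_c
    topology$n_terminus_side <- "C"
  }
  topology$sequence <- paste(aa, collapse = "")
  topology
}

#' Detect discontinuous ("helix - extended peptide - helix") motifs
#'
#' Within each transmembrane segment, reports every occurrence of a helix
#' run of at least `min_arm` residues, followed by 1..`max_break` non-helix
#' residues, followed by another helix run of at least `min_arm`.
#'
#' @param ss Secondary-structure string (from
#'   [assign_secondary_structure()]) or plain character string over
#'   `H`/`E`/`C`.
#' @param topology `acr3_topology` covering the same residues.
#' @param min_arm Minimum helix-arm length.
#' @param max_break Maximum break length.
#' @return data.frame with columns `segment_id`, `arm1_start`, `arm1_end`,
#'   `break_start`, `break_end`, `arm2_start`, `arm2_end` (residue
#'   coordinates).
#' @export
detect_discontinuous_helices <- function(ss, topology, min_arm = 4,
                                         max_break = 6) {
  if (inherits(ss, "acr3_ss")) ss <- as.character(ss)
  if (nchar(ss) != length(topology$location)) {
    stop("input error: ss and topology cover different residue counts")
  }
  seg <- topology$segments
  out <- data.frame(segment_id = integer(0), arm1_start = integer(0),
                    arm1_end = integer(0), break_start = integer(0),
                    break_end = integer(0), arm2_start = integer(0),
                    arm2_end = integer(0))
  pat <- sprintf("(H{%d,})([^H]{1,%d})(H{%d,})", min_arm, max_break, min_arm)
  for (i in seq_len(nrow(seg))) {
    sub <- substr(ss, seg$start[i], seg$end[i])
    offset <- seg$start[i] - 1
    from <- 1
    repeat {
      m <- regexec(pat, substr(sub, from, nchar(sub)), perl = TRUE)[[1]]
      if (m[1] == -1) break
      starts <- m + from - 1
      lens <- attr(m, "match.length")
      a1s <- starts[2]; a1e <- a1s + lens[2] - 1
      brs <- starts[3]; bre <- brs + lens[3] - 1
      a2s <- starts[4]; a2e <- a2s + lens[4] - 1
      out <- rbind(out, data.frame(
        segment_id = i,
        arm1_start = a1s + offset, arm1_end = a1e + offset,
        break_start = brs + offset, break_end = bre + offset,
        arm2_start = a2s + offset, arm2_end = a2e + offset))
      from <- a2s  # allow the second arm to start a new motif
      if (from > nchar(sub)) break
    }
  }
  rownames(out) <- NULL
  out
}
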