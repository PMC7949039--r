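#' Decide the reading frame of mapped fragments
#'
#' The frame of a reconstructed fragment is a pure function of its leftmost
#' mapped base relative to the ORF start codon, `(start - cds_start) mod 3`,
#' and its strand — the same rule the library simulator uses at cloning time,
#' because that base is what recombination fused to the adaptor. Singletons
#' and unmapped records get `NA` (no frame).
#'
#' @param fragments fragments data.frame of a `mapping_result`.
#' @param plasmid a [plasmid_map].
#' @param label_map a [frame_label_map].
#' @return the data.frame with a `frame` column added.
#' @export
decide_frame <- function(fragments, plasmid, label_map = frame_label_map()) {
  frame <- rep(NA_character_, nrow(fragments))
  ok <- fragments$status == "proper_pair"
  frame[ok] <- assign_frame_label(fragments$start[ok], fragments$strand[ok],
                                  plasmid, label_map)
  fragments$frame <- frame
  fragments
}

#' Reading-frame class distribution
#'
#' Counts and fractions over the six frame classes, plus the mean and
#' standard deviation of the six class percentages (the conventional
#' summary for a pre-selection library, where each class holds ~16.67%).
#'
#' @param frames character vector of frame labels (NAs dropped), e.g. the
#'   `frame` column of a fragment library or mapped fragment set.
#' @return an object of class `frame_distribution`.
#' @export
frame_distribution <- function(frames) {
  frames <- frames[!is.na(frames)]
  if (length(frames) == 0L) stop("empty frame distribution: no framed fragments")
  bad <- setdiff(unique(frames), frame_levels())
  if (length(bad)) stop("unknown frame labels: ", paste(bad, collapse = ", "))
  counts <- table(factor(frames, levels = frame_levels()))
  fractions <- as.numeric(counts) / length(frames)
  names(fractions) <- names(counts)
  structure(list(counts = counts, fractions = fractions,
                 n_total = length(frames),
                 mean_pct = mean(fractions * 100),
                 sd_pct = stats::sd(fractions * 100)),
            class = "frame_distribution")
}

#' @export
print.frame_distribution <- function(x, ...) {
  cat("<frame_distribution> n =", x$n_total, "\n")
  print(round(x$fractions * 100, 2))
  cat(sprintf("  mean = %.2f%% ± %.2f%%\n", x$mean_pct, x$sd_pct))
  invisible(x)
}

#' Extract the in-frame (coding) fragment set
#'
#' Retains proper pairs that are non-duplicate, in the coding frame class and
#' overlap the CDS (at least one complete codon covered). Order-stable.
#'
#' @param fragments a deduplicated, frame-decided fragments data.frame.
#' @param plasmid a [plasmid_map].
#' @param label_map a [frame_label_map].
#' @return the in-frame subset of `fragments`.
#' @export
filter_inframe <- function(fragments, plasmid, label_map = frame_label_map()) {
  b <- residue_span_bounds(fragments$start,
                           fragments$end - fragments$start, plasmid)
  keep <- fragments$status == "proper_pair" & !fragments$duplicate &
    !is.na(fragments$frame) & fragments$frame == label_map$coding_label &
    !is.na(b$first)
  fragments[keep, , drop = FALSE]
}

#' Stratified coverage track
#'
#' Per-position fragment depth over the plasmid (nt space) or per-residue
#' depth over the ORF (aa space, counting only fully covered codons). The
#' three modes mirror the standard stratification: `All` (every mapped
#' fragment, including singleton read spans in nt space), `UniquePE`
#' (deduplicated proper pairs) and `InFrame` (coding-frame UniquePE
#' fragments overlapping the CDS).
#'
#' @param fragments a deduplicated, frame-decided fragments data.frame.
#' @param plasmid a [plasmid_map].
#' @param mode `"All"`, `"UniquePE"` or `"InFrame"`.
#' @param space `"nt"` or `"aa"`.
#' @param label_map a [frame_label_map].
#' @return an object of class `coverage_track`.
#' @export
coverage_track <- function(fragments, plasmid, mode = c("All", "UniquePE", "InFrame"),
                           space = c("nt", "aa"), label_map = frame_label_map()) {
  mode <- match.arg(mode); space <- match.arg(space)
  sub <- switch(mode,
    All = fragments[fragments$status %in% c("proper_pair", "singleton"), , drop = FALSE],
    UniquePE = unique_pe(fragments),
    InFrame = filter_inframe(fragments, plasmid, label_map))
  if (space == "aa")  # residue space needs full fragments, not read stubs
    sub <- sub[sub$status == "proper_pair", , drop = FALSE]
  L <- plasmid$length
  if (space == "nt") {
    values <- numeric(L)
    if (nrow(sub)) {
      pos <- unlist(Map(seq.int, sub$start, sub$end - 1L), use.names = FALSE) %% L
      tab <- tabulate(pos + 1L, nbins = L)
      values <- as.numeric(tab)
    }
    chrom <- plasmid$name
  } else {
    n_aa <- plasmid$cds_aa_length
    values <- numeric(n_aa)
    if (nrow(sub)) {
      b <- residue_span_bounds(sub$start, sub$end - sub$start, plasmid)
      ok <- !is.na(b$first)
      if (any(ok)) {
        pos <- unlist(Map(seq.int, b$first[ok], b$last[ok]), use.names = FALSE)
        values <- as.numeric(tabulate(pos, nbins = n_aa))
      }
    }
    chrom <- paste0(plasmid$name, "_aa")
  }
  structure(list(space = space, mode = mode, values = values, chrom = chrom,
                 plasmid_name = plasmid$name, n_fragments = nrow(sub)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s/%s on %s: %d positions, max depth %g (%d fragments)\n",
              x$mode, x$space, x$chrom, length(x$values), max(x$values),
              x$n_fragments))
  invisible(x)
}

#' Write a coverage track as bedGraph
#'
#' 0-based half-open intervals, run-length merged (one line per constant
#' run, zeros included so the track round-trips bit-exactly). Residue-space
#' tracks use the pseudo-chromosome `<plasmid>_aa` with one "base" per
#' residue. Provenance (seed, config hash, mode) can be carried in `#`
#' comment lines before the track line.
#'
#' @param track a [coverage_track].
#' @param path output path.
#' @param provenance optional named character vector written as
#'   `# key=value` comment lines.
#' @return invisibly, `path`.
#' @export
write_bedgraph <- function(track, path, provenance = NULL) {
  r <- rle(track$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  hdr <- c(
    if (!is.null(provenance))
      paste0("# ", names(provenance), "=", provenance),
    paste0("# length=", length(track$values)),
    sprintf("track type=bedGraph name=\"%s_%s_%s\"",
            track$plasmid_name, track$mode, track$space))
  lines <- sprintf("%s\t%d\t%d\t%s", track$chrom, starts, ends,
                   format(r$values, trim = TRUE, scientific = FALSE))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' @param path bedGraph path written by [write_bedgraph()] (or compatible:
#'   `#` comments and a track line are skipped).
#' @return a [coverage_track]; overlapping intervals are a format error.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  len_line <- grep("^# length=", lines, value = TRUE)
  data <- lines[!startsWith(lines, "#") & !startsWith(lines, "track")]
  data <- data[nzchar(data)]
  if (length(data) == 0L) stop("bedGraph has no data lines: ", path)
  f <- strsplit(data, "\t", fixed = TRUE)
  chrom <- vapply(f, `[`, character(1L), 1L)
  if (length(unique(chrom)) != 1L) stop("multi-chromosome bedGraph not supported")
  start <- vapply(f, function(x) as.integer(x[2L]), integer(1L))
  end <- vapply(f, function(x) as.integer(x[3L]), integer(1L))
  val <- vapply(f, function(x) as.numeric(x[4L]), numeric(1L))
  o <- order(start)
  start <- start[o]; end <- end[o]; val <- val[o]
  if (any(start[-1L] < end[-length(end)]))
    stop("format error: overlapping bedGraph intervals in ", path)
  n <- if (length(len_line)) as.integer(sub("# length=", "", len_line[1L])) else max(end)
  values <- numeric(n)
  for (i in seq_along(start)) values[(start[i] + 1L):end[i]] <- val[i]
  space <- if (endsWith(chrom[1L], "_aa")) "aa" else "nt"
  structure(list(space = space, mode = "unknown", values = values,
                 chrom = chrom[1L],
                 plasmid_name = sub("_aa$", "", chrom[1L]),
                 n_fragments = NA_integer_),
            class = "coverage_track")
}
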