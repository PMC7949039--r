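#' Residue interval (1-based, inclusive)
#'
#' The reporting unit for mapped motifs: `aa_interval(58, 128)` is the
#' 71-residue stretch from residue 58 to residue 128 of the prey ORF.
#'
#' @param start_res first residue (1-based, inclusive).
#' @param end_res last residue (1-based, inclusive).
#' @return an object of class `aa_interval`.
#' @export
aa_interval <- function(start_res, end_res) {
  start_res <- as.integer(start_res); end_res <- as.integer(end_res)
  if (is.na(start_res) || is.na(end_res) || start_res < 1L || start_res > end_res)
    stop("invalid residue interval [", start_res, ", ", end_res, "]")
  structure(list(start_res = start_res, end_res = end_res), class = "aa_interval")
}

#' @export
print.aa_interval <- function(x, ...) {
  cat(sprintf("aa %d to %d (%d aa)\n", x$start_res, x$end_res, aa_width(x)))
  invisible(x)
}

#' Width of a residue interval in amino acids
#' @param interval an [aa_interval] (or `NULL`, giving 0).
#' @return integer width, `end_res - start_res + 1`.
#' @export
aa_width <- function(interval) {
  if (is.null(interval)) return(0L)
  interval$end_res - interval$start_res + 1L
}

#' Residues whose complete codon lies inside a fragment interval
#'
#' A residue counts as covered only when its full codon
#' `[cds_start + 3*(i-1), cds_start + 3*i)` is inside the fragment; partial
#' codons encode no residue. Circular-aware: any `start` representation and
#' its mod-length equivalent give identical results.
#'
#' @param start 0-based nt start of the fragment on the plasmid.
#' @param len fragment length in nt (`<=` plasmid length).
#' @param plasmid a [plasmid_map].
#' @return an [aa_interval], or `NULL` when no complete codon is covered.
#' @export
residue_span <- function(start, len, plasmid) {
  L <- plasmid$length
  stopifnot(len >= 0, len <= L)
  if (len < 3L) return(NULL)
  n_aa <- plasmid$cds_aa_length
  i <- seq_len(n_aa)
  d <- (plasmid$cds_start + 3L * (i - 1L) - as.integer(start)) %% L
  covered <- d <= (len - 3L)
  if (!any(covered)) return(NULL)
  w <- which(covered)
  if (length(w) != w[length(w)] - w[1L] + 1L)
    stop("non-contiguous residue span (fragment and CDS wrap pathologically)")
  aa_interval(w[1L], w[length(w)])
}

# Vectorised residue-span bounds for many fragments at once.
# Returns a data.frame(first, last) with NA for empty spans. Uses the signed
# circular distance from cds_start, valid for fragments shorter than half the
# plasmid (always true for sheared libraries).
residue_span_bounds <- function(start, len, plasmid) {
  L <- plasmid$length
  half <- L %/% 2L
  s_rel <- ((as.integer(start) - plasmid$cds_start + half) %% L) - half
  first <- pmax(1L, as.integer(ceiling(s_rel / 3)) + 1L)
  last <- pmin(plasmid$cds_aa_length, as.integer(floor((s_rel + len) / 3)))
  empty <- first > last
  first[empty] <- NA_integer_; last[empty] <- NA_integer_
  data.frame(first = first, last = last)
}

#' Exact intersection of the residue spans of a fragment set
#'
#' The saturation-limit oracle for the plateau caller: with noise-free
#' full-coverage selection, the called plateau converges to the intersection
#' of all selected fragments' residue spans.
#'
#' @param spans a list of [aa_interval] objects (`NULL` entries are empty
#'   spans and make the intersection empty).
#' @return an [aa_interval], or `NULL` for an empty intersection.
#' @export
oracle_intersection <- function(spans) {
  if (length(spans) == 0L) stop("no fragments given")
  if (any(vapply(spans, is.null, logical(1L)))) return(NULL)
  lo <- max(vapply(spans, function(x) x$start_res, integer(1L)))
  hi <- min(vapply(spans, function(x) x$end_res, integer(1L)))
  if (lo > hi) return(NULL)
  aa_interval(lo, hi)
}
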