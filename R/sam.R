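# Minimal SAM dialect: @HD/@SQ header, one line per read, POS 1-based,
# CIGAR <len>M for mapped reads, NM tag. Coordinate conversion between the
# internal 0-based system and SAM's 1-based POS is centralised here.

sam_pos <- function(pos0) as.integer(pos0) + 1L   # 0-based -> SAM POS
sam_pos0 <- function(pos1) as.integer(pos1) - 1L  # SAM POS -> 0-based

#' Export read alignments as SAM text
#'
#' Writes the minimal dialect produced by the internal mapper: `@HD`/`@SQ`
#' header, paired flags, 1-based POS, `<len>M` CIGAR and an `NM:i:` tag.
#' Reads aligned to the reverse strand are stored reference-forward per the
#' SAM convention.
#'
#' @param mapping a `mapping_result` from [map_read_pairs()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
export_sam <- function(mapping, path) {
  a <- mapping$alignments
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", mapping$reference, mapping$L))
  flag <- 1L +
    ifelse(a$proper, 2L, 0L) +
    ifelse(a$mapped, 0L, 4L) +
    ifelse(a$mate_mapped, 0L, 8L) +
    ifelse(a$mapped & a$strand == "-", 16L, 0L) +
    ifelse(a$mate_mapped & a$mate_strand == "-", 32L, 0L) +
    ifelse(a$read == 1L, 64L, 128L)
  seq_out <- a$seq; qual_out <- a$qual
  rev <- which(a$mapped & a$strand == "-")
  for (i in rev) {
    seq_out[i] <- revcomp(a$seq[i])
    qual_out[i] <- paste(rev(strsplit(a$qual[i], "")[[1L]]), collapse = "")
  }
  tlen <- integer(nrow(a))
  pp <- which(a$proper)
  if (length(pp)) {
    ins <- abs(((a$mate_pos[pp] + a$len[pp] - a$pos[pp]) %% mapping$L))
    # sign: plus-strand read gets +insert, minus-strand -insert
    plus <- a$strand[pp] == "+"
    span <- ifelse(plus,
                   (a$mate_pos[pp] + a$len[pp] - a$pos[pp]) %% mapping$L,
                   -((a$pos[pp] + a$len[pp] - a$mate_pos[pp]) %% mapping$L))
    tlen[pp] <- as.integer(span)
  }
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s\tNM:i:%d",
                   a$qname, flag,
                   ifelse(a$mapped, mapping$reference, "*"),
                   ifelse(a$mapped, sam_pos(a$pos), 0L),
                   ifelse(a$mapped, 60L, 0L),
                   ifelse(a$mapped, paste0(a$len, "M"), "*"),
                   ifelse(a$mate_mapped, "=", "*"),
                   ifelse(a$mate_mapped, sam_pos(a$mate_pos), 0L),
                   tlen, seq_out, qual_out,
                   ifelse(a$mapped, a$nm, 0L))
  writeLines(c(header, lines), path)
  invisible(path)
}

# reference-consumed length of a CIGAR string (M/D/N/=/X)
cigar_ref_span <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  if (length(ops) == 0L) return(NA_integer_)
  n <- as.integer(sub("[A-Z=]", "", ops))
  op <- sub("[0-9]+", "", ops)
  sum(n[op %in% c("M", "D", "N", "=", "X")])
}

#' Import a SAM file and reconstruct fragment intervals
#'
#' Accepts the package's own minimal dialect as well as externally produced
#' SAM (e.g. bwa mem): secondary (0x100) and supplementary (0x800) records
#' are skipped, CIGARs may contain clips/indels (the reference span is taken
#' from the CIGAR).
#'
#' @param path SAM file path.
#' @param plasmid a [plasmid_map]; the `@SQ` reference name must match.
#' @param params an [alignment_params] used for proper-pair insert bounds.
#' @return a `mapping_result` (without `alignments`) whose `fragments` table
#'   matches what the internal mapper would produce for the same alignments.
#' @export
import_sam <- function(path, plasmid, params = alignment_params()) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  if (length(sq) == 0L) stop("SAM header has no @SQ line")
  sn <- sub("^.*SN:([^\t]+).*$", "\\1", sq[1L])
  ln <- as.integer(sub("^.*LN:([0-9]+).*$", "\\1", sq[1L]))
  if (sn != plasmid$name || ln != plasmid$length)
    stop("SAM reference '", sn, "' (", ln, " nt) does not match plasmid '",
         plasmid$name, "' (", plasmid$length, " nt)")
  body <- lines[!startsWith(lines, "@")]
  body <- body[nzchar(body)]
  if (length(body) == 0L)
    return(structure(list(fragments = data.frame(), alignments = NULL,
                          reference = sn, L = ln, params = params),
                     class = "mapping_result"))
  f <- strsplit(body, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2L]), integer(1L))
  keep <- bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L
  f <- f[keep]; flag <- flag[keep]
  if (any(vapply(f, length, integer(1L)) < 11L))
    stop("malformed SAM line (fewer than 11 fields)")
  qname <- vapply(f, `[`, character(1L), 1L)
  rname <- vapply(f, `[`, character(1L), 3L)
  mapped <- bitwAnd(flag, 0x4L) == 0L
  if (any(mapped & rname != sn))
    stop("SAM alignment to unknown reference: ", unique(rname[mapped & rname != sn])[1L])
  pos1 <- vapply(f, function(x) as.integer(x[4L]), integer(1L))
  cigar <- vapply(f, `[`, character(1L), 6L)
  strand <- ifelse(bitwAnd(flag, 0x10L) != 0L, "-", "+")
  first <- bitwAnd(flag, 0x40L) != 0L
  refspan <- vapply(cigar, cigar_ref_span, integer(1L), USE.NAMES = FALSE)
  nm <- vapply(f, function(x) {
    t <- grep("^NM:i:", x[-(1:11)], value = TRUE)
    if (length(t)) as.integer(sub("NM:i:", "", t[1L])) else NA_integer_
  }, integer(1L))

  frags <- lapply(unique(qname), function(q) {
    idx <- which(qname == q)
    mk <- function(i) {
      if (length(i) == 0L || !mapped[i[1L]]) return(NULL)
      i <- i[1L]
      list(pos = sam_pos0(pos1[i]), strand = strand[i],
           nm = nm[i], len = refspan[i])
    }
    i1 <- idx[first[idx]]; i2 <- idx[!first[idx]]
    pair_to_fragment(q, mk(i1), mk(i2), params, ln)
  })
  fragments <- do.call(rbind, frags)
  rownames(fragments) <- NULL
  structure(list(fragments = fragments, alignments = NULL,
                 reference = sn, L = ln, params = params),
            class = "mapping_result")
}
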