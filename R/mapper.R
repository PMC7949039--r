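#' Parameters for the internal seed-and-verify mapper
#'
#' The mapper anchors reads by exact k-mer lookup against the doubled
#' circular reference and verifies candidates full-length, counting
#' mismatches; no gapped alignment (plasmid references are tiny and the
#' error model is substitution-only). Ambiguous best hits are dropped.
#'
#' @param k seed k-mer length (>= 11).
#' @param max_mismatches maximum substitutions tolerated per read.
#' @param min_insert,max_insert accepted insert (fragment) size range for a
#'   proper pair, nt.
#' @return an object of class `alignment_params`.
#' @export
alignment_params <- function(k = 15L, max_mismatches = 3L,
                             min_insert = 30L, max_insert = 1200L) {
  stopifnot(k >= 11L, max_mismatches >= 0L, min_insert <= max_insert)
  structure(list(k = as.integer(k), max_mismatches = as.integer(max_mismatches),
                 min_insert = as.integer(min_insert),
                 max_insert = as.integer(max_insert)),
            class = "alignment_params")
}

#' Build an exact k-mer index of a circular plasmid
#'
#' All k-mers of the doubled sequence starting in the first copy are indexed,
#' so k-mers spanning the origin are found; positions are reported mod
#' plasmid length.
#'
#' @param plasmid a [plasmid_map].
#' @param k k-mer length.
#' @return an object of class `kmer_index`.
#' @export
index_reference <- function(plasmid, k = 15L) {
  if (k >= plasmid$length) stop("k must be smaller than the plasmid length")
  L <- plasmid$length
  doubled <- paste0(plasmid$sequence, plasmid$sequence)
  kmers <- substring(doubled, seq_len(L), seq_len(L) + k - 1L)
  structure(list(k = as.integer(k), L = L, name = plasmid$name,
                 doubled = doubled, map = split(0:(L - 1L), kmers)),
            class = "kmer_index")
}

kmer_hits <- function(index, kmer) {
  h <- index$map[[kmer]]
  if (is.null(h)) integer(0L) else h
}

count_mismatches <- function(index, seq, pos) {
  ref <- substr(index$doubled, pos + 1L, pos + nchar(seq))
  sum(charToRaw(ref) != charToRaw(seq))
}

#' Map a single read to the circular reference
#'
#' Seed-and-verify on both strands; returns the unique best location with at
#' most `max_mismatches` substitutions, or `NULL` when the read is unmapped
#' or its best score is tied between distinct locations (ambiguous).
#'
#' @param read read sequence (string).
#' @param index a [kmer_index].
#' @param params an [alignment_params].
#' @return `NULL`, or a list with `pos` (0-based, mod length), `strand`,
#'   `nm` (mismatch count) and `len`.
#' @export
map_read <- function(read, index, params = alignment_params()) {
  read <- toupper(read)
  len <- nchar(read)
  k <- index$k
  if (len < k) return(NULL)
  offsets <- unique(c(seq(0L, len - k, by = k), len - k))
  best <- NULL; best_nm <- params$max_mismatches + 1L; ambiguous <- FALSE
  for (orient in c("+", "-")) {
    s <- if (orient == "+") read else revcomp(read)
    cand <- integer(0L)
    for (o in offsets)
      cand <- c(cand, (kmer_hits(index, substr(s, o + 1L, o + k)) - o) %% index$L)
    for (pos in unique(cand)) {
      nm <- count_mismatches(index, s, pos)
      if (nm < best_nm) {
        best_nm <- nm; best <- list(pos = pos, strand = orient, nm = nm, len = len)
        ambiguous <- FALSE
      } else if (nm == best_nm && !is.null(best) &&
                 !(pos == best$pos && orient == best$strand)) {
        ambiguous <- TRUE
      }
    }
  }
  if (is.null(best) || ambiguous || best_nm > params$max_mismatches) return(NULL)
  best
}

# Combine two read alignments into a fragment record. Returns a data.frame of
# one row (proper pair / unmapped) or one row per mapped read (singletons).
pair_to_fragment <- function(qname, m1, m2, params, L) {
  row <- function(start, end, strand, status, nm1 = NA_integer_, nm2 = NA_integer_)
    data.frame(qname = qname, start = start, end = end, strand = strand,
               status = status, nm1 = nm1, nm2 = nm2, duplicate = FALSE,
               stringsAsFactors = FALSE)
  if (is.null(m1) && is.null(m2))
    return(row(NA_integer_, NA_integer_, NA_character_, "unmapped"))
  if (is.null(m1) || is.null(m2)) {
    m <- if (is.null(m1)) m2 else m1
    return(row(m$pos, m$pos + m$len, m$strand, "singleton",
               if (is.null(m1)) NA_integer_ else m1$nm,
               if (is.null(m2)) NA_integer_ else m2$nm))
  }
  if (m1$strand != m2$strand) {
    plus <- if (m1$strand == "+") m1 else m2
    minus <- if (m1$strand == "-") m1 else m2
    insert <- (minus$pos + minus$len - plus$pos) %% L
    if (insert == 0L) insert <- L
    if (insert >= params$min_insert && insert <= params$max_insert &&
        insert >= plus$len && insert >= minus$len) {
      frag_strand <- if (m1$strand == "+") "+" else "-"
      return(row(plus$pos, plus$pos + insert, frag_strand, "proper_pair",
                 m1$nm, m2$nm))
    }
  }
  # same strand or implausible insert: two singletons
  rbind(row(m1$pos, m1$pos + m1$len, m1$strand, "singleton", nm1 = m1$nm),
        row(m2$pos, m2$pos + m2$len, m2$strand, "singleton", nm2 = m2$nm))
}

#' Map read pairs and reconstruct fragment intervals
#'
#' @param pairs a `read_pairs` data.frame.
#' @param index a [kmer_index].
#' @param params an [alignment_params].
#' @return a list of class `mapping_result`: `fragments` (one row per
#'   reconstructed fragment/singleton with 0-based half-open circular-aware
#'   coordinates) and `alignments` (one row per read, for SAM export).
#' @export
map_read_pairs <- function(pairs, index, params = alignment_params()) {
  frags <- vector("list", nrow(pairs))
  alns <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    m1 <- map_read(pairs$r1_seq[i], index, params)
    m2 <- map_read(pairs$r2_seq[i], index, params)
    frags[[i]] <- pair_to_fragment(pairs$id[i], m1, m2, params, index$L)
    proper <- frags[[i]]$status[1L] == "proper_pair"
    alns[[i]] <- rbind(
      alignment_row(pairs$id[i], 1L, m1, m2, proper,
                    pairs$r1_seq[i], pairs$r1_qual[i]),
      alignment_row(pairs$id[i], 2L, m2, m1, proper,
                    pairs$r2_seq[i], pairs$r2_qual[i]))
  }
  fragments <- do.call(rbind, frags)
  rownames(fragments) <- NULL
  structure(list(fragments = fragments,
                 alignments = do.call(rbind, alns),
                 reference = index$name, L = index$L, params = params),
            class = "mapping_result")
}

alignment_row <- function(qname, read_index, m, mate, proper, seq, qual) {
  data.frame(qname = qname, read = read_index,
             mapped = !is.null(m),
             pos = if (is.null(m)) NA_integer_ else m$pos,
             strand = if (is.null(m)) NA_character_ else m$strand,
             len = nchar(seq),
             nm = if (is.null(m)) NA_integer_ else m$nm,
             mate_mapped = !is.null(mate),
             mate_pos = if (is.null(mate)) NA_integer_ else mate$pos,
             mate_strand = if (is.null(mate)) NA_character_ else mate$strand,
             proper = proper, seq = seq, qual = qual,
             stringsAsFactors = FALSE)
}

#' Flag duplicate fragments (UniquePE set)
#'
#' Duplicate PE fragments are those with the same start and end location (and
#' strand); exactly one representative keeps `duplicate = FALSE`. Singletons
#' are never part of the UniquePE set.
#'
#' @param fragments the `fragments` data.frame of a [map_read_pairs()] result.
#' @return the data.frame with the `duplicate` column filled.
#' @export
dedup_fragments <- function(fragments) {
  proper <- which(fragments$status == "proper_pair")
  key <- paste(fragments$start, fragments$end, fragments$strand)
  fragments$duplicate <- FALSE
  fragments$duplicate[proper] <- duplicated(key[proper])
  fragments
}

#' Subset helper: the UniquePE fragment set
#' @param fragments a deduplicated fragments data.frame.
#' @return rows that are proper pairs and not duplicates.
#' @export
unique_pe <- function(fragments) {
  fragments[fragments$status == "proper_pair" & !fragments$duplicate, , drop = FALSE]
}
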