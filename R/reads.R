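#' Substitution-only sequencing error model
#'
#' @param substitution_rate per-base substitution probability (at most 0.1).
#' @param seed RNG seed for this stage.
#' @return an object of class `error_model`.
#' @export
error_model <- function(substitution_rate = 0, seed = 1L) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 0.1)
  structure(list(substitution_rate = substitution_rate, seed = as.integer(seed)),
            class = "error_model")
}

#' Simulate paired-end reads from selected fragments
#'
#' Each fragment yields one read pair drawn from opposite ends of the cloned
#' strand: read 1 is the first `read_len` bases, read 2 the reverse
#' complement of the last `read_len` bases. Fragments shorter than `read_len`
#' give fully overlapping truncated reads. The simulation truth is carried in
#' the read name as `frag<id>:<start>:<end>:<strand>`. Base qualities are
#' constant Q37.
#'
#' @param fragments data.frame of (selected) fragments with `id`, `start`,
#'   `length`, `strand`.
#' @param plasmid a [plasmid_map].
#' @param read_len read length, nt (>= 20).
#' @param errors an [error_model].
#' @return a data.frame of class `read_pairs`: `id`, `r1_seq`, `r2_seq`,
#'   `r1_qual`, `r2_qual`.
#' @export
simulate_read_pairs <- function(fragments, plasmid, read_len = 150,
                                errors = error_model()) {
  if (read_len < 20) stop("read_len must be >= 20")
  n <- nrow(fragments)
  ids <- sprintf("frag%d:%d:%d:%s", fragments$id, fragments$start,
                 fragments$start + fragments$length, fragments$strand)
  if (n == 0L)
    return(structure(data.frame(id = character(), r1_seq = character(),
                                r2_seq = character(), r1_qual = character(),
                                r2_qual = character()), class = c("read_pairs", "data.frame")))
  template <- vapply(seq_len(n), function(i)
    plasmid_subseq(plasmid, fragments$start[i], fragments$length[i]), character(1L))
  minus <- fragments$strand == "-"
  if (any(minus))
    template[minus] <- vapply(template[minus], revcomp, character(1L), USE.NAMES = FALSE)
  rl <- pmin(read_len, fragments$length)
  r1 <- substr(template, 1L, rl)
  r2 <- vapply(seq_len(n), function(i)
    revcomp(substr(template[i], fragments$length[i] - rl[i] + 1L,
                   fragments$length[i])), character(1L))
  if (errors$substitution_rate > 0) {
    set.seed(errors$seed)
    r1 <- add_substitutions(r1, errors$substitution_rate)
    r2 <- add_substitutions(r2, errors$substitution_rate)
  }
  qual <- strrep("F", rl)  # Phred+33 Q37
  structure(data.frame(id = ids, r1_seq = r1, r2_seq = r2,
                       r1_qual = qual, r2_qual = qual, stringsAsFactors = FALSE),
            class = c("read_pairs", "data.frame"))
}

add_substitutions <- function(seqs, rate) {
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    n <- nchar(s)
    k <- stats::rbinom(1L, n, rate)
    if (k == 0L) return(s)
    pos <- sample.int(n, k)
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    # substitute with a uniformly chosen different base
    ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(bases, b), 1L), character(1L))
    paste0(ch, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Write paired FASTQ files
#'
#' Four-line records, Phred+33 qualities; paths ending in `.gz` are written
#' compressed.
#'
#' @param pairs a `read_pairs` data.frame from [simulate_read_pairs()].
#' @param r1_path,r2_path output paths for the two mates.
#' @return invisibly, `c(r1_path, r2_path)`.
#' @export
write_fastq <- function(pairs, r1_path, r2_path) {
  write_one <- function(seqs, quals, ids, path) {
    x <- Biostrings::BStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals),
                                compress = endsWith(path, ".gz"))
  }
  write_one(pairs$r1_seq, pairs$r1_qual, pairs$id, r1_path)
  write_one(pairs$r2_seq, pairs$r2_qual, pairs$id, r2_path)
  invisible(c(r1_path, r2_path))
}

#' Read paired FASTQ files
#'
#' @param r1_path,r2_path paths to the two mate files (optionally gzipped).
#' @return a `read_pairs` data.frame; errors if record counts or ids disagree
#'   between the two files.
#' @export
read_fastq <- function(r1_path, r2_path) {
  # Biostrings warns that read-name metadata columns are dropped when the
  # qualities are attached; the names are all we carry, so this is benign
  r1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r1_path))
  r2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r2_path))
  if (length(r1) != length(r2))
    stop("pairing error: R1 has ", length(r1), " records, R2 has ", length(r2))
  id1 <- sub("/[12]$", "", sub("\\s.*$", "", names(r1)))
  id2 <- sub("/[12]$", "", sub("\\s.*$", "", names(r2)))
  if (!identical(id1, id2)) stop("pairing error: R1/R2 read ids differ")
  structure(data.frame(id = id1,
                       r1_seq = as.character(r1), r2_seq = as.character(r2),
                       r1_qual = as.character(Biostrings::quality(r1)),
                       r2_qual = as.character(Biostrings::quality(r2)),
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("read_pairs", "data.frame"))
}
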