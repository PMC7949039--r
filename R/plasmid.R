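#' Circular prey-plasmid reference
#'
#' A `plasmid_map` is the coordinate frame for the whole pipeline: a circular
#' DNA sequence carrying the prey ORF fused (N-terminally) to the activation
#' or DNA-binding domain of the two-hybrid vector. All nucleotide coordinates
#' are 0-based half-open and normalised to `[0, length)`; user-facing residue
#' coordinates are 1-based inclusive.
#'
#' @param name single identifier for the plasmid (used as the SAM/bedGraph
#'   reference name).
#' @param sequence circular DNA sequence, a single string over `A,C,G,T`
#'   (lowercase accepted, normalised to uppercase).
#' @param cds_start 0-based offset of the first base of the prey ORF's start
#'   codon.
#' @param cds_strand strand of the prey ORF, `"+"` or `"-"`. Only `"+"` is
#'   exercised by the simulator; the field is carried for annotation.
#' @param cds_aa_length number of residues of the prey ORF (excluding the
#'   stop codon).
#' @param features optional data.frame of backbone annotations with columns
#'   `label`, `start`, `end` (0-based half-open nt intervals).
#' @return an object of class `plasmid_map`.
#' @examples
#' seq <- paste0(strrep("AC", 50), "ATG", strrep("GCT", 10), "TAA", strrep("GT", 50))
#' p <- plasmid_map("toy", seq, cds_start = 100, cds_aa_length = 11)
#' p
#' @export
plasmid_map <- function(name, sequence, cds_start, cds_strand = "+",
                        cds_aa_length, features = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || !nzchar(sequence))
    stop("plasmid sequence must be a single non-empty string")
  if (grepl("[^ACGT]", sequence))
    stop("plasmid sequence contains characters outside {A,C,G,T}")
  len <- nchar(sequence)
  cds_start <- as.integer(cds_start) %% len
  if (!cds_strand %in% c("+", "-")) stop("cds_strand must be '+' or '-'")
  cds_aa_length <- as.integer(cds_aa_length)
  if (cds_aa_length < 1L) stop("cds_aa_length must be >= 1")
  if (3L * (cds_aa_length + 1L) > len)
    stop("CDS (including stop codon) longer than plasmid")
  obj <- structure(
    list(name = name, sequence = sequence, length = len,
         cds_start = cds_start, cds_strand = cds_strand,
         cds_aa_length = cds_aa_length,
         features = normalize_features(features, len)),
    class = "plasmid_map")
  start_codon <- plasmid_subseq(obj, cds_start, 3L)
  if (cds_strand == "-") start_codon <- revcomp(start_codon)
  if (start_codon != "ATG")
    stop("codon at cds_start on cds_strand is '", start_codon, "', expected ATG")
  obj
}

normalize_features <- function(features, len) {
  if (is.null(features) || NROW(features) == 0L)
    return(data.frame(label = character(), start = integer(), end = integer()))
  stopifnot(all(c("label", "start", "end") %in% names(features)))
  data.frame(label = as.character(features$label),
             start = as.integer(features$start) %% len,
             end = as.integer(features$end),
             stringsAsFactors = FALSE)
}

#' @export
print.plasmid_map <- function(x, ...) {
  cat(sprintf("<plasmid_map> %s: %d nt circular, ORF %d aa at nt %d (%s)\n",
              x$name, x$length, x$cds_aa_length, x$cds_start, x$cds_strand))
  if (nrow(x$features))
    cat("  features:", paste0(x$features$label, collapse = ", "), "\n")
  invisible(x)
}

#' Extract a (possibly origin-spanning) subsequence of a circular plasmid
#'
#' Operates on the doubled sequence so intervals crossing the origin need no
#' special casing. `start` is normalised mod plasmid length.
#'
#' @param plasmid a [plasmid_map].
#' @param start 0-based start offset.
#' @param len number of bases to extract (must be `<=` plasmid length).
#' @return a character string of length `len`.
#' @export
plasmid_subseq <- function(plasmid, start, len) {
  stopifnot(len <= plasmid$length)
  start <- as.integer(start) %% plasmid$length
  doubled <- paste0(plasmid$sequence, plasmid$sequence)
  substr(doubled, start + 1L, start + len)
}

#' Reverse complement of a DNA string
#' @param dna a DNA string over `A,C,G,T`.
#' @return the reverse complement string.
#' @export
revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

#' Read a plasmid reference from FASTA plus a structured sidecar config
#'
#' The FASTA carries only the sequence; the ORF annotation lives in a YAML
#' sidecar with keys `cds_start`, `cds_strand`, `cds_aa_length` and optionally
#' `features` (list of `label`/`start`/`end`). GenBank parsing is deliberately
#' out of scope.
#'
#' @param fasta_path path to a FASTA file. With `strict = TRUE` a multi-record
#'   file is an error; otherwise the first record is used with a warning.
#' @param config_path path to the YAML sidecar. If `NULL`, the default is the
#'   FASTA path with a `.yaml` extension.
#' @param strict error (rather than warn) on multi-record FASTA.
#' @return a [plasmid_map].
#' @export
read_plasmid <- function(fasta_path, config_path = NULL, strict = FALSE) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  recs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(recs) == 0L) stop("FASTA file has no records: ", fasta_path)
  nm <- sub("\\s.*$", "", names(recs))
  if (anyDuplicated(nm)) stop("duplicate record names in FASTA: ", fasta_path)
  if (length(recs) > 1L) {
    if (strict) stop("multi-record FASTA not allowed in strict mode")
    warning("multi-record FASTA; using first record '", nm[1L], "'")
  }
  if (is.null(config_path))
    config_path <- paste0(sub("\\.(fa|fasta|fna)$", "", fasta_path), ".yaml")
  if (!file.exists(config_path)) stop("plasmid config not found: ", config_path)
  cfg <- yaml::read_yaml(config_path)
  feats <- NULL
  if (!is.null(cfg$features) && length(cfg$features))
    feats <- do.call(rbind, lapply(cfg$features, function(f)
      data.frame(label = f$label, start = f$start, end = f$end)))
  plasmid_map(name = nm[1L], sequence = as.character(recs[[1L]]),
              cds_start = cfg$cds_start,
              cds_strand = if (is.null(cfg$cds_strand)) "+" else cfg$cds_strand,
              cds_aa_length = cfg$cds_aa_length, features = feats)
}

#' Write a plasmid reference as FASTA plus YAML sidecar
#'
#' Round-trips with [read_plasmid()].
#'
#' @param plasmid a [plasmid_map].
#' @param fasta_path output FASTA path.
#' @param config_path output YAML path; defaults to the FASTA path with a
#'   `.yaml` extension.
#' @return invisibly, the FASTA path.
#' @export
write_plasmid <- function(plasmid, fasta_path, config_path = NULL) {
  if (is.null(config_path))
    config_path <- paste0(sub("\\.(fa|fasta|fna)$", "", fasta_path), ".yaml")
  seqs <- Biostrings::DNAStringSet(plasmid$sequence)
  names(seqs) <- plasmid$name
  Biostrings::writeXStringSet(seqs, fasta_path)
  feats <- NULL
  if (nrow(plasmid$features))
    feats <- lapply(seq_len(nrow(plasmid$features)), function(i)
      list(label = plasmid$features$label[i],
           start = plasmid$features$start[i],
           end = plasmid$features$end[i]))
  yaml::write_yaml(list(cds_start = plasmid$cds_start,
                        cds_strand = plasmid$cds_strand,
                        cds_aa_length = plasmid$cds_aa_length,
                        features = feats),
                   config_path)
  invisible(fasta_path)
}
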