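# Shared toy fixtures, all generated in code.

# small circular plasmid with a random stop-free ORF
toy_plasmid <- function(orf_aa = 100L, total_len = 900L, cds_start = 300L,
                        seed = 42L, name = "toy", ...) {
  synthetic_plasmid(name, orf_aa = orf_aa, total_len = total_len,
                    cds_start = cds_start, seed = seed, ...)
}

# mapped-fragments-style data.frame from nt intervals (0-based half-open)
frag_df <- function(start, end, strand = "+", status = "proper_pair",
                    qname = NULL) {
  n <- length(start)
  data.frame(qname = qname %||% sprintf("f%d", seq_len(n)),
             start = as.integer(start), end = as.integer(end),
             strand = rep_len(strand, n), status = rep_len(status, n),
             nm1 = 0L, nm2 = 0L, duplicate = FALSE,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# library-style fragment data.frame (simulator schema)
lib_df <- function(start, length, strand = "+", plasmid = NULL) {
  n <- length(start)
  df <- data.frame(id = seq_len(n), start = as.integer(start),
                   length = as.integer(length),
                   strand = rep_len(strand, n),
                   frame = NA_character_, selected = FALSE, cause = "none",
                   stringsAsFactors = FALSE)
  if (!is.null(plasmid))
    df$frame <- assign_frame_label(df$start, df$strand, plasmid)
  df
}

# brute-force residue span: per-residue containment test on the circle
brute_residue_span <- function(start, len, plasmid) {
  L <- plasmid$length
  frag <- (start + seq_len(len) - 1L) %% L
  covered <- vapply(seq_len(plasmid$cds_aa_length), function(i) {
    codon <- (plasmid$cds_start + 3L * (i - 1L) + 0:2) %% L
    all(codon %in% frag)
  }, logical(1L))
  if (!any(covered)) return(NULL)
  w <- which(covered)
  aa_interval(min(w), max(w))
}

# in-frame nt start of the codon of residue r (for constructing fragments)
codon_nt <- function(plasmid, r) plasmid$cds_start + 3L * (r - 1L)
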