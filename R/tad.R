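#' Nine-residue transactivation-domain (9aaTAD) pattern
#'
#' Peptides combining acidic, hydrophobic and aromatic residues can activate
#' transcription when fused to a DNA-binding domain, producing
#' bait-independent (false positive) colonies in two-hybrid screens. The
#' scanner uses a configurable position-class pattern over nine residues;
#' the shipped default approximates the character of published 9aaTAD
#' predictors — it is calibrated to accept classic acidic/hydrophobic
#' activator nonamers (e.g. `EVYQVTVYQ`) and to reject basic or
#' featureless runs — but does not replicate any external tool exactly.
#'
#' @param position_classes list of exactly 9 non-empty character vectors of
#'   allowed residues (use [default_tad_pattern()] for the shipped default).
#' @param name pattern name carried into hit reports.
#' @param description free-text description.
#' @return an object of class `tad_pattern`.
#' @export
tad_pattern <- function(position_classes, name = "custom", description = "") {
  stopifnot(length(position_classes) == 9L)
  position_classes <- lapply(position_classes, function(x) {
    x <- toupper(as.character(x))
    if (length(x) == 0L) stop("empty position class")
    bad <- setdiff(x, AA20)
    if (length(bad)) stop("non-standard residues in pattern: ", paste(bad, collapse = ","))
    x
  })
  structure(list(name = name, position_classes = position_classes,
                 description = description), class = "tad_pattern")
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname tad_pattern
#' @export
default_tad_pattern <- function() {
  hydrophobic <- c("A", "I", "L", "M", "V", "F", "W", "Y")
  aromatic_hp <- c("F", "W", "Y", "I", "L", "V", "M")
  polar_acid <- c("D", "E", "N", "Q", "S", "T")
  tad_pattern(list(c("D", "E", "N", "Q"),       # acidic/amide anchor
                   hydrophobic,
                   aromatic_hp,
                   polar_acid,
                   hydrophobic,
                   c(polar_acid, "A", "G"),
                   hydrophobic,
                   aromatic_hp,
                   polar_acid),
              name = "acidic_hydrophobic_9mer",
              description = paste("Acidic/amide anchor alternating with",
                                  "hydrophobic-aromatic positions; approximates",
                                  "9aaTAD-style transactivation character."))
}

#' Scan a peptide for transactivation-domain windows
#'
#' Every 9-residue window is tested against the pattern; hits are reported
#' with their 1-based start residue. Peptides shorter than 9 residues give
#' no hits; the number of windows tested is `max(0, nchar(peptide) - 8)`.
#'
#' @param peptide amino-acid string over the 20 standard residues (`*`
#'   allowed as a stop; windows containing it never match).
#' @param pattern a [tad_pattern].
#' @return data.frame of hits: `start_res`, `peptide`, `pattern_name`.
#' @export
scan_peptide <- function(peptide, pattern = default_tad_pattern()) {
  stopifnot(inherits(pattern, "tad_pattern"))
  peptide <- toupper(peptide)
  if (grepl("[^A-Z*]", peptide) ||
      any(!strsplit(gsub("\\*", "", peptide), "")[[1L]] %in% AA20))
    stop("peptide contains non-standard residue letters")
  n <- nchar(peptide)
  empty <- data.frame(start_res = integer(), peptide = character(),
                      pattern_name = character())
  if (n < 9L) return(empty)
  ch <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  ok <- matrix(FALSE, nrow = n - 8L, ncol = 9L)
  for (j in 1:9)
    ok[, j] <- ch[seq_len(n - 8L) + (j - 1L)] %in% pattern$position_classes[[j]]
  hit <- which(rowSums(ok) == 9L)
  if (length(hit) == 0L) return(empty)
  data.frame(start_res = hit,
             peptide = substring(peptide, hit, hit + 8L),
             pattern_name = pattern$name)
}

#' Scan all six reading frames of a plasmid for TAD windows
#'
#' Translates the circular plasmid in all three offsets on both strands and
#' scans each translation. Hits carry their frame, the nt interval they
#' back-project to (so they can be cross-referenced with coverage peaks),
#' and any overlapping vector feature.
#'
#' @param plasmid a [plasmid_map].
#' @param pattern a [tad_pattern].
#' @return data.frame of hits: `frame_label`, `start_res` (1-based within
#'   that frame's translation), `peptide`, `nt_start`, `nt_end` (0-based
#'   half-open, sense-strand coordinates), `feature`, `pattern_name`.
#' @export
scan_plasmid_frames <- function(plasmid, pattern = default_tad_pattern()) {
  L <- plasmid$length
  # wrap two extra bases so the last codons of each offset are complete
  fwd <- paste0(plasmid$sequence, substr(plasmid$sequence, 1L, 2L))
  rev <- paste0(revcomp(plasmid$sequence),
                substr(revcomp(plasmid$sequence), 1L, 2L))
  out <- list()
  lm <- frame_label_map()
  for (offset in 0:2) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else rev
      pep <- translate_dna(substr(s, offset + 1L, offset + 3L * (L %/% 3L)), 0L)
      hits <- scan_peptide(pep, pattern)
      if (nrow(hits) == 0L) next
      # back-project: residue r in this frame starts at nt offset+3*(r-1)
      a <- offset + 3L * (hits$start_res - 1L)
      b <- a + 27L
      if (strand == "-") { tmp <- a; a <- L - b; b <- L - tmp }
      lab <- if (strand == "+") lm$plus[(offset - plasmid$cds_start) %% 3L + 1L]
             else lm$minus[(offset - plasmid$cds_start) %% 3L + 1L]
      hits$frame_label <- lab
      hits$strand <- strand
      hits$nt_start <- a %% L
      hits$nt_end <- ((b - 1L) %% L) + 1L
      out[[length(out) + 1L]] <- hits
    }
  }
  if (length(out) == 0L)
    return(data.frame(start_res = integer(), peptide = character(),
                      pattern_name = character(), frame_label = character(),
                      strand = character(), nt_start = integer(),
                      nt_end = integer(), feature = character()))
  res <- do.call(rbind, out)
  res$feature <- vapply(seq_len(nrow(res)), function(i) {
    f <- plasmid$features
    ov <- which(f$start < res$nt_end[i] & f$end > res$nt_start[i])
    if (length(ov)) paste(f$label[ov], collapse = ",") else ""
  }, character(1L))
  rownames(res) <- NULL
  res
}

#' Annotate domain calls with overlapping TAD hits
#'
#' Any call (primary or secondary) whose residue interval overlaps a TAD hit
#' on the prey ORF is flagged `possible_self_activation`. The flag is
#' advisory: binding and self-activation cannot be distinguished from
#' coverage alone, so hits never suppress a call. Abutting (non-overlapping)
#' hits do not flag.
#'
#' @param call a [domain_call].
#' @param hits data.frame of ORF-frame hits from [scan_peptide()] on the
#'   prey ORF translation (columns `start_res`, `peptide`).
#' @return the call with flags filled in.
#' @export
annotate_calls_with_tads <- function(call, hits) {
  overlaps <- function(lo, hi)
    any(hits$start_res <= hi & (hits$start_res + 8L) >= lo)
  if (nrow(hits)) {
    call$possible_self_activation <-
      overlaps(call$interval$start_res, call$interval$end_res)
    if (nrow(call$secondary))
      call$secondary$possible_self_activation <-
        vapply(seq_len(nrow(call$secondary)), function(i)
          overlaps(call$secondary$start_res[i], call$secondary$end_res[i]),
          logical(1L))
  }
  call
}

#' Write / read a TAD pattern definition file
#'
#' One line per position: allowed residues as a string, e.g. `DENQ`.
#' @param pattern a [tad_pattern].
#' @param path file path.
#' @return invisibly `path` / the read [tad_pattern].
#' @export
write_tad_pattern <- function(pattern, path) {
  writeLines(c(paste0("# ", pattern$name),
               vapply(pattern$position_classes, paste0, character(1L),
                      collapse = "")), path)
  invisible(path)
}

#' @rdname write_tad_pattern
#' @export
read_tad_pattern <- function(path) {
  lines <- readLines(path)
  name <- sub("^# ", "", lines[startsWith(lines, "#")][1L])
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) != 9L) stop("pattern file must have 9 position lines")
  tad_pattern(strsplit(body, "", fixed = TRUE),
              name = if (is.na(name)) "custom" else name)
}
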