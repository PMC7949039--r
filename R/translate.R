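#' Translate a DNA string in a given frame offset
#'
#' Standard genetic code (yeast nuclear expression); stop codons are rendered
#' `*` and an incomplete trailing codon is dropped, so the peptide length is
#' always `floor((nchar(dna) - offset) / 3)`.
#'
#' @param dna DNA string over `A,C,G,T` (lowercase accepted).
#' @param offset frame offset, 0, 1 or 2.
#' @return the peptide as a single string (possibly empty).
#' @examples
#' translate_dna("ATGGCT")        # "MA"
#' translate_dna("TAA")           # "*"
#' @export
translate_dna <- function(dna, offset = 0L) {
  stopifnot(length(dna) == 1L, offset %in% 0:2)
  dna <- toupper(dna)
  if (!nzchar(dna)) stop("empty DNA string")
  if (grepl("[^ACGT]", dna)) stop("DNA contains characters outside {A,C,G,T}")
  n_codons <- (nchar(dna) - offset) %/% 3L
  if (n_codons <= 0L) return("")
  starts <- offset + 3L * (seq_len(n_codons) - 1L) + 1L
  codons <- substring(dna, starts, starts + 2L)
  paste0(Biostrings::GENETIC_CODE[codons], collapse = "")
}

#' TruSeq 5' adaptor used as the translated fusion linker
#'
#' The read-1 primer-binding sequence of the TruSeq adaptor, in the frame in
#' which it reads through into the cloned insert. Translated in frame 0 it
#' yields the linker peptide `HSFPTRRSSD` plus a final leucine formed from the
#' adaptor's terminal `CT` and the first base of the insert.
#' @export
TRUSEQ_ADAPTOR_5P <- "CACTCTTTCCCTACACGACGCTCTTCCGATCT"

#' Fusion construct specification
#'
#' Describes the N-terminal fusion geometry: the activation (or DNA-binding)
#' domain and adaptor precede the insert, and the adaptor frame is chosen so
#' that its terminal `CT` overhang pairs with the first base of the insert to
#' always encode leucine, avoiding junction-dependent stop codons.
#'
#' @param adaptor_5p DNA of the translated linker region (default: TruSeq
#'   read-1 primer site).
#' @param adaptor_frame_offset frame in which the adaptor is read, 0/1/2.
#' @param linker_peptide expected amino-acid sequence of the translated
#'   adaptor including the junction leucine.
#' @return an object of class `fusion_construct_spec`.
#' @export
fusion_construct_spec <- function(adaptor_5p = TRUSEQ_ADAPTOR_5P,
                                  adaptor_frame_offset = 0L,
                                  linker_peptide = "HSFPTRRSSDL") {
  adaptor_5p <- toupper(adaptor_5p)
  stopifnot(adaptor_frame_offset %in% 0:2)
  spec <- structure(list(fusion_side = "N-terminal",
                         adaptor_5p = adaptor_5p,
                         adaptor_frame_offset = as.integer(adaptor_frame_offset),
                         linker_peptide = linker_peptide),
                    class = "fusion_construct_spec")
  # the final residue must be insert-independent: a CT overhang (CTN = Leu)
  tail_len <- (nchar(adaptor_5p) - adaptor_frame_offset) %% 3L
  if (endsWith(linker_peptide, "L") &&
      !(tail_len == 2L && substr(adaptor_5p, nchar(adaptor_5p) - 1L,
                                 nchar(adaptor_5p)) == "CT"))
    stop("construct-spec error: linker ends in L but adaptor does not end in a CT overhang")
  spec
}

#' Translated linker peptide at the adaptor/insert junction
#'
#' Appends the first base of the insert to the adaptor and translates in the
#' construct frame. By design of the CT overhang the result is independent of
#' that base (CTA/CTC/CTG/CTT all encode leucine).
#'
#' @param spec a [fusion_construct_spec].
#' @param first_insert_base first base of the cloned insert (`A`,`C`,`G`,`T`).
#' @return the linker peptide string.
#' @examples
#' linker_peptide(fusion_construct_spec(), "A")  # "HSFPTRRSSDL"
#' @export
linker_peptide <- function(spec, first_insert_base = "A") {
  stopifnot(inherits(spec, "fusion_construct_spec"),
            first_insert_base %in% c("A", "C", "G", "T"))
  pep <- translate_dna(paste0(spec$adaptor_5p, first_insert_base),
                       spec$adaptor_frame_offset)
  if (pep != spec$linker_peptide)
    stop("translated linker '", pep, "' does not match declared linker_peptide '",
         spec$linker_peptide, "'")
  pep
}
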