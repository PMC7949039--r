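# Packaged synthetic scenarios: each reproduces one of the canonical mapping
# experiments (bait/prey pair) as simulation truth, using a random stop-free
# ORF embedded in a ~9-kb synthetic vector. Real interactor nucleotide
# sequences are deliberately not bundled; the reported motif coordinates are
# carried as ground truth on synthetic sequence.

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE)[
  Biostrings::GENETIC_CODE != "*"], character(0L))

# codons (one per residue) for a given peptide, first codon per residue in
# the standard table -- used to seed an exact peptide into a synthetic ORF
codons_for_peptide <- function(peptide) {
  ch <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  vapply(ch, function(a) names(Biostrings::GENETIC_CODE)[
    Biostrings::GENETIC_CODE == a][1L], character(1L))
}

#' Build a synthetic prey plasmid with a random stop-free ORF
#'
#' @param name plasmid name.
#' @param orf_aa ORF length in residues (including the initiator Met).
#' @param total_len total circular plasmid length, nt (~8-10 kb typical).
#' @param cds_start 0-based offset of the ORF start codon.
#' @param seed RNG seed.
#' @param embed_peptide optional peptide to encode verbatim within the ORF.
#' @param embed_at 1-based residue position of the embedded peptide.
#' @return a [plasmid_map] with an `AD_fusion_cassette` feature upstream of
#'   the ORF and the remainder annotated as backbone.
#' @export
synthetic_plasmid <- function(name, orf_aa, total_len = 9000L, cds_start = 3000L,
                              seed = 1L, embed_peptide = NULL, embed_at = NULL) {
  stopifnot(3L * orf_aa + 3L + cds_start < total_len)
  set.seed(as.integer(seed))
  codons <- c("ATG", sample(SENSE_CODONS, orf_aa - 1L, replace = TRUE))
  if (!is.null(embed_peptide)) {
    emb <- codons_for_peptide(embed_peptide)
    stopifnot(embed_at >= 2L, embed_at + length(emb) - 1L <= orf_aa)
    codons[embed_at:(embed_at + length(emb) - 1L)] <- emb
  }
  orf <- paste0(paste0(codons, collapse = ""), "TAA")
  n_back <- total_len - nchar(orf)
  backbone <- paste0(sample(c("A", "C", "G", "T"), n_back, replace = TRUE),
                     collapse = "")
  sequence <- paste0(substr(backbone, 1L, cds_start), orf,
                     substr(backbone, cds_start + 1L, n_back))
  plasmid_map(name, sequence, cds_start = cds_start, cds_strand = "+",
              cds_aa_length = orf_aa,
              features = data.frame(
                label = c("AD_fusion_cassette", "prey_orf", "backbone"),
                start = c(cds_start - 150L, cds_start, cds_start + nchar(orf)),
                end = c(cds_start, cds_start + nchar(orf), total_len)))
}

scenario_names <- function() c("craf_kras", "craf_mek1", "rgl3_rit1",
                               "mdm2_p53", "unselected_control")

#' Build a packaged mapping scenario
#'
#' Returns a ready-to-run configuration (plus its synthetic reference) for
#' one of the canonical fragment-screen experiments. Truth intervals are the
#' respective published motif coordinates; sequences are synthetic. Library
#' sizes default to 10^6 clones for the selection scenarios (the saturating
#' transformant scale of a real screen; required for sharp plateau edges)
#' and 5x10^4 for the pre-selection control, where no saturation is needed.
#'
#' * `craf_kras`: 700-aa prey, binding motif aa 58-128, 350-bp shear.
#' * `craf_mek1`: 700-aa prey, motif aa 310-375 with a negative element at
#'   aa 376-385 that abolishes binding when included (sharp 3' edge);
#'   200-bp shear so fragment capacity matches the motif width.
#' * `rgl3_rit1`: 750-aa prey, motif aa 614-695, 350-bp shear.
#' * `mdm2_p53`: 491-aa prey, motif aa 28-107, plus a transactivating
#'   nonamer `EVYQVTVYQ` encoded at aa 274-282 that self-activates a
#'   fraction (0.16) of the fragments carrying it in frame (acidic-region
#'   false positive peak below the specific plateau).
#' * `unselected_control`: the craf_kras construct with selection off
#'   (pre-selection library; uniform frame classes).
#'
#' @param name scenario name (see above).
#' @param seed master seed; stage seeds are derived deterministically.
#' @param n_fragments optional override of the scenario library size.
#' @param outdir optional directory to write the reference FASTA + YAML
#'   config into.
#' @return a list of class `scenario`: `name`, `plasmid`, `config` (a
#'   [run_config]) and `truth` (list with `true_interval` and, where set,
#'   `forbidden_interval` / `tad_interval`).
#' @export
make_scenario <- function(name, seed = 1L, n_fragments = NULL, outdir = NULL) {
  if (!name %in% scenario_names()) stop("unknown scenario: ", name)
  seed <- as.integer(seed)
  p <- switch(name,
    craf_kras = , unselected_control =
      list(orf_aa = 700L, true = c(58L, 128L), forb = NULL, tad = NULL,
           shear = c(350, 35), n = 1e6),
    craf_mek1 =
      list(orf_aa = 700L, true = c(310L, 375L), forb = c(376L, 385L), tad = NULL,
           shear = c(200, 20), n = 1e6),
    rgl3_rit1 =
      list(orf_aa = 750L, true = c(614L, 695L), forb = NULL, tad = NULL,
           shear = c(350, 35), n = 1e6),
    mdm2_p53 =
      list(orf_aa = 491L, true = c(28L, 107L), forb = NULL, tad = c(274L, 282L),
           shear = c(350, 35), n = 1e6))
  if (name == "unselected_control") p$n <- 5e4
  if (!is.null(n_fragments)) p$n <- n_fragments

  plasmid <- synthetic_plasmid(
    name = name, orf_aa = p$orf_aa, seed = stage_seed(seed, 0L),
    embed_peptide = if (!is.null(p$tad)) "EVYQVTVYQ" else NULL,
    embed_at = if (!is.null(p$tad)) p$tad[1L] else NULL)

  binding <- NULL
  if (name != "unselected_control")
    binding <- list(true_interval = p$true,
                    coverage_stringency = 0,
                    forbidden_interval = p$forb,
                    tad_intervals = if (is.null(p$tad)) list() else list(p$tad),
                    tad_rate = if (name == "mdm2_p53") 0.16 else 1,
                    background_rate = 0)

  config <- run_config(
    name = name,
    shear = list(mean_len = p$shear[1L], sd_len = p$shear[2L],
                 min_len = 30L, n_fragments = as.integer(p$n)),
    binding = binding,
    reads = list(read_len = 150L, substitution_rate = 0),
    mapper = list(k = 15L, max_mismatches = 3L),
    caller = list(tau = 0.99, secondary_floor = 0.5, min_run = 10L),
    seed = seed)

  sc <- structure(list(name = name, plasmid = plasmid, config = config,
                       truth = list(
                         true_interval = if (!is.null(p$true))
                           aa_interval(p$true[1L], p$true[2L]) else NULL,
                         forbidden_interval = if (!is.null(p$forb))
                           aa_interval(p$forb[1L], p$forb[2L]) else NULL,
                         tad_interval = if (!is.null(p$tad))
                           aa_interval(p$tad[1L], p$tad[2L]) else NULL)),
                  class = "scenario")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_plasmid(plasmid, file.path(outdir, paste0(name, ".fasta")),
                  file.path(outdir, paste0(name, ".yaml")))
    yaml::write_yaml(config_to_list(config), file.path(outdir, "config.yaml"))
  }
  sc
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario>", x$name, "\n")
  print(x$plasmid)
  if (!is.null(x$truth$true_interval)) {
    cat("  truth: "); print(x$truth$true_interval)
  }
  invisible(x)
}
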