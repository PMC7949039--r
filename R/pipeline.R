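# One master seed per run; per-stage child seeds are derived deterministically
# so stages can be rerun in isolation. Stage indices: 0 reference, 1 shear,
# 2 selection, 3 reads, 4 mapping.
stage_seed <- function(master, stage) {
  as.integer((abs(as.numeric(master)) %% 65521) * 31627 + stage * 10007) %% 2147483629L
}

CONFIG_SCHEMA_VERSION <- "1"

#' Assemble and validate a pipeline run configuration
#'
#' Unknown keys are rejected (fail-fast: silent misconfiguration is the main
#' user hazard). The blocks mirror the pipeline stages; `binding = NULL`
#' runs an unselected (pre-selection) library.
#'
#' @param name run name, used in provenance headers.
#' @param shear list: `mean_len`, `sd_len`, `min_len`, `n_fragments`.
#' @param binding list or `NULL`: `true_interval` (c(lo, hi)),
#'   `coverage_stringency`, `forbidden_interval`, `tad_intervals`,
#'   `tad_rate`, `background_rate`.
#' @param reads list: `read_len`, `substitution_rate`.
#' @param mapper list: `k`, `max_mismatches`, optional `min_insert`,
#'   `max_insert` (defaults: read length and `mean_len + 6 sd_len`).
#' @param caller list: `tau`, `secondary_floor`, `min_run`.
#' @param tad list: `enabled` (default TRUE).
#' @param seed master seed.
#' @param input optional analysis-only input: list with `r1`/`r2` FASTQ
#'   paths or `sam` path; simulation stages are skipped.
#' @return an object of class `run_config`.
#' @export
run_config <- function(name = "run", shear = list(), binding = NULL,
                       reads = list(), mapper = list(), caller = list(),
                       tad = list(enabled = TRUE), seed = 1L, input = NULL) {
  cfg <- list(name = name, shear = shear, binding = binding, reads = reads,
              mapper = mapper, caller = caller, tad = tad,
              seed = as.integer(seed), input = input)
  defaults <- list(
    shear = list(mean_len = 350, sd_len = 35, min_len = 30L, n_fragments = 1e6),
    reads = list(read_len = 150L, substitution_rate = 0),
    mapper = list(k = 15L, max_mismatches = 3L, min_insert = NULL, max_insert = NULL),
    caller = list(tau = 0.99, secondary_floor = 0.5, min_run = 10L),
    tad = list(enabled = TRUE))
  for (blk in names(defaults)) {
    unknown <- setdiff(names(cfg[[blk]]), names(defaults[[blk]]))
    if (length(unknown))
      stop("unknown key(s) in [", blk, "] block: ", paste(unknown, collapse = ", "))
    cfg[[blk]] <- utils::modifyList(defaults[[blk]], cfg[[blk]],
                                    keep.null = TRUE)
  }
  if (!is.null(binding)) {
    known <- c("true_interval", "coverage_stringency", "forbidden_interval",
               "tad_intervals", "tad_rate", "background_rate")
    unknown <- setdiff(names(binding), known)
    if (length(unknown))
      stop("unknown key(s) in [binding] block: ", paste(unknown, collapse = ", "))
  }
  cfg$schema_version <- CONFIG_SCHEMA_VERSION
  structure(cfg, class = "run_config")
}

config_to_list <- function(config) {
  x <- unclass(config)
  x$binding <- lapply(x$binding, function(v) v)  # drop aa_interval classes
  x
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config_to_list(config), tmp)
  unname(tools::md5sum(tmp))
}

binding_from_config <- function(b) {
  if (is.null(b)) return(NULL)
  as_iv <- function(x) {
    if (is.null(x)) return(NULL)
    if (inherits(x, "aa_interval")) x else aa_interval(x[1L], x[2L])
  }
  binding_model(true_interval = as_iv(b$true_interval),
                coverage_stringency = b$coverage_stringency %||% 0,
                forbidden_interval = as_iv(b$forbidden_interval),
                tad_intervals = lapply(b$tad_intervals %||% list(), as_iv),
                tad_rate = b$tad_rate %||% 1,
                background_rate = b$background_rate %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline: simulate, sequence, map, stratify, call
#'
#' Executes shear -> selection -> paired-end reads -> mapping -> dedup ->
#' frame decision -> coverage -> plateau call -> TAD annotation. When
#' `outdir` is given every artifact is written (fragments.tsv, FASTQ, SAM,
#' frames.tsv, six bedGraph tracks, calls.tsv, tad_hits.tsv, report.txt),
#' each with a provenance header (config hash, master seed, stage). Reruns
#' with the same config and seed are byte-identical. With `config$input`
#' set, simulation is skipped and reads/alignments are taken from disk.
#'
#' @param config a [run_config].
#' @param plasmid a [plasmid_map] (or use [make_scenario()], which bundles
#'   both).
#' @param outdir optional output directory.
#' @return an object of class `run_report`.
#' @export
run_pipeline <- function(config, plasmid, outdir = NULL) {
  stopifnot(inherits(config, "run_config"), inherits(plasmid, "plasmid_map"))
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  chash <- config_hash(config)
  prov <- c(run = config$name, config_hash = chash, seed = config$seed,
            schema_version = config$schema_version)
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(stage, n_in, n_out)
    message(sprintf("[%s] %s: n_in=%s n_out=%s elapsed=%.1fs", config$name,
                    stage, n_in, n_out, proc.time()[["elapsed"]] - t0))

  read_len <- config$reads$read_len
  params <- alignment_params(
    k = config$mapper$k, max_mismatches = config$mapper$max_mismatches,
    min_insert = config$mapper$min_insert %||% read_len,
    max_insert = config$mapper$max_insert %||%
      as.integer(config$shear$mean_len + 6 * config$shear$sd_len))

  n_fragments <- NA_integer_; n_selected <- NA_integer_
  selection <- NULL; pairs <- NULL
  if (is.null(config$input)) {
    sm <- shear_model(config$shear$mean_len, config$shear$sd_len,
                      config$shear$min_len, config$shear$n_fragments,
                      seed = stage_seed(config$seed, 1L))
    library_frags <- shear_plasmid(plasmid, sm)
    n_fragments <- nrow(library_frags)
    log_stage("shear", config$shear$n_fragments, n_fragments)

    binding <- binding_from_config(config$binding)
    if (!is.null(binding)) {
      selection <- simulate_selection(library_frags, plasmid, binding,
                                      seed = stage_seed(config$seed, 2L))
      sel <- selection$selected
    } else {
      sel <- library_frags
    }
    n_selected <- nrow(sel)
    log_stage("selection", n_fragments, n_selected)
    if (!is.null(outdir))
      write_fragments_tsv(sel, plasmid,
                          file.path(outdir, "fragments.tsv"), prov)

    pairs <- simulate_read_pairs(sel, plasmid, read_len = read_len,
                                 errors = error_model(config$reads$substitution_rate,
                                                      seed = stage_seed(config$seed, 3L)))
    log_stage("reads", n_selected, nrow(pairs))
    if (!is.null(outdir))
      write_fastq(pairs, file.path(outdir, "reads_R1.fastq.gz"),
                  file.path(outdir, "reads_R2.fastq.gz"))
    index <- index_reference(plasmid, k = params$k)
    mapping <- map_read_pairs(pairs, index, params)
  } else if (!is.null(config$input$sam)) {
    mapping <- import_sam(config$input$sam, plasmid, params)
  } else {
    pairs <- read_fastq(config$input$r1, config$input$r2)
    index <- index_reference(plasmid, k = params$k)
    mapping <- map_read_pairs(pairs, index, params)
  }
  if (!is.null(outdir) && !is.null(mapping$alignments))
    export_sam(mapping, file.path(outdir, "aln.sam"))

  frags <- dedup_fragments(mapping$fragments)
  frags <- decide_frame(frags, plasmid)
  n_proper <- sum(frags$status == "proper_pair")
  n_unique <- nrow(unique_pe(frags))
  inframe <- filter_inframe(frags, plasmid)
  n_inframe <- nrow(inframe)
  log_stage("map", if (!is.null(pairs)) nrow(pairs) else NA, n_proper)
  stopifnot(n_inframe <= n_unique, n_unique <= n_proper)

  fd <- frame_distribution(unique_pe(frags)$frame)
  if (!is.null(outdir)) {
    write_frames_tsv(frags, file.path(outdir, "frames.tsv"), prov)
    for (mode in c("All", "UniquePE", "InFrame")) {
      for (space in c("nt", "aa")) {
        tr <- coverage_track(frags, plasmid, mode, space)
        fn <- sprintf("coverage_%s.%s.bedgraph",
                      c(All = "all", UniquePE = "unique", InFrame = "inframe")[mode],
                      space)
        write_bedgraph(tr, file.path(outdir, fn),
                       provenance = c(prov, mode = mode, space = space))
      }
    }
  }

  aa_track <- coverage_track(frags, plasmid, "InFrame", "aa")
  call <- NULL
  call <- tryCatch(call_plateau(aa_track, tau = config$caller$tau,
                                secondary_floor = config$caller$secondary_floor,
                                min_run = config$caller$min_run),
                   error = function(e) {
                     message("domain caller: ", conditionMessage(e))
                     NULL
                   })

  tad_hits <- NULL
  if (isTRUE(config$tad$enabled)) {
    orf_pep <- translate_dna(plasmid_subseq(plasmid, plasmid$cds_start,
                                            3L * plasmid$cds_aa_length), 0L)
    tad_hits <- scan_peptide(orf_pep)
    if (!is.null(call)) call <- annotate_calls_with_tads(call, tad_hits)
    vector_hits <- scan_plasmid_frames(plasmid)
    if (!is.null(outdir))
      write_tsv_with_header(vector_hits, file.path(outdir, "tad_hits.tsv"), prov)
  }
  if (!is.null(outdir))
    write_tsv_with_header(report_call(call), file.path(outdir, "calls.tsv"), prov)

  report <- structure(list(
    name = config$name, config_hash = chash, seed = config$seed,
    counts = c(fragments = n_fragments, selected = n_selected,
               proper = n_proper, unique_pe = n_unique, inframe = n_inframe),
    selection = selection,
    frame_distribution = fd,
    call = call,
    tad_hits = tad_hits,
    aa_track = aa_track,
    fragments = frags), class = "run_report")
  if (!is.null(outdir)) {
    txt <- utils::capture.output(print(report))
    writeLines(c(paste0("# ", names(prov), "=", prov), txt),
               file.path(outdir, "report.txt"))
  }
  report
}

#' Run a packaged scenario end to end
#'
#' Convenience wrapper: `run_scenario(make_scenario("craf_kras", seed = 7))`.
#'
#' @param scenario a `scenario` from [make_scenario()].
#' @param outdir optional output directory, as in [run_pipeline()].
#' @return a `run_report`.
#' @export
run_scenario <- function(scenario, outdir = NULL) {
  stopifnot(inherits(scenario, "scenario"))
  run_pipeline(scenario$config, scenario$plasmid, outdir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>", x$name, " seed", x$seed, " config", x$config_hash, "\n")
  cat("  counts:", paste(names(x$counts), x$counts, sep = "=", collapse = "  "), "\n")
  cat(sprintf("  frame classes (UniquePE): mean %.2f%% ± %.2f%%\n",
              x$frame_distribution$mean_pct, x$frame_distribution$sd_pct))
  print(round(x$frame_distribution$fractions * 100, 2))
  if (!is.null(x$call)) print(x$call) else cat("  no domain call\n")
  if (!is.null(x$tad_hits) && nrow(x$tad_hits))
    cat("  ORF TAD hits at:",
        paste(x$tad_hits$start_res, x$tad_hits$peptide, collapse = "; "), "\n")
  invisible(x)
}

write_tsv_with_header <- function(df, path, prov) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", names(prov), "=", prov), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# BED-like fragment library TSV: chrom, start, end, id, selection_cause,
# strand, frame_label
write_fragments_tsv <- function(frags, plasmid, path, prov) {
  df <- data.frame(chrom = plasmid$name, start = frags$start,
                   end = frags$start + frags$length,
                   id = frags$id, selection_cause = frags$cause,
                   strand = frags$strand, frame_label = frags$frame)
  write_tsv_with_header(df, path, prov)
}

write_frames_tsv <- function(frags, path, prov) {
  write_tsv_with_header(
    frags[, c("qname", "start", "end", "strand", "status", "duplicate", "frame")],
    path, prov)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with the [run_config()] blocks.
#' @return a validated [run_config].
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$schema_version <- NULL
  do.call(run_config, x)
}
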