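#' Reporter-selection model for a two-hybrid fragment screen
#'
#' Encodes which fragments activate the reporter and survive auxotrophic
#' selection. A fragment is selected for *binding* when it is in the coding
#' frame, its translation from the fusion junction reaches the end of the
#' true binding interval without a stop codon, its residue span covers the
#' whole interval, and it does not touch the forbidden interval. Fragments
#' carrying a transactivating (TAD) interval in frame self-activate the
#' reporter bait-independently; any fragment can come up as background at a
#' small rate (empty-vector colonies).
#'
#' @param true_interval [aa_interval]: the bait-binding motif on the prey ORF.
#' @param coverage_stringency probability that a fragment covering only part
#'   of `true_interval` is still selected. 0 (default) models high-stringency
#'   quadruple-dropout selection (full coverage required); values > 0 model
#'   leaky triple-dropout selection.
#' @param forbidden_interval optional [aa_interval] whose in-frame inclusion
#'   abolishes selection (a negative binding element giving a sharp coverage
#'   edge).
#' @param tad_intervals list of [aa_interval]s whose in-frame inclusion causes
#'   bait-independent self-activation.
#' @param tad_rate probability that a coding-frame fragment covering a TAD
#'   interval actually self-activates (1 = always).
#' @param background_rate probability that any fragment is selected
#'   regardless of content.
#' @return an object of class `binding_model`.
#' @export
binding_model <- function(true_interval = NULL, coverage_stringency = 0,
                          forbidden_interval = NULL, tad_intervals = list(),
                          tad_rate = 1, background_rate = 0) {
  stopifnot(is.null(true_interval) || inherits(true_interval, "aa_interval"),
            is.null(forbidden_interval) || inherits(forbidden_interval, "aa_interval"),
            coverage_stringency >= 0, coverage_stringency <= 1,
            tad_rate >= 0, tad_rate <= 1,
            background_rate >= 0, background_rate <= 1)
  if (inherits(tad_intervals, "aa_interval")) tad_intervals <- list(tad_intervals)
  structure(list(true_interval = true_interval,
                 coverage_stringency = coverage_stringency,
                 forbidden_interval = forbidden_interval,
                 tad_intervals = tad_intervals,
                 tad_rate = tad_rate,
                 background_rate = background_rate),
            class = "binding_model")
}

# Sorted signed (relative to cds_start) positions of stop-codon starts, per
# codon phase class 0/1/2 on the sense strand. Used to test read-through from
# an arbitrary junction without translating every candidate.
stop_positions_by_phase <- function(plasmid) {
  L <- plasmid$length
  doubled <- paste0(plasmid$sequence, plasmid$sequence)
  starts <- seq_len(L)
  codons <- substring(doubled, starts, starts + 2L)
  is_stop <- codons %in% c("TAA", "TAG", "TGA")
  half <- L %/% 2L
  rel <- ((starts - 1L - plasmid$cds_start + half) %% L) - half
  rel <- rel[is_stop]
  lapply(0:2, function(ph) sort(rel[rel %% 3L == ph]))
}

# TRUE when a stop codon occurs at signed relative position in [from, to]
# within phase class `from %% 3`. `stops` comes from stop_positions_by_phase.
has_stop_between <- function(stops, from, to) {
  if (length(from) == 0L) return(logical(0L))
  ph <- unique(from %% 3L)
  stopifnot(length(ph) == 1L)
  v <- stops[[ph + 1L]]
  if (length(v) == 0L) return(rep(FALSE, length(from)))
  # count stops <= to minus stops < from, vectorised
  findInterval(to, v) - findInterval(from - 0.5, v) > 0L
}

#' Apply the selection model to a fragment library
#'
#' Vectorised over the library; one pre-drawn uniform per fragment per
#' stochastic rule (partial coverage, TAD activation, background) so that
#' increasing a rate with the same seed can only add selected fragments
#' (coupled randomness).
#'
#' @param fragments data.frame from [shear_plasmid()].
#' @param plasmid a [plasmid_map].
#' @param binding a [binding_model].
#' @param seed RNG seed for the stochastic selection rules.
#' @param label_map the [frame_label_map] used at cloning.
#' @return `fragments` with `selected` and `cause`
#'   (`binding`/`self_activation`/`background`/`none`) filled in.
#' @export
select_fragments <- function(fragments, plasmid, binding, seed = 1L,
                             label_map = frame_label_map()) {
  stopifnot(inherits(binding, "binding_model"))
  n <- nrow(fragments)
  if (n == 0L) return(fragments)
  set.seed(as.integer(seed))
  u_partial <- stats::runif(n)
  u_tad <- stats::runif(n)
  u_bg <- stats::runif(n)

  coding <- fragments$strand == "+" &
    ((fragments$start - plasmid$cds_start) %% 3L == 0L)
  b <- residue_span_bounds(fragments$start, fragments$length, plasmid)
  has_span <- !is.na(b$first)
  L <- plasmid$length
  half <- L %/% 2L
  s_rel <- ((fragments$start - plasmid$cds_start + half) %% L) - half

  cause <- rep("none", n)

  if (!is.null(binding$true_interval)) {
    lo <- binding$true_interval$start_res; hi <- binding$true_interval$end_res
    full <- has_span & b$first <= lo & b$last >= hi
    partial <- has_span & !full & b$first <= hi & b$last >= lo
    stops <- stop_positions_by_phase(plasmid)
    # stop-free from the junction codon through the last codon of the interval
    # (N-terminal fusion: stops downstream of the interval are tolerated)
    cand <- coding & (full | partial)
    stop_ok <- rep(FALSE, n)
    if (any(cand)) {
      to <- pmin(3L * (hi - 1L), 3L * (b$last[cand] - 1L))
      stop_ok[cand] <- !has_stop_between(stops, s_rel[cand], to)
    }
    ok_forbidden <- rep(TRUE, n)
    if (!is.null(binding$forbidden_interval)) {
      flo <- binding$forbidden_interval$start_res
      fhi <- binding$forbidden_interval$end_res
      ok_forbidden <- !(has_span & b$first <= fhi & b$last >= flo)
    }
    hit <- coding & stop_ok & ok_forbidden &
      (full | (partial & u_partial < binding$coverage_stringency))
    cause[hit] <- "binding"
  }

  for (tad in binding$tad_intervals) {
    tad_hit <- cause == "none" & coding & has_span &
      b$first <= tad$start_res & b$last >= tad$end_res &
      u_tad < binding$tad_rate
    cause[tad_hit] <- "self_activation"
  }

  bg <- cause == "none" & u_bg < binding$background_rate
  cause[bg] <- "background"

  fragments$cause <- cause
  fragments$selected <- cause != "none"
  fragments
}

#' Run selection and summarise the outcome
#'
#' @inheritParams select_fragments
#' @return a list of class `selection_summary` with elements `fragments`
#'   (the full annotated library), `selected` (the surviving subset),
#'   `by_cause` and `by_frame` count tables.
#' @export
simulate_selection <- function(fragments, plasmid, binding, seed = 1L,
                               label_map = frame_label_map()) {
  if (nrow(fragments) == 0L) stop("empty fragment library")
  fragments <- select_fragments(fragments, plasmid, binding, seed, label_map)
  sel <- fragments[fragments$selected, , drop = FALSE]
  if (nrow(sel) == 0L)
    stop("empty selection: no fragment activated the reporter; ",
         "increase n_fragments or relax the binding model")
  structure(list(fragments = fragments, selected = sel,
                 by_cause = table(factor(sel$cause, levels = c(
                   "binding", "self_activation", "background"))),
                 by_frame = table(factor(sel$frame, levels = frame_levels()))),
            class = "selection_summary")
}

frame_levels <- function() c("-3", "-2", "-1", "+1", "+2", "+3")

#' @export
print.selection_summary <- function(x, ...) {
  cat(sprintf("<selection_summary> %d / %d fragments selected\n",
              nrow(x$selected), nrow(x$fragments)))
  cat("  by cause:", paste(names(x$by_cause), x$by_cause, collapse = ", "), "\n")
  cat("  by frame:", paste(names(x$by_frame), x$by_frame, collapse = ", "), "\n")
  invisible(x)
}
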