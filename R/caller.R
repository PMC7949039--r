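#' Call the core binding domain as a coverage plateau
#'
#' The core binding motif of a saturating fragment screen appears as a
#' plateau in the in-frame residue-space coverage: every selected fragment
#' must cover the whole motif, so coverage is (essentially) constant there
#' and decays on the flanks at a rate set by the number of admissible
#' fragment placements. The primary call is the longest maximal run of
#' consecutive residues with depth at least `tau * max(depth)`; ties are
#' broken by higher mean depth, then leftmost. Disjoint runs above the
#' secondary floor (at least `min_run` residues long) are reported as
#' secondary calls — e.g. a transactivating (self-activation) peak elsewhere
#' on the ORF.
#'
#' @param track an aa-space `InFrame` [coverage_track].
#' @param tau plateau threshold as a fraction of the maximum depth, in (0,1].
#'   The default 0.99 excludes the first flanking residue once the number of
#'   selected fragments is large compared to the number of admissible
#'   junction placements, while tolerating minor mapping loss.
#' @param secondary_floor fraction of the maximum depth above which a
#'   disjoint run is reported as a secondary call.
#' @param min_run minimum secondary-run length, residues.
#' @return an object of class `domain_call`.
#' @export
call_plateau <- function(track, tau = 0.99, secondary_floor = 0.5, min_run = 10L) {
  stopifnot(inherits(track, "coverage_track"), track$space == "aa",
            tau > 0, tau <= 1)
  v <- track$values
  m <- max(v)
  if (m <= 0) stop("no-call: coverage track is all zero")
  runs <- runs_at_least(v, tau * m)
  if (nrow(runs) == 0L) stop("no-call: no run reaches tau * max depth")
  runs$mean_depth <- vapply(seq_len(nrow(runs)), function(i)
    mean(v[runs$start[i]:runs$end[i]]), numeric(1L))
  o <- order(-(runs$end - runs$start), -runs$mean_depth, runs$start)
  prim <- runs[o[1L], ]
  interval <- aa_interval(prim$start, prim$end)
  plateau_depth <- max(v[prim$start:prim$end])

  sec_runs <- runs_at_least(v, secondary_floor * m)
  contains_prim <- sec_runs$start <= prim$start & sec_runs$end >= prim$end
  sec_runs <- sec_runs[!contains_prim &
                       (sec_runs$end - sec_runs$start + 1L) >= min_run, , drop = FALSE]
  secondary <- data.frame(start_res = sec_runs$start, end_res = sec_runs$end,
                          width_aa = sec_runs$end - sec_runs$start + 1L,
                          depth = vapply(seq_len(nrow(sec_runs)), function(i)
                            max(v[sec_runs$start[i]:sec_runs$end[i]]), numeric(1L)),
                          possible_self_activation = rep(FALSE, nrow(sec_runs)))

  call <- structure(list(interval = interval,
                         width_aa = aa_width(interval),
                         plateau_depth = plateau_depth,
                         tau = tau,
                         secondary_floor = secondary_floor,
                         min_run = as.integer(min_run),
                         secondary = secondary,
                         orf = track$plasmid_name,
                         possible_self_activation = FALSE),
                    class = "domain_call")
  sl <- flank_asymmetry(track, call)
  call$left_slope_aa <- sl$left_slope_aa
  call$right_slope_aa <- sl$right_slope_aa
  call$left_censored <- sl$left_censored
  call$right_censored <- sl$right_censored
  call$slope_ratio <- sl$ratio
  call
}

# maximal runs of values >= threshold, as data.frame(start, end) in 1-based
# inclusive positions
runs_at_least <- function(v, thr) {
  r <- rle(v >= thr)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Flank slope diagnostics of a domain call
#'
#' Distance (in residues) from each plateau edge outward to the first
#' position with depth at most half the plateau depth. A short slope means
#' coverage stops sharply (e.g. against a negative binding element); a long
#' slope means fragments freely overlap into the flanking sequence. The
#' ratio left/right (right floored at 1 residue) quantifies the asymmetry.
#' Slopes hitting the ORF boundary are reported boundary-censored.
#'
#' @param track the aa-space [coverage_track] the call was made on.
#' @param call a [domain_call].
#' @return a list with `left_slope_aa`, `right_slope_aa`, `left_censored`,
#'   `right_censored` and `ratio`.
#' @export
flank_asymmetry <- function(track, call) {
  v <- track$values
  half <- call$plateau_depth / 2
  lo <- call$interval$start_res; hi <- call$interval$end_res
  left <- NA_integer_; left_cens <- FALSE
  if (lo == 1L) { left <- 0L; left_cens <- TRUE } else {
    below <- which(v[seq_len(lo - 1L)] <= half)
    if (length(below)) left <- lo - max(below)
    else { left <- lo - 1L; left_cens <- TRUE }
  }
  right <- NA_integer_; right_cens <- FALSE
  n <- length(v)
  if (hi == n) { right <- 0L; right_cens <- TRUE } else {
    after <- which(v[(hi + 1L):n] <= half)
    if (length(after)) right <- min(after)
    else { right <- n - hi; right_cens <- TRUE }
  }
  list(left_slope_aa = left, right_slope_aa = right,
       left_censored = left_cens, right_censored = right_cens,
       ratio = left / max(right, 1L))
}

#' @export
print.domain_call <- function(x, ...) {
  cat(sprintf("<domain_call> %s: aa %d to %d (%d aa), depth %g, tau %.2f\n",
              x$orf, x$interval$start_res, x$interval$end_res, x$width_aa,
              x$plateau_depth, x$tau))
  cat(sprintf("  flank slopes: left %s%s, right %s%s (ratio %.2f)\n",
              x$left_slope_aa, if (x$left_censored) " (boundary-censored)" else "",
              x$right_slope_aa, if (x$right_censored) " (boundary-censored)" else "",
              x$slope_ratio))
  if (x$possible_self_activation)
    cat("  flagged: possible_self_activation\n")
  if (nrow(x$secondary)) {
    cat(sprintf("  secondary: aa %d to %d (%d aa), depth %g%s\n",
                x$secondary$start_res, x$secondary$end_res, x$secondary$width_aa,
                x$secondary$depth,
                ifelse(x$secondary$possible_self_activation,
                       " [possible_self_activation]", "")))
  }
  invisible(x)
}

#' Tabulate a domain call (and its secondaries) for reporting
#'
#' One row per call: `orf`, `start_res`, `end_res`, `width_aa`, `depth`,
#' `tau`, `left_slope_aa`, `right_slope_aa`, `secondary`,
#' `possible_self_activation`. Writes TSV when `path` is given; an empty
#' (no-call) input yields a single `no_call` row.
#'
#' @param call a [domain_call], or `NULL` for no call.
#' @param path optional output TSV path.
#' @return the report data.frame, invisibly when `path` is given.
#' @export
report_call <- function(call, path = NULL) {
  if (is.null(call)) {
    out <- data.frame(orf = "no_call", start_res = NA, end_res = NA,
                      width_aa = NA, depth = NA, tau = NA,
                      left_slope_aa = NA, right_slope_aa = NA,
                      secondary = FALSE, possible_self_activation = FALSE)
  } else {
    out <- data.frame(orf = call$orf,
                      start_res = call$interval$start_res,
                      end_res = call$interval$end_res,
                      width_aa = call$width_aa,
                      depth = call$plateau_depth,
                      tau = call$tau,
                      left_slope_aa = call$left_slope_aa,
                      right_slope_aa = call$right_slope_aa,
                      secondary = FALSE,
                      possible_self_activation = call$possible_self_activation)
    if (nrow(call$secondary))
      out <- rbind(out, data.frame(orf = call$orf,
                                   start_res = call$secondary$start_res,
                                   end_res = call$secondary$end_res,
                                   width_aa = call$secondary$width_aa,
                                   depth = call$secondary$depth,
                                   tau = call$tau,
                                   left_slope_aa = NA, right_slope_aa = NA,
                                   secondary = TRUE,
                                   possible_self_activation =
                                     call$secondary$possible_self_activation))
  }
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
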