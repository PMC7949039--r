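#' Acoustic-shear model for fragment library construction
#'
#' Fragment starts are uniform on the circular plasmid; lengths are drawn from
#' a normal distribution truncated below at `min_len` (rounded to integers);
#' insertion orientation is uniform. The defaults mirror a size-selected
#' ~350-bp shear fraction.
#'
#' @param mean_len mean fragment length, nt.
#' @param sd_len length standard deviation, nt.
#' @param min_len smallest retained fragment, nt.
#' @param n_fragments number of fragments (clones) in the library.
#' @param seed RNG seed for this stage.
#' @return an object of class `shear_model`.
#' @export
shear_model <- function(mean_len = 350, sd_len = 35, min_len = 30,
                        n_fragments = 1e6, seed = 1L) {
  stopifnot(min_len >= 1, mean_len >= min_len, n_fragments >= 0, sd_len >= 0)
  structure(list(mean_len = mean_len, sd_len = sd_len, min_len = as.integer(min_len),
                 n_fragments = as.integer(n_fragments), seed = as.integer(seed)),
            class = "shear_model")
}

#' Shear a plasmid into a random fragment library
#'
#' @param plasmid a [plasmid_map].
#' @param model a [shear_model].
#' @param label_map a [frame_label_map] used to assign the six reading-frame
#'   classes at cloning time.
#' @return a data.frame with one row per fragment: `id`, `start` (0-based nt),
#'   `length`, `strand`, `frame` (one of the six class labels), and placeholder
#'   `selected`/`cause` columns filled by [select_fragments()].
#' @export
shear_plasmid <- function(plasmid, model, label_map = frame_label_map()) {
  stopifnot(inherits(plasmid, "plasmid_map"), inherits(model, "shear_model"))
  n <- model$n_fragments
  if (n == 0L) {
    warning("empty library: n_fragments is 0")
    return(data.frame(id = integer(), start = integer(), length = integer(),
                      strand = character(), frame = character(),
                      selected = logical(), cause = character()))
  }
  set.seed(model$seed)
  start <- sample.int(plasmid$length, n, replace = TRUE) - 1L
  len <- pmax(model$min_len,
              pmin(plasmid$length,
                   as.integer(round(stats::rnorm(n, model$mean_len, model$sd_len)))))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  data.frame(id = seq_len(n), start = start, length = len, strand = strand,
             frame = assign_frame_label(start, strand, plasmid, label_map),
             selected = FALSE, cause = "none", stringsAsFactors = FALSE)
}

#' The six reading-frame class labels
#'
#' A sheared fragment can be cloned behind the fusion tag at any of three
#' codon offsets on either strand, giving six reading-frame classes. Labels
#' are bookkeeping, not biology: the map fixes which label marks the offset
#' that places the insert in the prey's native frame (the coding class,
#' `"+2"` by convention). Negative labels mean reverse-strand insertion.
#'
#' @param coding_label label carried by the in-frame sense class.
#' @return an object of class `frame_label_map`: a list with `plus` and
#'   `minus` character vectors indexed by `(start - cds_start) mod 3`.
#' @export
frame_label_map <- function(coding_label = "+2") {
  plus_all <- c("+1", "+2", "+3")
  k <- match(coding_label, plus_all)
  if (is.na(k)) stop("coding_label must be one of +1, +2, +3")
  # offsets 0,1,2 cycle through the labels starting at the coding label
  plus <- plus_all[((k - 1L) + 0:2) %% 3L + 1L]
  minus <- sub("\\+", "-", plus)
  structure(list(plus = plus, minus = minus, coding_label = coding_label),
            class = "frame_label_map")
}

#' Assign reading-frame class labels to fragments
#'
#' The label is a pure function of the fragment's leftmost base offset
#' relative to the ORF start codon, `(start - cds_start) mod 3`, and the
#' insertion strand. Offset 0 on the sense strand is the coding class.
#'
#' @param start 0-based nt start position(s).
#' @param strand `"+"`/`"-"` vector recycled against `start`.
#' @param plasmid a [plasmid_map].
#' @param label_map a [frame_label_map].
#' @return character vector of frame labels.
#' @export
assign_frame_label <- function(start, strand, plasmid, label_map = frame_label_map()) {
  offset <- (as.integer(start) - plasmid$cds_start) %% 3L
  ifelse(strand == "+", label_map$plus[offset + 1L], label_map$minus[offset + 1L])
}
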