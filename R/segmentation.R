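#' Chromatin-state segmentation over a time course
#'
#' Per-bin state labels for each time point on a shared [genome_bins()]
#' grid.
#'
#' @param states Integer bin x time-point matrix of state labels in
#'   `1..n_states` (columns named by time point).
#' @param bins The [genome_bins()] grid.
#' @param n_states Number of states K.
#' @return An object of class `state_segmentation`.
#' @export
state_segmentation <- function(states, bins, n_states) {
  states <- as.matrix(states)
  stopifnot(inherits(bins, "genome_bins"), nrow(states) == bins$n_bins,
            all(states >= 1), all(states <= n_states))
  if (is.null(colnames(states)))
    colnames(states) <- paste0("t", seq_len(ncol(states)))
  storage.mode(states) <- "integer"
  structure(list(states = states, bins = bins,
                 time_points = colnames(states),
                 n_states = as.integer(n_states)),
            class = "state_segmentation")
}

#' @export
print.state_segmentation <- function(x, ...) {
  cat("<state_segmentation> ", x$n_states, " states, ",
      length(x$time_points), " time point(s), ", x$bins$n_bins,
      " bins\n", sep = "")
  invisible(x)
}

#' @describeIn state_segmentation Merged maximal runs of identical state
#'   as a tibble (chrom, start, end, state, time_point), the interval form
#'   written to BED.
#' @param x A `state_segmentation`.
#' @param ... Unused.
#' @export
tidy.state_segmentation <- function(x, ...) {
  purrr::map_dfr(x$time_points, function(tp) {
    purrr::map_dfr(names(x$bins$n_bins_chrom), function(chrom) {
      n <- x$bins$n_bins_chrom[[chrom]]
      if (n == 0) return(NULL)
      off <- x$bins$offsets[[chrom]]
      v <- x$states[off + seq_len(n), tp]
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      tibble::tibble(
        chrom = chrom,
        start = starts * x$bins$bin_width,
        end = ends * x$bins$bin_width,
        state = paste0("cs", r$values),
        time_point = tp)
    })
  })
}

#' Genome fraction covered by each state
#'
#' Fraction of binned genome assigned to each state at each time point.
#' When a model is supplied, states whose maximal emission probability
#' falls below `blank_threshold` are flagged as "blank" (mark-devoid
#' background chromatin), and the covered (non-blank) genome fraction is
#' attached as attribute `"marked_fraction"`.
#'
#' @param segmentation A [state_segmentation()].
#' @param model Optional [chromatin_state_model()] used to flag blank
#'   states.
#' @param blank_threshold Emission ceiling below which a state is called
#'   blank (default 0.1).
#' @return Tibble with state, time_point, n_bins, fraction and (when a
#'   model is given) a logical `blank` column.
#' @export
state_coverage <- function(segmentation, model = NULL, blank_threshold = 0.1) {
  stopifnot(inherits(segmentation, "state_segmentation"))
  K <- segmentation$n_states
  out <- purrr::map_dfr(segmentation$time_points, function(tp) {
    counts <- tabulate(segmentation$states[, tp], nbins = K)
    tibble::tibble(state = seq_len(K), time_point = tp,
                   n_bins = counts,
                   fraction = counts / segmentation$bins$n_bins)
  })
  if (!is.null(model)) {
    stopifnot(model$K == K)
    blank_states <- apply(model$emission, 1, max) < blank_threshold
    out$blank <- blank_states[out$state]
    marked <- out |>
      dplyr::filter(!.data$blank) |>
      dplyr::group_by(.data$time_point) |>
      dplyr::summarise(marked_fraction = sum(.data$fraction),
                       .groups = "drop")
    attr(out, "marked_fraction") <- marked
  }
  out
}

#' Per-state segment length distribution
#'
#' Run-length statistics of the merged state intervals: minimum (never
#' below one bin width), quartiles, maximum and count, per state and time
#' point.
#'
#' @param segmentation A [state_segmentation()].
#' @return Tibble with state, time_point, n_segments and length summaries
#'   in bases.
#' @export
segment_length_stats <- function(segmentation) {
  intervals <- tidy(segmentation) |>
    dplyr::mutate(length = .data$end - .data$start)
  intervals |>
    dplyr::group_by(.data$state, .data$time_point) |>
    dplyr::summarise(
      n_segments = dplyr::n(),
      min_bp = min(.data$length),
      q25_bp = unname(quantile(.data$length, 0.25)),
      median_bp = unname(quantile(.data$length, 0.5)),
      q75_bp = unname(quantile(.data$length, 0.75)),
      max_bp = max(.data$length),
      .groups = "drop")
}

#' Transition structure summary
#'
#' For each state, the most likely off-diagonal successor and a sparsity
#' measure of its transition row: the Shannon entropy (bits) of the row.
#' Low entropy means the state is followed by itself or one other state
#' rather than by many, the spatial-grammar signature of chromatin
#' domains.
#'
#' @param model A [chromatin_state_model()].
#' @return Tibble with state, self_transition, top_successor (NA when the
#'   off-diagonal mass is zero), top_successor_prob and entropy_bits.
#' @export
transition_summary <- function(model) {
  stopifnot(inherits(model, "chromatin_state_model"))
  K <- model$K
  purrr::map_dfr(seq_len(K), function(k) {
    row <- model$transition[k, ]
    off <- row
    off[k] <- 0
    top <- if (sum(off) <= 0) NA_integer_ else as.integer(which.max(off))
    p <- row[row > 0]
    tibble::tibble(
      state = k,
      self_transition = unname(row[k]),
      top_successor = top,
      top_successor_prob = if (is.na(top)) NA_real_ else unname(off[top]),
      entropy_bits = -sum(p * log2(p)))
  })
}
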