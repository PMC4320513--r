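#' Per-bin chromatin mark tracks over a time course
#'
#' Container for bin x mark signal matrices, one per time point, aligned
#' to a common [genome_bins()] grid. Tracks are either raw per-bin counts
#' (`mode = "count"`) or binarized presence calls (`mode = "binary"`), the
#' form consumed by [hmm_fit()].
#'
#' @param tracks Named list (one element per time point) of bin x mark
#'   matrices with identical dimensions.
#' @param bins The [genome_bins()] grid the rows align to.
#' @param marks Character vector of mark names (matrix columns).
#' @param mode `"count"` or `"binary"`.
#' @return An object of class `mark_track_set`.
#' @export
mark_track_set <- function(tracks, bins, marks, mode = c("count", "binary")) {
  mode <- match.arg(mode)
  stopifnot(inherits(bins, "genome_bins"), is.list(tracks),
            length(tracks) >= 1, !is.null(names(tracks)))
  for (tp in names(tracks)) {
    m <- tracks[[tp]]
    if (!is.matrix(m) || nrow(m) != bins$n_bins || ncol(m) != length(marks))
      stop("track for ", tp, " must be a ", bins$n_bins, " x ",
           length(marks), " matrix")
    if (any(m < 0)) stop("negative values in track for ", tp)
    if (mode == "binary" && !all(m %in% c(0, 1)))
      stop("binary tracks must contain only 0/1")
    colnames(tracks[[tp]]) <- marks
  }
  structure(list(tracks = tracks, bins = bins, marks = marks,
                 time_points = names(tracks), mode = mode),
            class = "mark_track_set")
}

#' @export
print.mark_track_set <- function(x, ...) {
  cat("<mark_track_set> ", length(x$time_points), " time point(s) x ",
      x$bins$n_bins, " bins x ", length(x$marks), " marks (",
      x$mode, " mode)\n", sep = "")
  invisible(x)
}

#' Poisson upper-tail binarization threshold
#'
#' The smallest count `c` whose upper-tail probability under a Poisson
#' background, `P(X >= c; lambda)`, does not exceed `p_threshold`. This is
#' the standard signal/background call used to binarize ChIP-seq bin
#' counts before chromatin-state learning.
#'
#' @param lambda Poisson background rate (mean count per bin).
#' @param p_threshold Upper-tail probability cutoff, default `1e-4`.
#' @return Integer threshold count.
#' @examples
#' poisson_threshold(1)    # 7: P(X >= 7; 1) ~ 8.3e-5 <= 1e-4
#' @export
poisson_threshold <- function(lambda, p_threshold = 1e-4) {
  stopifnot(lambda > 0, p_threshold > 0, p_threshold <= 1)
  cc <- 0L
  # P(X >= c) = ppois(c - 1, lower.tail = FALSE); decreasing in c
  while (ppois(cc - 1, lambda, lower.tail = FALSE) > p_threshold) {
    cc <- cc + 1L
    if (cc > lambda + 1000)
      stop("threshold search did not converge; check lambda/p_threshold")
  }
  cc
}

#' Binarize count tracks against a Poisson background
#'
#' Each bin is called present (1) for a mark iff its count reaches the
#' mark's [poisson_threshold()]. The background rate per mark defaults to
#' its genome-wide mean count pooled across time points.
#'
#' @param counts A `mark_track_set` in count mode.
#' @param background_rate Optional named numeric vector of per-mark
#'   background rates; estimated from the data when `NULL`.
#' @param p_threshold Upper-tail cutoff, default `1e-4`.
#' @return A `mark_track_set` in binary mode; per-mark thresholds and
#'   rates are attached as attribute `"binarization"`.
#' @export
binarize_tracks <- function(counts, background_rate = NULL,
                            p_threshold = 1e-4) {
  stopifnot(inherits(counts, "mark_track_set"))
  if (counts$mode != "count")
    stop("binarize_tracks() expects a count-mode track set")
  marks <- counts$marks
  if (is.null(background_rate)) {
    pooled <- do.call(rbind, counts$tracks)
    background_rate <- colMeans(pooled)
  } else {
    stopifnot(length(background_rate) == length(marks),
              all(background_rate > 0))
    background_rate <- setNames(as.numeric(background_rate), marks)
  }
  # a mark with zero background (no counts anywhere) can never be called
  thresholds <- vapply(background_rate, function(l) {
    if (l == 0) return(NA_integer_)
    poisson_threshold(l, p_threshold = p_threshold)
  }, integer(1))
  binary <- lapply(counts$tracks, function(m) {
    out <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
    thr <- ifelse(is.na(thresholds), Inf, thresholds)
    out[m >= matrix(thr, nrow(m), ncol(m), byrow = TRUE)] <- 1L
    out
  })
  out <- mark_track_set(binary, counts$bins, marks, mode = "binary")
  attr(out, "binarization") <- tibble::tibble(
    mark = marks, background_rate = unname(background_rate),
    threshold = unname(thresholds), p_threshold = p_threshold)
  out
}
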