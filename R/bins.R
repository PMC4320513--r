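#' Fixed-width genome binning
#'
#' Partition each chromosome into consecutive fixed-width bins (200 bp by
#' default, the resolution at which chromatin-state models are learned).
#' Bins are half-open `[start, start + bin_width)` in 0-based coordinates;
#' a trailing partial bin shorter than `bin_width` is dropped. Bins carry a
#' global index running over chromosomes in the order given, so per-bin
#' vectors (signals, states) align across the whole genome.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bases.
#' @param bin_width Bin width in bases (default 200).
#'
#' @return An object of class `genome_bins`: a list with `chrom_lengths`,
#'   `bin_width`, per-chromosome bin counts `n_bins_chrom`, global offsets
#'   `offsets` and total bin count `n_bins`.
#' @examples
#' bins <- genome_bins(c(chr1 = 1e6, chr2 = 5e5))
#' bins$n_bins
#' @export
genome_bins <- function(chrom_lengths, bin_width = 200) {
  stopifnot(length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)),
            all(nzchar(names(chrom_lengths))), bin_width >= 1)
  if (anyDuplicated(names(chrom_lengths)))
    stop("duplicated chromosome names")
  n_bins_chrom <- as.integer(floor(chrom_lengths / bin_width))
  names(n_bins_chrom) <- names(chrom_lengths)
  offsets <- c(0L, cumsum(n_bins_chrom))[seq_along(n_bins_chrom)]
  names(offsets) <- names(chrom_lengths)
  structure(
    list(chrom_lengths = chrom_lengths,
         bin_width = as.integer(bin_width),
         n_bins_chrom = n_bins_chrom,
         offsets = offsets,
         n_bins = sum(n_bins_chrom)),
    class = "genome_bins")
}

#' @export
print.genome_bins <- function(x, ...) {
  cat("<genome_bins> ", length(x$chrom_lengths), " chromosome(s), ",
      x$n_bins, " bins of ", x$bin_width, " bp\n", sep = "")
  invisible(x)
}

#' @describeIn genome_bins Bins as a tibble with chrom, start, end and the
#'   global bin index (one row per bin).
#' @param x A `genome_bins` object.
#' @param ... Unused.
#' @method as_tibble genome_bins
#' @export
as_tibble.genome_bins <- function(x, ...) {
  chrom <- rep(names(x$n_bins_chrom), x$n_bins_chrom)
  local_idx <- unlist(lapply(x$n_bins_chrom, function(n) seq_len(n) - 1L),
                      use.names = FALSE)
  start <- local_idx * x$bin_width
  tibble::tibble(chrom = chrom, start = start, end = start + x$bin_width,
                 bin = seq_len(x$n_bins))
}

# (chrom, position) -> global bin index; positions outside the binned span -> NA
bin_index <- function(bins, chrom, pos) {
  stopifnot(all(chrom %in% names(bins$chrom_lengths)))
  local <- floor(pos / bins$bin_width)
  idx <- bins$offsets[chrom] + local + 1L
  bad <- local < 0 | local >= bins$n_bins_chrom[chrom]
  idx[bad] <- NA_integer_
  as.integer(idx)
}

# global bin index -> chrom name and 0-based start
bin_location <- function(bins, idx) {
  stopifnot(all(idx >= 1), all(idx <= bins$n_bins))
  chrom_id <- findInterval(idx - 1L, unname(bins$offsets))
  chrom <- names(bins$offsets)[chrom_id]
  start <- (idx - 1L - bins$offsets[chrom_id]) * bins$bin_width
  list(chrom = chrom, start = as.numeric(start))
}
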