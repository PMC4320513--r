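#' Aggregate a bedGraph track onto genome bins
#'
#' Reads a bedGraph file and produces one value per bin of a
#' [genome_bins()] grid. Intervals straddling bin edges are split
#' pro-rata: for `sum`, an interval's value is apportioned to bins in
#' proportion to the overlapped fraction of the interval; for `mean`, the
#' bin value is the per-base mean signal over the bin (uncovered bases
#' count as zero); for `max`, the bin takes the maximum value among
#' overlapping intervals. Uncovered bins are 0.
#'
#' @param path bedGraph file (0-based half-open intervals).
#' @param bins A [genome_bins()] grid.
#' @param aggregation One of `"sum"`, `"mean"`, `"max"`.
#' @return Numeric vector of length `bins$n_bins`.
#' @export
read_bedgraph_to_bins <- function(path, bins,
                                  aggregation = c("sum", "mean", "max")) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(bins, "genome_bins"))
  out <- numeric(bins$n_bins)
  if (file.size(path) == 0) return(out)
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0) return(out)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start <- GenomicRanges::start(gr) - 1  # back to 0-based half-open
  end <- GenomicRanges::end(gr)
  value <- gr$score
  unknown <- setdiff(unique(chrom), names(bins$chrom_lengths))
  if (length(unknown))
    stop("bedGraph ", path, ": unknown chromosome(s) ",
         paste(unknown, collapse = ", "))
  too_far <- end > bins$chrom_lengths[chrom]
  if (any(too_far)) {
    i <- which(too_far)[1]
    stop("bedGraph ", path, ": interval ", chrom[i], ":", start[i], "-",
         end[i], " extends beyond chromosome length ",
         bins$chrom_lengths[chrom[i]])
  }
  w <- bins$bin_width
  # expand every interval into (bin, overlap) pairs
  b0 <- floor(start / w)
  b1 <- floor((end - 1) / w)
  nb <- b1 - b0 + 1L
  idx_rep <- rep(seq_along(start), nb)
  local_bin <- sequence(nb) - 1L + rep(b0, nb)
  seg_start <- pmax(local_bin * w, start[idx_rep])
  seg_end <- pmin((local_bin + 1) * w, end[idx_rep])
  overlap <- seg_end - seg_start
  # drop bins past the binned span (trailing partial bin was dropped)
  keep <- local_bin < bins$n_bins_chrom[chrom[idx_rep]]
  idx_rep <- idx_rep[keep]
  local_bin <- local_bin[keep]
  overlap <- overlap[keep]
  gbin <- bins$offsets[chrom[idx_rep]] + local_bin + 1L
  v <- value[idx_rep]
  if (aggregation == "sum") {
    contrib <- v * overlap / (end[idx_rep] - start[idx_rep])
    agg <- tapply(contrib, gbin, sum)
  } else if (aggregation == "mean") {
    agg <- tapply(v * overlap, gbin, sum) / w
  } else {
    agg <- tapply(v, gbin, max)
  }
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

#' Write or read a chromatin-state segmentation as BED
#'
#' Maximal runs of identical state are merged into BED intervals with the
#' state in the name field (`cs1`..`csK`), one file per time point,
#' in deterministic (chrom, start) order. Reading the files back onto the
#' same bin grid reproduces the per-bin labels exactly.
#'
#' @param segmentation A [state_segmentation()].
#' @param path Output path; for multi-time-point segmentations either a
#'   vector of one path per time point or a single path used as a stem
#'   (`<stem>_<time_point>.bed`).
#' @return `write_segmentation_bed()` invisibly returns the written file
#'   paths (named by time point).
#' @export
write_segmentation_bed <- function(segmentation, path) {
  stopifnot(inherits(segmentation, "state_segmentation"))
  tps <- segmentation$time_points
  if (length(path) == 1 && length(tps) > 1) {
    stem <- sub("\\.bed$", "", path)
    path <- paste0(stem, "_", gsub("[^A-Za-z0-9.-]", "_", tps), ".bed")
  }
  stopifnot(length(path) == length(tps))
  names(path) <- tps
  intervals <- tidy(segmentation)
  for (tp in tps) {
    df <- intervals |>
      dplyr::filter(.data$time_point == tp) |>
      dplyr::arrange(.data$chrom, .data$start)
    gr <- GenomicRanges::GRanges(
      seqnames = df$chrom,
      ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
      name = df$state,
      score = as.integer(sub("^cs", "", df$state)))
    rtracklayer::export(gr, path[[tp]], format = "bed")
  }
  invisible(path)
}

#' @rdname write_segmentation_bed
#' @param paths Named character vector (by time point) of BED files, as
#'   returned by `write_segmentation_bed()`.
#' @param bins The [genome_bins()] grid the segmentation lives on.
#' @param n_states Number of states K.
#' @export
read_segmentation_bed <- function(paths, bins, n_states) {
  stopifnot(inherits(bins, "genome_bins"), !is.null(names(paths)))
  states <- matrix(NA_integer_, bins$n_bins, length(paths),
                   dimnames = list(NULL, names(paths)))
  w <- bins$bin_width
  for (tp in names(paths)) {
    gr <- rtracklayer::import(paths[[tp]], format = "bed")
    chrom <- as.character(GenomicRanges::seqnames(gr))
    start <- GenomicRanges::start(gr) - 1
    end <- GenomicRanges::end(gr)
    st <- as.integer(sub("^cs", "", gr$name))
    for (i in seq_along(st)) {
      b0 <- bins$offsets[chrom[i]] + start[i] / w + 1
      b1 <- bins$offsets[chrom[i]] + end[i] / w
      states[b0:b1, tp] <- st[i]
    }
  }
  if (anyNA(states))
    stop("segmentation BED does not cover every bin")
  state_segmentation(states, bins, n_states)
}

#' Read a gene annotation from BED or GTF
#'
#' BED6 rows, or GTF `gene` features, are mapped to the internal 0-based
#' half-open convention (GTF's 1-based closed coordinates are shifted at
#' the parse boundary; BED already matches).
#'
#' @param path Annotation file.
#' @param format `"bed"` or `"gtf"` (default guessed from the extension).
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_annotation <- function(path, format = NULL) {
  format <- tolower(format %||% tools::file_ext(path))
  format <- match.arg(format, c("bed", "gtf"))
  gr <- tryCatch(
    rtracklayer::import(path, format = format),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (format == "gtf") {
    if (!"type" %in% names(GenomicRanges::mcols(gr)))
      stop(path, ": GTF lacks a feature type column")
    gr <- gr[gr$type == "gene"]
    ids <- gr$gene_id
  } else {
    ids <- gr$name
  }
  tibble::tibble(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    strand = as.character(GenomicRanges::strand(gr))) |>
    dplyr::mutate(strand = ifelse(.data$strand %in% c("+", "-"),
                                  .data$strand, "+")) |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' @rdname read_gene_annotation
#' @param genes Gene annotation tibble (`gene_id`, `chrom`, `start`,
#'   `end`, `strand`; 0-based half-open).
#' @export
write_gene_annotation <- function(genes, path, format = NULL) {
  format <- tolower(format %||% tools::file_ext(path))
  format <- match.arg(format, c("bed", "gtf"))
  genes <- dplyr::arrange(genes, .data$chrom, .data$start)
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1, end = genes$end),
    strand = genes$strand)
  if (format == "bed") {
    gr$name <- genes$gene_id
    gr$score <- 0L
    rtracklayer::export(gr, path, format = "bed")
  } else {
    gr$type <- "gene"
    gr$source <- "chromdyn"
    gr$gene_id <- genes$gene_id
    rtracklayer::export(gr, path, format = "gtf")
  }
  invisible(path)
}

#' Read or write a gene x time-point FPKM table
#'
#' Tab-separated with a `gene_id` column followed by one FPKM column per
#' time point in temporal order. Values must be non-negative with no
#' missing cells.
#'
#' @param path TSV file.
#' @param time_points Optional expected time-point labels (validated
#'   against the header).
#' @return Tibble with `gene_id` and the time-point columns.
#' @export
read_expression <- function(path, time_points = NULL) {
  expr <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(expr)[1] != "gene_id")
    stop(path, ": first column must be gene_id")
  tps <- names(expr)[-1]
  if (!is.null(time_points) && !identical(tps, time_points))
    stop(path, ": time-point columns are ", paste(tps, collapse = ", "),
         "; expected ", paste(time_points, collapse = ", "))
  vals <- as.matrix(expr[, -1])
  if (anyNA(vals)) stop(path, ": missing FPKM values")
  if (any(vals < 0)) stop(path, ": negative FPKM values")
  expr
}

#' @rdname read_expression
#' @param expr Expression tibble (`gene_id` + time-point columns).
#' @export
write_expression <- function(expr, path) {
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}
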