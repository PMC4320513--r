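#' Bins whose chromatin state changes between two time points
#'
#' @param segmentation A [state_segmentation()].
#' @param from,to Time-point labels (default the first adjacent pair).
#' @return Integer vector of global bin indices where the state differs.
#' @export
changed_bins <- function(segmentation, from = segmentation$time_points[1],
                         to = segmentation$time_points[2]) {
  stopifnot(inherits(segmentation, "state_segmentation"))
  missing_tp <- setdiff(c(from, to), segmentation$time_points)
  if (length(missing_tp))
    stop("unknown time point(s): ", paste(missing_tp, collapse = ", "))
  which(segmentation$states[, from] != segmentation$states[, to])
}

#' Derive the gene extension window from state-change distances
#'
#' For every adjacent time-point transition, measures the distance from
#' each changing bin (midpoint) to the nearest gene edge (zero inside a
#' gene; strand is ignored, distances symmetric upstream/downstream).
#' The per-transition upper-quantile distances (75th percentile by
#' default) are averaged across transitions and the window is
#' `fraction` (50% by default) of that average, rounded to the nearest
#' bin multiple. The window defines the flank added to gene bodies when
#' attributing chromatin states to genes.
#'
#' @param segmentation A [state_segmentation()] with >= 2 time points.
#' @param annotation Gene annotation tibble.
#' @param quantile Upper quantile of the distance distribution (default
#'   0.75).
#' @param fraction Fraction of the averaged quantile used as the window
#'   (default 0.5).
#' @return Object of class `extension_window`: list with `W` (bases),
#'   `raw_mean_quantile`, `quantile`, `fraction`, and `per_transition`
#'   tibble (transition, n_changed_bins, mean_distance,
#'   quantile_distance).
#' @export
derive_extension_window <- function(segmentation, annotation,
                                    quantile = 0.75, fraction = 0.5) {
  stopifnot(inherits(segmentation, "state_segmentation"),
            length(segmentation$time_points) >= 2,
            quantile > 0, quantile <= 1, fraction >= 0)
  tps <- segmentation$time_points
  w <- segmentation$bins$bin_width
  per <- purrr::map_dfr(seq_len(length(tps) - 1), function(i) {
    idx <- changed_bins(segmentation, tps[i], tps[i + 1])
    if (!length(idx))
      return(tibble::tibble(transition = paste0(tps[i], "/", tps[i + 1]),
                            n_changed_bins = 0L, mean_distance = NA_real_,
                            quantile_distance = NA_real_))
    loc <- bin_location(segmentation$bins, idx)
    mid <- loc$start + w / 2
    d <- distance_to_nearest_gene(loc$chrom, mid, annotation)
    tibble::tibble(transition = paste0(tps[i], "/", tps[i + 1]),
                   n_changed_bins = length(idx),
                   mean_distance = mean(d),
                   quantile_distance = unname(quantile(d, quantile)))
  })
  if (all(per$n_changed_bins == 0))
    stop("no dynamics: no bin changes state between any time points; ",
         "supply W explicitly")
  if (any(per$n_changed_bins == 0))
    warning("transition(s) without state changes excluded from the window ",
            "derivation")
  raw <- mean(per$quantile_distance, na.rm = TRUE)
  W <- round(fraction * raw / w) * w
  structure(list(W = W, raw_mean_quantile = raw, quantile = quantile,
                 fraction = fraction, per_transition = per),
            class = "extension_window")
}

#' @export
print.extension_window <- function(x, ...) {
  cat("<extension_window> W = ", x$W, " bp (", x$fraction * 100,
      "% of the averaged ", x$quantile * 100,
      "th-percentile change-to-gene distance ",
      round(x$raw_mean_quantile), " bp)\n", sep = "")
  invisible(x)
}

# distance from points to the nearest gene edge: 0 inside a gene,
# otherwise bases to the closest start/end over genes on the same
# chromosome; Inf where a chromosome carries no gene
distance_to_nearest_gene <- function(chrom, pos, annotation) {
  out <- rep(Inf, length(pos))
  for (cc in unique(chrom)) {
    sel <- chrom == cc
    genes <- annotation[annotation$chrom == cc, , drop = FALSE]
    if (!nrow(genes)) next
    p <- pos[sel]
    d <- rep(Inf, length(p))
    for (i in seq_len(nrow(genes))) {
      di <- pmax(0, genes$start[i] - p, p - genes$end[i])
      d <- pmin(d, di)
    }
    out[sel] <- d
  }
  if (any(!is.finite(out)))
    warning("changed bins on chromosome(s) without genes were dropped")
  out[is.finite(out)]
}

#' Attribute chromatin states to gene regions
#'
#' Marks a state as present for a gene at a time point iff at least one
#' bin labelled with that state overlaps the extended gene region
#' `[start - W, end + W)` (half-open, clipped to chromosome bounds;
#' strand ignored, the extension is symmetric).
#'
#' @param segmentation A [state_segmentation()].
#' @param annotation Gene annotation tibble.
#' @param window Extension W in bases, or an
#'   [derive_extension_window()] result.
#' @return A logical gene x state x time-point array of class
#'   `state_presence`.
#' @export
attribute_states <- function(segmentation, annotation, window) {
  stopifnot(inherits(segmentation, "state_segmentation"))
  W <- if (inherits(window, "extension_window")) window$W else window
  stopifnot(is.numeric(W), W >= 0)
  bins <- segmentation$bins
  bad <- setdiff(unique(annotation$chrom), names(bins$chrom_lengths))
  if (length(bad))
    stop("gene(s) on chromosome(s) absent from the segmentation: ",
         paste(annotation$gene_id[annotation$chrom %in% bad],
               collapse = ", "))
  K <- segmentation$n_states
  tps <- segmentation$time_points
  w <- bins$bin_width
  presence <- array(FALSE,
                    dim = c(nrow(annotation), K, length(tps)),
                    dimnames = list(annotation$gene_id,
                                    paste0("cs", seq_len(K)), tps))
  for (i in seq_len(nrow(annotation))) {
    chrom <- annotation$chrom[i]
    lo_pos <- max(annotation$start[i] - W, 0)
    hi_pos <- min(annotation$end[i] + W, bins$chrom_lengths[[chrom]])
    b0 <- floor(lo_pos / w)
    b1 <- min(floor((hi_pos - 1) / w), bins$n_bins_chrom[[chrom]] - 1)
    if (b1 < b0) next
    rows <- bins$offsets[[chrom]] + (b0:b1) + 1L
    for (tp in tps) {
      seen <- unique(segmentation$states[rows, tp])
      presence[i, seen, tp] <- TRUE
    }
  }
  class(presence) <- c("state_presence", class(presence))
  presence
}

#' @describeIn attribute_states Long-form tibble (gene_id, state,
#'   time_point, present).
#' @param x A `state_presence` array.
#' @param ... Unused.
#' @export
tidy.state_presence <- function(x, ...) {
  y <- x
  class(y) <- "array"
  tibble::as_tibble(as.data.frame.table(y, responseName = "present")) |>
    dplyr::rename(gene_id = "Var1", state = "Var2", time_point = "Var3") |>
    dplyr::mutate(dplyr::across(c("gene_id", "state", "time_point"),
                                as.character))
}

#' Gene ratios: per-module chromatin-state enrichment
#'
#' For each expression module, state and time point, the fraction of the
#' module's genes whose extended region carries the state. The
#' denominator is the full module size, including genes lacking the
#' state, so ratios are comparable across modules.
#'
#' @param presence A `state_presence` array from [attribute_states()].
#' @param modules Module assignment tibble (`gene_id`, `module`).
#' @return Tibble with `module`, `state`, `time_point`, `n_with_state`,
#'   `module_size`, `ratio`.
#' @export
gene_ratios <- function(presence, modules) {
  genes <- dimnames(presence)[[1]]
  miss <- setdiff(genes, modules$gene_id)
  if (length(miss))
    stop("gene(s) without module assignment: ",
         paste(head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ...")
  mod <- modules$module[match(genes, modules$gene_id)]
  sizes <- table(mod)
  if (any(sizes == 0)) stop("empty module")
  K <- dim(presence)[2]
  tps <- dimnames(presence)[[3]]
  purrr::map_dfr(tps, function(tp) {
    m <- presence[, , tp, drop = FALSE]  # gene x state
    dim(m) <- dim(m)[1:2]
    counts <- rowsum(m + 0, mod)  # module x state
    msize <- rep(as.vector(sizes[rownames(counts)]), times = K)
    tibble::tibble(
      module = rep(as.integer(rownames(counts)), times = K),
      state = rep(seq_len(K), each = nrow(counts)),
      time_point = tp,
      n_with_state = as.vector(counts),
      module_size = msize,
      ratio = as.vector(counts) / msize)
  }) |>
    dplyr::arrange(.data$module, .data$state,
                   match(.data$time_point, tps))
}

#' Number of distinct chromatin states per gene region
#'
#' The chromatin-signature complexity of each gene at each time point:
#' how many distinct states its extended region carries. The blank state
#' is counted by default (`exclude_blank` drops it).
#'
#' @param presence A `state_presence` array.
#' @param exclude_blank Drop `blank_state` from the count.
#' @param blank_state State index treated as blank (default 1).
#' @return Tibble with `gene_id`, `time_point`, `n_states`.
#' @export
state_count_per_gene <- function(presence, exclude_blank = FALSE,
                                 blank_state = 1) {
  states <- seq_len(dim(presence)[2])
  if (exclude_blank) states <- setdiff(states, blank_state)
  tps <- dimnames(presence)[[3]]
  purrr::map_dfr(tps, function(tp) {
    tibble::tibble(
      gene_id = dimnames(presence)[[1]],
      time_point = tp,
      n_states = as.integer(rowSums(presence[, states, tp, drop = FALSE])))
  })
}
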