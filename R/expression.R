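#' Filter to expressed genes
#'
#' Keeps exactly the genes with FPKM > 0 at at least one time point.
#'
#' @param expr Expression tibble (`gene_id` + time-point FPKM columns).
#' @return The filtered tibble.
#' @export
filter_expressed <- function(expr) {
  vals <- as.matrix(expr[, -1])
  expr[apply(vals, 1, max) > 0, , drop = FALSE]
}

#' Call differentially expressed genes between two time points
#'
#' Pseudocounted fold-change thresholding: a gene is up-regulated across
#' the transition iff `(FPKM_to + c) / (FPKM_from + c) > fc_threshold`
#' and down-regulated iff the ratio is below `1 / fc_threshold`.
#' Replicate-based significance testing is not part of this operation; a
#' caller-supplied per-gene P-value vector can be combined downstream.
#'
#' @param expr Expression tibble.
#' @param transition Length-2 character vector `c(from, to)` of time-point
#'   column names, e.g. `c("D0", "D3")`.
#' @param fc_threshold Fold-change threshold (> 1), default 2.
#' @param pseudocount Added to both FPKM values (default 1).
#' @return Tibble with `gene_id`, `from`, `to`, `fold_change` and
#'   `direction` (`"up"`, `"down"`, `"none"`).
#' @examples
#' expr <- tibble::tibble(gene_id = "g1", D0 = 10, D3 = 30)
#' call_differential(expr, c("D0", "D3"))   # ratio 31/11 > 2 -> up
#' @export
call_differential <- function(expr, transition, fc_threshold = 2,
                              pseudocount = 1) {
  stopifnot(length(transition) == 2, fc_threshold > 1, pseudocount > 0)
  missing_tp <- setdiff(transition, names(expr))
  if (length(missing_tp))
    stop("unknown time point(s): ", paste(missing_tp, collapse = ", "))
  ratio <- (expr[[transition[2]]] + pseudocount) /
    (expr[[transition[1]]] + pseudocount)
  tibble::tibble(
    gene_id = expr$gene_id,
    from = transition[1], to = transition[2],
    fold_change = ratio,
    direction = dplyr::case_when(
      ratio > fc_threshold ~ "up",
      ratio < 1 / fc_threshold ~ "down",
      TRUE ~ "none"))
}

#' Expression-noise profile: CV-squared vs expression level
#'
#' Bins genes by log10 FPKM (genes with zero FPKM at a time point are
#' excluded from that time point's curve) and reports, per bin and time
#' point, the squared coefficient of variation of FPKM across the bin's
#' genes: CV^2 = variance / mean^2 (sample variance). Bins with fewer
#' than two genes yield `NA`.
#'
#' @param expr Expression tibble.
#' @param n_bins Number of equal-width log-expression bins (default 20).
#' @return Tibble with `time_point`, `bin`, `log_fpkm_mid`, `n_genes`,
#'   `cv2`.
#' @export
cv2_profile <- function(expr, n_bins = 20) {
  stopifnot(n_bins >= 1)
  tps <- names(expr)[-1]
  purrr::map_dfr(tps, function(tp) {
    x <- expr[[tp]]
    x <- x[x > 0]
    if (!length(x))
      return(tibble::tibble(time_point = tp, bin = integer(),
                            log_fpkm_mid = numeric(), n_genes = integer(),
                            cv2 = numeric()))
    lx <- log10(x)
    breaks <- seq(min(lx), max(lx), length.out = n_bins + 1)
    breaks[1] <- breaks[1] - 1e-9
    bin <- cut(lx, breaks, labels = FALSE)
    mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
    purrr::map_dfr(seq_len(n_bins), function(b) {
      xs <- x[which(bin == b)]
      tibble::tibble(
        time_point = tp, bin = b, log_fpkm_mid = mids[b],
        n_genes = length(xs),
        cv2 = if (length(xs) >= 2) var(xs) / mean(xs)^2 else NA_real_)
    })
  })
}

#' Time-point coordinates on the first two principal components
#'
#' PCA of the log(FPKM + 1) matrix with time points as observations and
#' genes as variables (centred, unscaled). Component signs are fixed by a
#' canonical rule - the largest-magnitude loading of each component is
#' made positive - so coordinates are reproducible across runs.
#'
#' @param expr Expression tibble with at least 2 genes.
#' @return Tibble with `time_point`, `PC1`, `PC2` and, as attribute
#'   `"variance_explained"`, the per-component variance fractions.
#' @export
pca_summary <- function(expr) {
  vals <- log1p(as.matrix(expr[, -1]))
  if (nrow(vals) < 2) stop("need at least 2 genes")
  m <- t(vals)  # time points x genes
  if (all(apply(m, 2, var) == 0)) stop("no variance in expression matrix")
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  n_pc <- ncol(pc$x)
  out <- tibble::tibble(
    time_point = rownames(pc$x),
    PC1 = unname(pc$x[, 1]),
    PC2 = if (n_pc >= 2) unname(pc$x[, 2]) else 0)
  attr(out, "variance_explained") <- pc$sdev^2 / sum(pc$sdev^2)
  out
}

#' Cluster gene expression time-courses into modules
#'
#' Agglomerative hierarchical clustering of per-gene temporal profiles,
#' cut into `k` modules. Profiles are log(FPKM + 1) transformed and, with
#' the default `scaling = "zscore"`, z-scaled per gene so that shape
#' rather than magnitude drives module membership (constant genes get a
#' zero profile); `scaling = "log"` keeps magnitude information and
#' `"none"` clusters raw FPKM. When `k` is `NULL` and `k_range` is given,
#' k is chosen automatically by maximising the mean silhouette width over
#' the range (smallest k on ties).
#'
#' @param expr Expression tibble of expressed genes.
#' @param k Number of modules, or `NULL` to select from `k_range`.
#' @param k_range Integer vector of candidate k for automatic selection.
#' @param linkage `hclust` agglomeration method (default `"complete"`).
#' @param metric `dist` metric (default `"euclidean"`).
#' @param scaling `"zscore"`, `"log"` or `"none"`.
#' @return Tibble with `gene_id` and `module` (dense ids `1..k`).
#'   Attributes: `"k"`, `"mean_profiles"` (module x time-point mean
#'   FPKM), `"silhouette"` (per-candidate mean widths when auto-selected).
#' @export
cluster_modules <- function(expr, k = NULL, k_range = NULL,
                            linkage = "complete", metric = "euclidean",
                            scaling = c("zscore", "log", "none")) {
  scaling <- match.arg(scaling)
  vals <- as.matrix(expr[, -1])
  rownames(vals) <- expr$gene_id
  n <- nrow(vals)
  profiles <- switch(scaling,
    none = vals,
    log = log1p(vals),
    zscore = {
      lv <- log1p(vals)
      mu <- rowMeans(lv)
      s <- apply(lv, 1, sd)
      z <- (lv - mu) / ifelse(s > 0, s, 1)
      z[s == 0, ] <- 0
      z
    })
  d <- dist(profiles, method = metric)
  tree <- hclust(d, method = linkage)
  sil_tbl <- NULL
  if (is.null(k)) {
    if (is.null(k_range)) stop("supply k or k_range")
    k_range <- k_range[k_range >= 2 & k_range < n]
    widths <- vapply(k_range, function(kk) {
      cl <- cutree(tree, k = kk)
      mean(cluster::silhouette(cl, d)[, "sil_width"])
    }, numeric(1))
    sil_tbl <- tibble::tibble(k = k_range, mean_silhouette = widths)
    k <- k_range[which.max(widths)]
  }
  if (k > n) stop("k exceeds the number of genes")
  cl <- cutree(tree, k = k)
  out <- tibble::tibble(gene_id = expr$gene_id, module = as.integer(cl))
  mean_prof <- rowsum(vals, cl) / as.vector(table(cl))
  attr(out, "k") <- as.integer(k)
  attr(out, "mean_profiles") <-
    dplyr::bind_cols(tibble::tibble(module = sort(unique(out$module))),
                     tibble::as_tibble(as.data.frame(mean_prof,
                                                     check.names = FALSE)))
  attr(out, "silhouette") <- sil_tbl
  out
}
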