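# Independent oracles used across tests. These are deliberately naive
# (enumeration, exhaustive scans, textbook formulas) and share no code
# with the package implementation.

# exact per-position posteriors of a Bernoulli-emission HMM by summing
# over all K^T hidden paths
enumerate_posterior <- function(emission, transition, initial, obs) {
  K <- nrow(emission)
  T_ <- nrow(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  post <- matrix(0, T_, K)
  total <- 0
  for (r in seq_len(nrow(paths))) {
    path <- paths[r, ]
    p <- initial[path[1]]
    if (T_ > 1)
      for (t in 2:T_) p <- p * transition[path[t - 1], path[t]]
    for (t in seq_len(T_)) {
      e <- emission[path[t], ]
      p <- p * prod(ifelse(obs[t, ] == 1, e, 1 - e))
    }
    total <- total + p
    for (t in seq_len(T_)) post[t, path[t]] <- post[t, path[t]] + p
  }
  post / total
}

# exact two-sided rank-sum P by enumerating all assignments of the
# pooled values to the two groups (requires no ties)
enumerate_wilcoxon <- function(x, y, alternative = "two.sided") {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  n <- length(x)
  W_obs <- sum(rank(pooled)[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(length(pooled), n)
  W_all <- apply(combos, 2, function(idx) {
    sum(rank(pooled)[idx]) - n * (n + 1) / 2
  })
  if (alternative == "two.sided") {
    mu <- n * length(y) / 2
    mean(abs(W_all - mu) >= abs(W_obs - mu) - 1e-12)
  } else if (alternative == "less") {
    mean(W_all <= W_obs + 1e-12)
  } else {
    mean(W_all >= W_obs - 1e-12)
  }
}

# textbook one-sample two-sided t-test P
textbook_t_p <- function(x, mu) {
  n <- length(x)
  tstat <- (mean(x) - mu) / (sd(x) / sqrt(n))
  2 * pt(-abs(tstat), df = n - 1)
}

# brute-force state presence: scan every bin of every gene region
brute_presence <- function(segmentation, annotation, W) {
  bins <- segmentation$bins
  w <- bins$bin_width
  tps <- segmentation$time_points
  K <- segmentation$n_states
  out <- array(FALSE, c(nrow(annotation), K, length(tps)),
               dimnames = list(annotation$gene_id,
                               paste0("cs", seq_len(K)), tps))
  bin_tbl <- tibble::as_tibble(bins)
  for (i in seq_len(nrow(annotation))) {
    lo <- annotation$start[i] - W
    hi <- annotation$end[i] + W
    rows <- which(bin_tbl$chrom == annotation$chrom[i] &
                    bin_tbl$start < hi & bin_tbl$end > lo)
    for (tp in tps)
      for (b in rows)
        out[i, segmentation$states[b, tp], tp] <- TRUE
  }
  out
}

# brute-force distance from a point to the nearest gene on its chromosome
brute_nearest_gene <- function(chrom, pos, annotation) {
  genes <- annotation[annotation$chrom == chrom, ]
  if (!nrow(genes)) return(Inf)
  min(vapply(seq_len(nrow(genes)), function(i) {
    if (pos >= genes$start[i] && pos < genes$end[i]) return(0)
    min(abs(pos - genes$start[i]), abs(pos - genes$end[i]))
  }, numeric(1)))
}

# small random segmentation over an existing bin grid
random_segmentation <- function(bins, n_states, n_time = 2, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(sample.int(n_states, bins$n_bins * n_time, replace = TRUE),
                bins$n_bins, n_time)
    colnames(m) <- paste0("t", seq_len(n_time))
    state_segmentation(m, bins, n_states)
  })
}

expect_tibble_equal <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b), ignore_attr = TRUE)
}
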