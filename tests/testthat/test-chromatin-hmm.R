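toy_tracks <- function(obs, bins = NULL, marks = NULL) {
  # wrap a 0/1 matrix (bins x marks) as a single-time-point track set
  marks <- marks %||% paste0("m", seq_len(ncol(obs)))
  bins <- bins %||% genome_bins(c(chr1 = nrow(obs) * 200), 200)
  colnames(obs) <- marks
  mark_track_set(list(D0 = obs), bins, marks, mode = "binary")
}

test_that("Poisson binarization threshold matches tail enumeration", {
  # independent oracle: accumulate the Poisson pmf directly
  oracle_threshold <- function(lambda, p) {
    upper <- 1
    cc <- 0
    while (upper > p) {
      upper <- upper - dpois(cc, lambda)
      cc <- cc + 1
    }
    cc
  }
  for (lambda in c(0.5, 1, 2, 5)) {
    for (p in c(1e-4, 1e-3, 0.01)) {
      expect_equal(poisson_threshold(lambda, p),
                   oracle_threshold(lambda, p))
    }
  }
  expect_equal(poisson_threshold(1, 1e-4), 7L)
  # P(X >= 7; 1) ~ 8.3e-5 <= 1e-4 < P(X >= 6; 1) ~ 5.9e-4
  expect_lte(ppois(6, 1, lower.tail = FALSE), 1e-4)
  expect_gt(ppois(5, 1, lower.tail = FALSE), 1e-4)
  # degenerate limit: p = 1 calls every bin
  expect_equal(poisson_threshold(1, 1), 0L)
})

test_that("binarize_tracks applies per-mark thresholds", {
  bins <- genome_bins(c(chr1 = 2000), 200)
  cnt <- matrix(c(0, 1, 6, 7, 8, 20, 0, 3, 5, 2), 10, 2)
  colnames(cnt) <- c("a", "b")
  tr <- mark_track_set(list(D0 = cnt), bins, c("a", "b"), mode = "count")
  bin <- binarize_tracks(tr, background_rate = c(1, 1), p_threshold = 1e-4)
  expect_equal(bin$tracks$D0[, "a"], as.integer(cnt[, "a"] >= 7))
  expect_equal(bin$tracks$D0[, "b"], as.integer(cnt[, "b"] >= 7))
  expect_equal(attr(bin, "binarization")$threshold, c(7L, 7L))

  # all-zero counts give an all-zero binary track
  z <- mark_track_set(list(D0 = matrix(0, 10, 2,
                                       dimnames = list(NULL, c("a", "b")))),
                      bins, c("a", "b"), mode = "count")
  expect_true(all(binarize_tracks(z)$tracks$D0 == 0))

  expect_error(mark_track_set(list(D0 = cnt - 1), bins, c("a", "b"),
                              mode = "count"), "negative")
})

test_that("K = 1 training recovers empirical mark frequencies in closed form", {
  set.seed(4)
  obs <- matrix(rbinom(600, 1, rep(c(0.3, 0.7, 0.5), each = 200)),
                200, 3)
  fit <- hmm_fit(toy_tracks(obs), n_states = 1, n_restarts = 1, seed = 1)
  expect_equal(as.vector(fit$model$emission), colMeans(obs),
               tolerance = 1e-6)
  expect_equal(unname(fit$model$transition), matrix(1, 1, 1))
})

test_that("Baum-Welch recovers a planted 2-state model", {
  truth <- chromatin_state_model(
    emission = rbind(c(0.9, 0.9, 0.1, 0.1), c(0.1, 0.1, 0.9, 0.9)),
    transition = rbind(c(0.95, 0.05), c(0.05, 0.95)),
    initial = c(0.5, 0.5), marks = paste0("m", 1:4))
  bins <- genome_bins(c(chr1 = 6e6), 200)
  withr::local_seed(91)
  path <- integer(bins$n_bins)
  path[1] <- 1
  for (i in 2:bins$n_bins)
    path[i] <- sample.int(2, 1, prob = truth$transition[path[i - 1], ])
  obs <- matrix(rbinom(bins$n_bins * 4, 1, truth$emission[path, ]),
                bins$n_bins, 4)
  fit <- hmm_fit(toy_tracks(obs, bins, truth$marks), n_states = 2,
                 seed = 5, n_restarts = 2)
  perm <- match_states(fit$model, truth)
  expect_lt(max(abs(fit$model$emission[perm, ] - truth$emission)), 0.05)
  expect_lt(max(abs(fit$model$transition[perm, perm] - truth$transition)),
            0.05)
  # EM guarantee: the log-likelihood trace never decreases
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
})

test_that("posterior decoding matches exhaustive path enumeration", {
  withr::local_seed(17)
  model <- chromatin_state_model(
    emission = rbind(c(0.85, 0.2, 0.4), c(0.15, 0.7, 0.6)),
    transition = rbind(c(0.8, 0.2), c(0.3, 0.7)),
    initial = c(0.6, 0.4), marks = paste0("m", 1:3))
  obs <- matrix(rbinom(36, 1, 0.5), 12, 3)
  tracks <- toy_tracks(obs, marks = model$marks)
  post <- state_posterior(model, tracks)$D0
  oracle <- enumerate_posterior(model$emission, model$transition,
                                model$initial, obs)
  expect_lt(max(abs(post - oracle)), 1e-6)
  expect_equal(rowSums(post), rep(1, 12), tolerance = 1e-9)
  # decoded labels are the per-bin posterior argmax
  seg <- decode_states(model, tracks)
  expect_equal(seg$states[, 1], max.col(oracle, ties.method = "first"))
})

test_that("decoding noiseless emissions recovers the true path exactly", {
  cfg <- synthetic_config(n_chromosomes = 2, chromosome_length = 1e6,
                          module_spec = tibble::tibble(archetype = 1,
                                                       n_genes = 0),
                          n_states = 4, seed = 41)
  model <- synthetic_model(4)
  # deterministic emissions: each state shows exactly its signature marks
  model$emission[model$emission > 0.1] <- 1
  model$emission[model$emission <= 0.1] <- 0
  paths <- generate_state_paths(cfg, model)
  tracks <- emit_mark_tracks(paths, model, seed = 42)
  for (method in c("posterior", "viterbi")) {
    seg <- decode_states(model, tracks, method = method)
    expect_equal(seg$states, paths$states)
  }
})

test_that("a fully uninformative model decodes to state 1 by the tie rule", {
  model <- chromatin_state_model(
    emission = matrix(0.5, 3, 2),
    transition = matrix(1 / 3, 3, 3),
    initial = rep(1 / 3, 3), marks = c("a", "b"))
  obs <- matrix(rbinom(40, 1, 0.5), 20, 2)
  seg <- decode_states(model, toy_tracks(obs, marks = model$marks))
  expect_true(all(seg$states == 1L))
})

test_that("state coverage and marked fraction match a counting oracle", {
  bins <- genome_bins(c(chr1 = 4000), 200)
  seg_const <- state_segmentation(matrix(3L, 20, 1,
                                         dimnames = list(NULL, "D0")),
                                  bins, 4)
  cov <- state_coverage(seg_const)
  expect_equal(cov$fraction, c(0, 0, 1, 0))

  seg_half <- state_segmentation(matrix(rep(c(1L, 2L), each = 10), ncol = 1,
                                        dimnames = list(NULL, "D0")),
                                 bins, 2)
  expect_equal(state_coverage(seg_half)$fraction, c(0.5, 0.5))

  seg_rand <- random_segmentation(bins, n_states = 5, n_time = 3, seed = 8)
  cov_rand <- state_coverage(seg_rand, model = synthetic_model(5))
  for (tp in seg_rand$time_points) {
    tally <- vapply(1:5, function(s) sum(seg_rand$states[, tp] == s),
                    numeric(1))
    expect_equal(cov_rand$fraction[cov_rand$time_point == tp],
                 tally / bins$n_bins)
  }
  # the blank state is flagged and excluded from the marked fraction
  expect_true(all(cov_rand$blank == (cov_rand$state == 1)))
  mf <- attr(cov_rand, "marked_fraction")
  expect_equal(mf$marked_fraction,
               1 - cov_rand$fraction[cov_rand$blank],
               tolerance = 1e-12)
})

test_that("segment length statistics match a run-scanning oracle", {
  bins <- genome_bins(c(chr1 = 4000), 200)
  stats_const <- segment_length_stats(
    state_segmentation(matrix(2L, 20, 1, dimnames = list(NULL, "D0")),
                       bins, 2))
  expect_equal(stats_const$n_segments, 1L)
  expect_equal(stats_const$max_bp, 4000)

  alt <- segment_length_stats(
    state_segmentation(matrix(rep(c(1L, 2L), 10), ncol = 1,
                              dimnames = list(NULL, "D0")), bins, 2))
  expect_true(all(alt$min_bp == 200 & alt$max_bp == 200))

  seg <- random_segmentation(bins, n_states = 3, n_time = 1, seed = 5)
  got <- segment_length_stats(seg)
  # oracle: scan the label vector run by run
  v <- seg$states[, 1]
  runs <- list()
  start <- 1
  for (i in seq_along(v)[-1]) {
    if (v[i] != v[i - 1]) {
      runs[[length(runs) + 1]] <- c(v[start], i - start)
      start <- i
    }
  }
  runs[[length(runs) + 1]] <- c(v[start], length(v) - start + 1)
  runs <- do.call(rbind, runs)
  for (s in unique(runs[, 1])) {
    lens <- sort(runs[runs[, 1] == s, 2] * 200)
    row <- got[got$state == paste0("cs", s), ]
    expect_equal(row$n_segments, length(lens))
    expect_equal(row$min_bp, min(lens))
    expect_equal(row$median_bp, unname(quantile(lens, 0.5)))
  }
  expect_true(all(got$min_bp >= 200))
})

test_that("transition summary reports modal successors and row entropy", {
  ident <- chromatin_state_model(matrix(0.5, 3, 2), diag(3), c(1, 0, 0),
                                 marks = c("a", "b"))
  ts <- transition_summary(ident)
  expect_true(all(is.na(ts$top_successor)))
  expect_equal(ts$entropy_bits, rep(0, 3))

  unif <- chromatin_state_model(matrix(0.5, 4, 2), matrix(0.25, 4, 4),
                                rep(0.25, 4), marks = c("a", "b"))
  expect_equal(transition_summary(unif)$entropy_bits, rep(log2(4), 4))

  row <- c(0.7, 0.1, 0.15, 0.05)
  m <- chromatin_state_model(matrix(0.5, 4, 2),
                             rbind(row, row[c(2, 1, 3, 4)],
                                   row[c(3, 2, 1, 4)], row[c(4, 2, 3, 1)]),
                             rep(0.25, 4), marks = c("a", "b"))
  ts3 <- transition_summary(m)
  expect_equal(ts3$entropy_bits[1], -sum(row * log2(row)))
  expect_equal(ts3$top_successor[1], 3L)
  expect_equal(ts3$top_successor_prob[1], 0.15)
})
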