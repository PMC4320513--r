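test_that("changed_bins is the exact label symmetric difference", {
  bins <- genome_bins(c(chr1 = 2e4), 200)
  same <- random_segmentation(bins, 4, n_time = 1, seed = 1)
  seg <- state_segmentation(cbind(t1 = same$states[, 1],
                                  t2 = same$states[, 1]), bins, 4)
  expect_equal(changed_bins(seg, "t1", "t2"), integer(0))

  flipped <- (same$states[, 1] %% 4L) + 1L
  seg2 <- state_segmentation(cbind(t1 = same$states[, 1], t2 = flipped),
                             bins, 4)
  expect_equal(changed_bins(seg2, "t1", "t2"), seq_len(bins$n_bins))

  rand <- random_segmentation(bins, 4, n_time = 2, seed = 2)
  got <- changed_bins(rand, "t1", "t2")
  want <- which(vapply(seq_len(bins$n_bins), function(i) {
    rand$states[i, 1] != rand$states[i, 2]
  }, logical(1)))
  expect_equal(got, want)
  expect_error(changed_bins(rand, "t1", "t9"), "unknown time")
})

test_that("extension window derivation reproduces the quantile-halving rule", {
  # all changed bins inside genes: every distance 0, so W = 0
  bins <- genome_bins(c(chr1 = 1e4), 200)
  states <- cbind(t1 = rep(1L, 50), t2 = rep(1L, 50))
  states[10:20, 2] <- 2L
  seg <- state_segmentation(states, bins, 2)
  genes_all <- tibble::tibble(gene_id = "g1", chrom = "chr1",
                              start = 0, end = 1e4, strand = "+")
  w0 <- derive_extension_window(seg, genes_all)
  expect_equal(w0$W, 0)

  # crafted fixture: per-transition 75th-percentile distance 20,000 bp
  # halves to a 10,000 bp window
  bins2 <- genome_bins(c(chr1 = 2e5), 200)
  # gene start congruent to 100 mod 200 so bin midpoints land at exact
  # distances upstream
  gene <- tibble::tibble(gene_id = "g1", chrom = "chr1",
                         start = 100100, end = 120100, strand = "+")
  # changed-bin midpoints sit at chosen distances upstream of the gene:
  # distances {0, 5000, 10000, 20000, 24000}; quantile(p = .75) = 20000
  dist_want <- c(0, 5000, 10000, 20000, 24000)
  mid_pos <- 100100 - dist_want
  bin_idx <- floor((mid_pos - 100) / 200) + 1
  states2 <- cbind(t1 = rep(1L, bins2$n_bins), t2 = rep(1L, bins2$n_bins))
  states2[bin_idx, 2] <- 2L
  seg2 <- state_segmentation(states2, bins2, 2)
  w <- derive_extension_window(seg2, gene, quantile = 0.75, fraction = 0.5)
  expect_equal(w$per_transition$quantile_distance, 20000)
  expect_equal(w$raw_mean_quantile, 20000)
  expect_equal(w$W, 10000)

  # no dynamics at all is an error directing the caller to supply W
  frozen <- state_segmentation(cbind(t1 = rep(1L, 50), t2 = rep(1L, 50)),
                               bins, 2)
  expect_error(derive_extension_window(frozen, genes_all), "no dynamics")

  # random fixture against the brute-force nearest-gene oracle
  cfg <- synthetic_config(n_chromosomes = 2, chromosome_length = 4e5,
                          module_spec = tibble::tibble(archetype = 1,
                                                       n_genes = 30),
                          seed = 3)
  ann <- generate_genome(cfg)
  seg3 <- random_segmentation(genome_bins(c(chr1 = 4e5, chr2 = 4e5), 200),
                              3, n_time = 3, seed = 4)
  got <- derive_extension_window(seg3, ann)
  qs <- vapply(1:2, function(i) {
    idx <- which(seg3$states[, i] != seg3$states[, i + 1])
    loc <- bin_location(seg3$bins, idx)
    d <- vapply(seq_along(idx), function(j) {
      brute_nearest_gene(loc$chrom[j], loc$start[j] + 100, ann)
    }, numeric(1))
    unname(quantile(d, 0.75))
  }, numeric(1))
  expect_equal(got$raw_mean_quantile, mean(qs))
  expect_equal(got$W, round(0.5 * mean(qs) / 200) * 200)
})

test_that("state attribution equals a brute-force overlap scan", {
  # a gene spanning a single-state region sees only that state
  bins <- genome_bins(c(chr1 = 1e4), 200)
  states <- matrix(rep(c(1L, 2L), c(25, 25)), ncol = 1,
                   dimnames = list(NULL, "D0"))
  seg <- state_segmentation(states, bins, 2)
  gene <- tibble::tibble(gene_id = "g1", chrom = "chr1",
                         start = 600, end = 1800, strand = "+")
  pres <- attribute_states(seg, gene, 0)
  expect_true(pres["g1", "cs1", "D0"])
  expect_false(pres["g1", "cs2", "D0"])

  # half-open boundary contract at the extension edge: a state segment
  # 1 bp inside the window is present, 1 bp outside is absent
  gene2 <- tibble::tibble(gene_id = "g2", chrom = "chr1",
                          start = 2000, end = 2200, strand = "+")
  # state 2 occupies [5000, 10000); window W: region [2000 - W, 2200 + W)
  expect_true(attribute_states(seg, gene2, 2801)["g2", "cs2", "D0"])
  expect_false(attribute_states(seg, gene2, 2600)["g2", "cs2", "D0"])

  expect_error(
    attribute_states(seg, tibble::tibble(gene_id = "gX", chrom = "chrZ",
                                         start = 0, end = 100,
                                         strand = "+"), 0),
    "absent from the segmentation")

  # 200-gene random fixture, exact match with the per-bin oracle
  cfg <- synthetic_config(n_chromosomes = 2, chromosome_length = 1e6,
                          module_spec = tibble::tibble(archetype = 1,
                                                       n_genes = 200),
                          seed = 6)
  ann <- generate_genome(cfg)
  seg2 <- random_segmentation(genome_bins(c(chr1 = 1e6, chr2 = 1e6), 200),
                              5, n_time = 2, seed = 7)
  for (W in c(0, 1000)) {
    got <- attribute_states(seg2, ann, W)
    want <- brute_presence(seg2, ann, W)
    expect_equal(unclass(got), want, ignore_attr = TRUE)
  }
})

test_that("presence grows monotonically with the window", {
  cfg <- synthetic_config(n_chromosomes = 1, chromosome_length = 1e6,
                          module_spec = tibble::tibble(archetype = 1,
                                                       n_genes = 50),
                          seed = 8)
  ann <- generate_genome(cfg)
  seg <- random_segmentation(genome_bins(c(chr1 = 1e6), 200), 6,
                             n_time = 2, seed = 9)
  prev <- attribute_states(seg, ann, 0)
  for (W in c(400, 2000, 10000)) {
    cur <- attribute_states(seg, ann, W)
    expect_true(all(cur[prev] == TRUE))
    prev <- cur
  }
})

test_that("gene ratios count module genes carrying each state", {
  bins <- genome_bins(c(chr1 = 1e5), 200)
  seg <- random_segmentation(bins, 4, n_time = 2, seed = 10)
  cfg <- synthetic_config(n_chromosomes = 1, chromosome_length = 1e5,
                          module_spec = tibble::tibble(archetype = 1,
                                                       n_genes = 20),
                          seed = 11)
  ann <- generate_genome(cfg)
  pres <- attribute_states(seg, ann, 400)
  mods <- tibble::tibble(gene_id = ann$gene_id,
                         module = rep(1:2, each = 10))
  rat <- gene_ratios(pres, mods)
  expect_true(all(rat$ratio >= 0 & rat$ratio <= 1))
  # ratio times module size is an integer gene count
  expect_equal(rat$ratio * rat$module_size, rat$n_with_state)
  # brute-force counting oracle
  for (r in sample(nrow(rat), 10)) {
    row <- rat[r, ]
    genes_in <- mods$gene_id[mods$module == row$module]
    cnt <- sum(pres[genes_in, paste0("cs", row$state), row$time_point])
    expect_equal(row$n_with_state, cnt)
    expect_equal(row$ratio, cnt / length(genes_in))
  }
  # degenerate extremes: all genes carry the state / none do
  all_one <- pres
  all_one[, 1, ] <- TRUE
  all_one[, 2, ] <- FALSE
  rat2 <- gene_ratios(all_one, mods)
  expect_true(all(rat2$ratio[rat2$state == 1] == 1))
  expect_true(all(rat2$ratio[rat2$state == 2] == 0))
  # ratios are invariant under module relabeling
  mods_flip <- dplyr::mutate(mods, module = 3L - module)
  rat3 <- gene_ratios(pres, mods_flip)
  expect_equal(rat3$ratio[rat3$module == 2], rat$ratio[rat$module == 1])

  expect_error(gene_ratios(pres, mods[-1, ]), "without module")
})

test_that("state counts per gene are presence row sums", {
  bins <- genome_bins(c(chr1 = 1e5), 200)
  seg <- random_segmentation(bins, 5, n_time = 2, seed = 12)
  ann <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                        start = c(0, 5e4), end = c(4e4, 9e4),
                        strand = c("+", "-"))
  pres <- attribute_states(seg, ann, 0)
  cnt <- state_count_per_gene(pres)
  for (i in seq_len(nrow(cnt))) {
    expect_equal(cnt$n_states[i],
                 sum(pres[cnt$gene_id[i], , cnt$time_point[i]]))
  }
  expect_true(all(cnt$n_states >= 1 & cnt$n_states <= 5))

  # a blank-only gene counts 1 by default and 0 with the blank excluded
  blank_pres <- pres
  blank_pres[1, , ] <- FALSE
  blank_pres[1, 1, ] <- TRUE
  c_def <- state_count_per_gene(blank_pres)
  expect_equal(c_def$n_states[c_def$gene_id == "g1"], c(1L, 1L))
  c_ex <- state_count_per_gene(blank_pres, exclude_blank = TRUE)
  expect_equal(c_ex$n_states[c_ex$gene_id == "g1"], c(0L, 0L))
})
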