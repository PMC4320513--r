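#' Generate a synthetic gene annotation
#'
#' Places non-overlapping genes on the configured chromosomes. Gene
#' lengths are drawn from a log-normal distribution (meanlog `log(3000)`,
#' sdlog 0.6, giving a median of 3 kb); genes are distributed evenly over
#' chromosomes and laid out with Dirichlet-distributed intergenic gaps
#' (uniform stick-breaking of the free space), which guarantees a
#' non-overlapping arrangement whenever the genes fit on the chromosome.
#' Output is deterministic for a fixed seed.
#'
#' @param config A [synthetic_config()].
#' @param seed Seed; defaults to the config seed.
#' @return Tibble with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, sorted by (chrom, start).
#' @export
generate_genome <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  n <- config$n_genes
  if (n == 0)
    return(tibble::tibble(gene_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          strand = character()))
  local_seed(seed, {
    # genes per chromosome, proportional to length (equal lengths here,
    # so as even a split as possible, deterministic)
    per_chrom <- diff(round(seq(0, n, length.out = config$n_chromosomes + 1)))
    lens <- pmax(round(rlnorm(n, meanlog = log(3000), sdlog = 0.6)), 200)
    out <- vector("list", config$n_chromosomes)
    gi <- 0L
    for (ci in seq_along(chroms)) {
      nc <- per_chrom[ci]
      if (nc == 0) next
      clens <- lens[gi + seq_len(nc)]
      gi <- gi + nc
      free <- config$chromosome_length - sum(clens)
      if (free < 0)
        stop("cannot place ", nc, " genes of total length ", sum(clens),
             " on a ", config$chromosome_length, " bp chromosome (",
             chroms[ci], "); reduce n_genes or enlarge chromosome_length")
      # Dirichlet-distributed intergenic gaps: uniform stick-breaking of
      # the free space into nc + 1 segments; overlap-free by construction
      g <- -log(runif(nc + 1))
      bounds <- floor(free * cumsum(g) / sum(g))
      starts <- head(bounds, -1) + cumsum(c(0, head(clens, -1)))
      out[[ci]] <- tibble::tibble(chrom = chroms[ci], start = starts,
                                  end = starts + clens)
    }
    genes <- dplyr::bind_rows(out) |>
      dplyr::arrange(.data$chrom, .data$start) |>
      dplyr::mutate(gene_id = sprintf("g%05d", dplyr::row_number()),
                    strand = sample(c("+", "-"), dplyr::n(), replace = TRUE)) |>
      dplyr::select("gene_id", "chrom", "start", "end", "strand")
    genes
  })
}

#' Sample per-time-point chromatin-state paths
#'
#' The backbone of the first time point is sampled from the model's
#' Markov chain (the chain restarts at each chromosome), after which
#' `n_burnin` flux-balanced scramble passes at the per-state mean flip
#' rates equilibrate the remodelling texture, so the first observed time
#' point already carries the steady-state mixture of chromatin domains
#' and scattered remodelled bins (without burn-in, the first transition
#' is dominated by a transient scattering artefact that inflates every
#' state's gene ratio). Each later time point derives from the previous
#' one by per-bin resampling: a bin in state `s` flips with probability
#' `dynamics_coupling[s, transition]`, and a flipped bin adopts a
#' different state drawn with probability proportional to destination
#' occupancy times destination flip propensity - the flux-balancing
#' kernel under which every state's expected occupancy is constant, so
#' nothing drifts under equal flip probabilities. States listed in
#' `flip_sink_exclude` (default the planted hyper-dynamic state) are
#' excluded as destinations during the observed transitions: they
#' resolve without being re-established, as bivalent chromatin does
#' during differentiation, and so lose occupancy at a rate set by their
#' flip probability. The fraction of changed bins per state equals the
#' configured flip probability up to binomial error.
#'
#' @param config A [synthetic_config()].
#' @param model The generating [chromatin_state_model()]; defaults to
#'   [synthetic_model()] at the configured K.
#' @param seed Seed; defaults to the config seed plus 1.
#' @param n_burnin Number of equilibration scramble passes applied to
#'   the first time point (default 2; a no-op when all flip rates are
#'   zero).
#' @return A [state_segmentation()] with one column per time point.
#' @export
generate_state_paths <- function(config, model = NULL,
                                 seed = config$seed + 1, n_burnin = 2) {
  stopifnot(inherits(config, "synthetic_config"))
  model <- model %||% synthetic_model(config$n_states, config$marks)
  if (model$K != config$n_states)
    stop("model K does not match config n_states")
  if (any(abs(rowSums(model$transition) - 1) > 1e-9))
    stop("transition rows must sum to 1")
  bins <- genome_bins(
    setNames(rep(config$chromosome_length, config$n_chromosomes),
             paste0("chr", seq_len(config$n_chromosomes))),
    config$bin_width)
  K <- model$K
  flips <- config$dynamics_coupling
  base_flip <- rowMeans(flips)
  sink_excl <- config$flip_sink_exclude %||% integer(0)
  n_time <- length(config$time_points)
  local_seed(seed, {
    first <- unlist(lapply(bins$n_bins_chrom, function(nb) {
      sample_markov_chain(nb, model$transition, model$initial)
    }), use.names = FALSE)
    for (b in seq_len(n_burnin))
      first <- resample_pass(first, base_flip, base_flip, K, integer(0))
    states <- matrix(0L, bins$n_bins, n_time,
                     dimnames = list(NULL, config$time_points))
    states[, 1] <- first
    for (tr in seq_len(n_time - 1)) {
      states[, tr + 1] <- resample_pass(states[, tr], flips[, tr],
                                        base_flip, K, sink_excl)
    }
    state_segmentation(states, bins, K)
  })
}

# One per-bin resampling pass with per-state flip rates. Ordinary churn
# (flips out of non-sink states) redistributes with weight occupancy x
# flip propensity, the flux-balancing kernel; flips out of sink-excluded
# (resolving) states redistribute by occupancy alone, so their lost
# territory is shared by all remaining states in proportion to genome
# composition. Destinations never include the current state or a sink
# state.
resample_pass <- function(cur, rates, base_flip, K, sink_excl) {
  nxt <- cur
  flip <- runif(length(cur)) < rates[cur]
  occ <- tabulate(cur, nbins = K) / length(cur)
  for (s in seq_len(K)) {
    idx <- which(flip & cur == s)
    if (!length(idx)) next
    w <- if (s %in% sink_excl) occ else occ * base_flip
    w[c(s, sink_excl)] <- 0
    if (sum(w) <= 0) w <- replace(rep(1, K), unique(c(s, sink_excl)), 0)
    if (sum(w) <= 0) w <- replace(rep(1, K), s, 0)
    nxt[idx] <- sample.int(K, length(idx), replace = TRUE, prob = w)
  }
  nxt
}

sample_markov_chain <- function(n, transition, initial) {
  K <- nrow(transition)
  cum <- t(apply(transition, 1, cumsum))
  u <- runif(n)
  path <- integer(n)
  path[1] <- findInterval(u[1], cumsum(initial)) + 1L
  for (i in seq_len(n - 1L) + 1L)
    path[i] <- findInterval(u[i], cum[path[i - 1L], ]) + 1L
  path
}

#' Emit mark tracks from state paths
#'
#' Samples, independently per bin and mark, the binary presence of each
#' mark given the bin's state (Bernoulli with the model's emission
#' probability). In count mode a Poisson count layer is added on top:
#' `Poisson(lambda_high)` where the mark is present and
#' `Poisson(lambda_low)` background elsewhere, for exercising the
#' binarization step.
#'
#' @param paths A [state_segmentation()] of true per-bin states.
#' @param model The generating [chromatin_state_model()].
#' @param mode `"binary"` (default) or `"count"`.
#' @param lambda_low,lambda_high Poisson background and signal rates for
#'   count mode (defaults 1 and 8).
#' @param seed Integer seed.
#' @return A [mark_track_set()] in the requested mode.
#' @export
emit_mark_tracks <- function(paths, model, mode = c("binary", "count"),
                             lambda_low = 1, lambda_high = 8, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(paths, "state_segmentation"),
            inherits(model, "chromatin_state_model"),
            paths$n_states == model$K, lambda_low > 0, lambda_high > 0)
  M <- length(model$marks)
  n <- paths$bins$n_bins
  local_seed(seed, {
    tracks <- lapply(paths$time_points, function(tp) {
      p <- model$emission[paths$states[, tp], , drop = FALSE]
      present <- matrix(rbinom(n * M, 1L, p), n, M,
                        dimnames = list(NULL, model$marks))
      if (mode == "binary") return(present)
      counts <- matrix(rpois(n * M, ifelse(present == 1L,
                                           lambda_high, lambda_low)),
                       n, M, dimnames = list(NULL, model$marks))
      counts
    })
    names(tracks) <- paths$time_points
    mark_track_set(tracks, paths$bins, model$marks, mode = mode)
  })
}

#' Generate a synthetic expression table
#'
#' Assigns each gene to an archetype according to the configured module
#' spec (assignment order randomised over genes) and produces FPKM values
#' from the archetype template scaled by the module's `scale` factor with
#' multiplicative log-normal noise of the configured SD. Template zeros
#' stay exactly zero, so genes induced at a time point have zero FPKM
#' before it (and symmetrically for repressed genes).
#'
#' @param config A [synthetic_config()].
#' @param gene_ids Gene identifiers; default matches [generate_genome()].
#' @param seed Seed; defaults to the config seed plus 2.
#' @return List with `expression` (tibble: gene_id plus one FPKM column
#'   per time point) and `modules` (tibble: gene_id, module, archetype,
#'   class).
#' @export
generate_expression <- function(config,
                                gene_ids = sprintf("g%05d",
                                                   seq_len(config$n_genes)),
                                seed = config$seed + 2) {
  stopifnot(inherits(config, "synthetic_config"),
            length(gene_ids) == config$n_genes)
  arch <- expression_archetypes()
  spec <- config$module_spec
  tps <- config$time_points
  if (!all(tps %in% names(arch)))
    stop("archetype table lacks columns for time points: ",
         paste(setdiff(tps, names(arch)), collapse = ", "))
  local_seed(seed, {
    order_ids <- sample(gene_ids)
    assign_arch <- rep(spec$archetype, spec$n_genes)
    assign_scale <- rep(spec$scale, spec$n_genes)
    template <- as.matrix(arch[match(assign_arch, arch$archetype), tps])
    noise <- matrix(rlnorm(length(order_ids) * length(tps),
                           meanlog = 0, sdlog = config$noise_sd),
                    length(order_ids), length(tps))
    fpkm <- template * assign_scale * noise
    expr <- tibble::as_tibble(as.data.frame(fpkm, check.names = FALSE))
    names(expr) <- tps
    expr <- dplyr::bind_cols(tibble::tibble(gene_id = order_ids), expr) |>
      dplyr::arrange(.data$gene_id)
    modules <- tibble::tibble(
      gene_id = order_ids,
      module = match(assign_arch, spec$archetype),
      archetype = assign_arch,
      class = arch$class[match(assign_arch, arch$archetype)]) |>
      dplyr::arrange(.data$gene_id)
    list(expression = expr, modules = modules)
  })
}

#' Simulate a complete synthetic experiment
#'
#' Orchestrates the full generator: planted model, gene annotation,
#' per-time-point state paths, mark tracks and expression table, all
#' from one seed. When `couple_expression` is set in the config, gene
#' bodies are overwritten (identically at every time point) with a
#' mixture of blank and non-blank states whose non-blank probability
#' increases with the gene's expression rank, planting a positive
#' relationship between expression level and chromatin-state complexity.
#'
#' @param config A [synthetic_config()].
#' @param track_mode `"binary"` or `"count"` mark tracks.
#' @return List of class `synthetic_experiment`: `config`, `model`,
#'   `annotation`, `paths` (true segmentation), `tracks`, `expression`,
#'   `modules`, and planted-truth metadata (`dynamic_state`,
#'   `stable_state`, `blank_state`).
#' @export
simulate_experiment <- function(config, track_mode = c("binary", "count")) {
  track_mode <- match.arg(track_mode)
  stopifnot(inherits(config, "synthetic_config"))
  model <- synthetic_model(config$n_states, config$marks)
  annotation <- generate_genome(config)
  paths <- generate_state_paths(config, model)
  exprs <- generate_expression(config)
  if (config$couple_expression)
    paths <- couple_states_to_expression(paths, annotation,
                                         exprs$expression, config)
  tracks <- emit_mark_tracks(paths, model, mode = track_mode,
                             seed = config$seed + 3)
  structure(
    list(config = config, model = model, annotation = annotation,
         paths = paths, tracks = tracks,
         expression = exprs$expression, modules = exprs$modules,
         dynamic_state = config$planted_dynamic_state,
         stable_state = config$planted_stable_state,
         blank_state = config$blank_state),
    class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat("<synthetic_experiment> ", nrow(x$annotation), " genes, ",
      x$paths$bins$n_bins, " bins, ", x$config$n_states, " states, ",
      length(x$config$time_points), " time points\n", sep = "")
  invisible(x)
}

# overwrite gene-body bins so that the expected number of distinct states
# in a gene region grows with expression rank
couple_states_to_expression <- function(paths, annotation, expression,
                                        config) {
  tps <- config$time_points
  level <- rowMeans(log1p(as.matrix(expression[, tps])))
  pr <- 0.05 + 0.9 * (rank(level, ties.method = "first") - 1) /
    max(length(level) - 1, 1)
  names(pr) <- expression$gene_id
  states <- paths$states
  K <- paths$n_states
  local_seed(config$seed + 4, {
    for (i in seq_len(nrow(annotation))) {
      g <- annotation[i, ]
      lo <- bin_index(paths$bins, g$chrom, g$start)
      hi <- bin_index(paths$bins, g$chrom, g$end - 1)
      if (is.na(lo)) next
      if (is.na(hi)) hi <- paths$bins$offsets[g$chrom] +
          paths$bins$n_bins_chrom[g$chrom]
      idx <- lo:hi
      p <- pr[g$gene_id]
      rich <- runif(length(idx)) < p
      new_states <- ifelse(rich,
                           sample(2:K, length(idx), replace = TRUE),
                           config$blank_state)
      for (tp in tps) states[idx, tp] <- new_states
    }
  })
  state_segmentation(states, paths$bins, K)
}
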