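#' Temporal expression archetypes
#'
#' The 19 named expression-profile templates used by the synthetic-data
#' generator, shipped as a plain-text table: four stable profiles (two
#' low, two high), three sequentially induced from zero FPKM at D0, D3 or
#' D9, one expressed-and-up-regulated, three sequentially repressed to
#' zero, and eight transient or oscillatory single-pulse shapes. Template
#' FPKM levels are free parameters of the generator chosen so that strong
#' profiles exceed weak ones by at least 10-fold and all pairs of
#' templates are well separated in log space.
#'
#' @return Tibble with columns `archetype`, `class` and one FPKM column
#'   per time point.
#' @examples
#' expression_archetypes()
#' @export
expression_archetypes <- function() {
  path <- system.file("extdata", "archetypes.tsv", package = "chromdyn",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Configuration for the synthetic experiment generator
#'
#' Bundles every tunable of the synthetic genome, chromatin and
#' expression generator. Defaults emulate the study design the pipeline
#' targets: 7 marks, 4 time points, 200 bp bins, a blank-dominated
#' chromatin-state model with one hyper-dynamic "bivalent-promoter-like"
#' state and one near-frozen "gene-body-enhancer-like" state, and genes
#' drawn from the 19 expression archetypes.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Length of each chromosome in bases
#'   (`bin_width` must divide it).
#' @param bin_width Bin width in bases (default 200).
#' @param n_states Number of chromatin states K (2..8 for the built-in
#'   planted model).
#' @param marks Mark names (default the 7 profiled marks).
#' @param time_points Ordered time-point labels (default D-2, D0, D3, D9).
#' @param module_spec Tibble with columns `archetype`, `n_genes` and
#'   optionally `scale` (multiplier on the template FPKM); defaults to 50
#'   genes per archetype.
#' @param dynamics_coupling Per-state flip probabilities for the temporal
#'   resampling of state paths: a length-K vector, or a K x (T-1) matrix
#'   for per-transition control. Default: 0.1 everywhere except the
#'   planted dynamic state (0.4) and the planted stable state (0.01),
#'   scaled per transition by `c(0.5, 1, 0.15)` so chromatin remodelling
#'   peaks just after adipogenic induction and subsides as the
#'   differentiation programme stabilises.
#' @param flip_sink_exclude States excluded as flip destinations during
#'   the observed transitions (default the planted dynamic state, which
#'   resolves without re-establishment); set `integer(0)` for a fully
#'   flux-balanced null in which no state drifts.
#' @param couple_expression If `TRUE`, chromatin complexity in gene bodies
#'   is made to increase with expression level (to exercise the
#'   expression-complexity regression); default `FALSE`, chromatin and
#'   expression independent.
#' @param noise_sd SD of the multiplicative log-normal FPKM noise
#'   (natural-log scale), default 0.1.
#' @param seed Integer seed; all generator randomness derives from it.
#'
#' @return An object of class `synthetic_config`.
#' @seealso [simulate_experiment()]
#' @export
synthetic_config <- function(n_chromosomes = 2,
                             chromosome_length = 5e6,
                             bin_width = 200,
                             n_states = 8,
                             marks = DEFAULT_MARKS,
                             time_points = DEFAULT_TIME_POINTS,
                             module_spec = NULL,
                             dynamics_coupling = NULL,
                             flip_sink_exclude = NULL,
                             couple_expression = FALSE,
                             noise_sd = 0.1,
                             seed = 1) {
  stopifnot(n_chromosomes >= 1, chromosome_length >= bin_width,
            bin_width >= 1, n_states >= 2, n_states <= 8,
            length(time_points) >= 2, noise_sd >= 0)
  if (chromosome_length %% bin_width != 0)
    stop("bin_width must divide chromosome_length")
  arch <- expression_archetypes()
  if (is.null(module_spec))
    module_spec <- tibble::tibble(archetype = arch$archetype, n_genes = 50)
  if (!"scale" %in% names(module_spec)) module_spec$scale <- 1
  if (!all(module_spec$archetype %in% arch$archetype))
    stop("unknown archetype id(s): ",
         paste(setdiff(module_spec$archetype, arch$archetype), collapse = ", "))
  n_trans <- length(time_points) - 1
  dyn_state <- 2L     # bivalent-promoter-like
  stable_state <- 3L  # gene-body-enhancer-like
  if (is.null(dynamics_coupling)) {
    base <- rep(0.1, n_states)
    base[dyn_state] <- 0.4
    base[stable_state] <- 0.01
    dynamics_coupling <- outer(base, c(0.5, 1, 0.15)[seq_len(n_trans)])
  }
  if (is.vector(dynamics_coupling))
    dynamics_coupling <- matrix(dynamics_coupling, n_states, n_trans)
  stopifnot(nrow(dynamics_coupling) == n_states,
            ncol(dynamics_coupling) == n_trans,
            all(dynamics_coupling >= 0), all(dynamics_coupling <= 1))
  structure(
    list(n_chromosomes = n_chromosomes,
         chromosome_length = chromosome_length,
         bin_width = bin_width,
         n_states = as.integer(n_states),
         marks = marks,
         time_points = time_points,
         module_spec = module_spec,
         n_genes = sum(module_spec$n_genes),
         dynamics_coupling = dynamics_coupling,
         flip_sink_exclude = flip_sink_exclude %||% dyn_state,
         planted_dynamic_state = dyn_state,
         planted_stable_state = stable_state,
         blank_state = 1L,
         couple_expression = couple_expression,
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config> ", x$n_chromosomes, " x ",
      format(x$chromosome_length, big.mark = ","), " bp, ",
      x$n_states, " states, ", length(x$marks), " marks, ",
      x$n_genes, " genes in ", nrow(x$module_spec),
      " modules, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Planted chromatin-state model
#'
#' Builds the ground-truth [chromatin_state_model()] the synthetic
#' generator samples from. State 1 is a blank state (near-zero emission of
#' every mark) occupying the largest genome share; state 2 is a
#' bivalent-promoter-like state (H3K27me3 + H3K4me2), the planted
#' hyper-dynamic state; state 3 is a gene-body-enhancer-like state
#' (H3K4me1 + H3K36me3), the planted stable state; the remaining states
#' are repressive-domain, active-promoter, active-enhancer, weak-enhancer
#' and transcribed-body patterns. Transitions are diagonal-dominant
#' (self-probability `self_transition`) with a slight preference for
#' returning to blank, mirroring segmental chromatin organisation.
#'
#' @param n_states K in 2..8; the first K rows of the built-in pattern
#'   set are used.
#' @param marks Mark names; emission patterns are defined on the default
#'   7-mark panel.
#' @param self_transition Self-transition probability (default 0.95).
#' @return A [chromatin_state_model()].
#' @export
synthetic_model <- function(n_states = 8, marks = DEFAULT_MARKS,
                            self_transition = 0.95) {
  stopifnot(n_states >= 2, n_states <= 8,
            length(marks) == length(DEFAULT_MARKS))
  lo <- 0.02
  #            K27me3 K27ac K4me1 K4me2 K4me3 K36me3 CTCF
  patterns <- rbind(
    blank             = c(lo, lo, lo, lo, lo, lo, lo),
    bivalent_promoter = c(0.70, lo, lo, 0.75, 0.30, lo, lo),
    gene_body_enhancer = c(lo, lo, 0.70, lo, lo, 0.80, lo),
    repressive_domain = c(0.80, lo, lo, lo, lo, lo, 0.10),
    active_promoter   = c(lo, 0.60, lo, 0.70, 0.85, lo, 0.20),
    active_enhancer   = c(lo, 0.70, 0.80, 0.30, lo, lo, lo),
    weak_enhancer     = c(lo, lo, 0.75, lo, lo, lo, lo),
    transcribed_body  = c(lo, lo, lo, lo, lo, 0.85, lo))
  emission <- patterns[seq_len(n_states), , drop = FALSE]
  colnames(emission) <- marks
  K <- n_states
  transition <- matrix((1 - self_transition - 0.02) / max(K - 2, 1), K, K)
  transition[, 1] <- 0.02 + (1 - self_transition - 0.02) / max(K - 2, 1)
  diag(transition) <- 0
  transition <- transition / rowSums(transition) * (1 - self_transition)
  diag(transition) <- self_transition
  initial <- c(0.4, rep(0.6 / (K - 1), K - 1))
  chromatin_state_model(emission, transition, initial, marks = marks,
                        state_labels = rownames(patterns)[seq_len(K)])
}
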