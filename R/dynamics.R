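#' Temporal chromatin-state change tests
#'
#' For each module, state and adjacent time-point transition, computes
#' the gene-ratio difference `delta = ratio(t+1) - ratio(t)` and tests it
#' against the module's overall difference in ratios: the sample is the
#' set of deltas of all non-excluded states in the module at that
#' transition, and a two-sided one-sample t-test asks whether the
#' tested state's delta is consistent with that sample's mean (a
#' per-state outlier test across the module's states). Raw P-values are
#' Bonferroni-adjusted within the chosen family.
#'
#' With a zero-variance sample the degenerate contract applies: P = 1
#' when the tested delta equals the common value and P = 0 otherwise.
#'
#' The reverse orientation (`orientation = "sample_vs_zero"`) instead
#' tests the state's delta sample against mean zero per state across
#' modules; the default matches the per-state outlier reading.
#'
#' @param ratios Gene-ratio tibble from [gene_ratios()].
#' @param exclude_states States excluded from both sample and tested set
#'   (default the blank state, 1); use `integer(0)` to test all.
#' @param alpha Significance level applied to adjusted P (default 0.05).
#' @param family Bonferroni family: `"module"` (all state x transition
#'   tests within a module, default) or `"global"` (all tests).
#' @param orientation `"state_vs_module"` (default) or
#'   `"sample_vs_zero"`.
#' @return Tibble with `module`, `state`, `transition`, `delta`,
#'   `p_value`, `p_adjusted`, `significant`; the family size is attached
#'   as attribute `"family_size"`.
#' @export
temporal_change_tests <- function(ratios, exclude_states = 1L,
                                  alpha = 0.05,
                                  family = c("module", "global"),
                                  orientation = c("state_vs_module",
                                                  "sample_vs_zero")) {
  family <- match.arg(family)
  orientation <- match.arg(orientation)
  tps <- unique(ratios$time_point)
  n_trans <- length(tps) - 1
  deltas <- ratios |>
    dplyr::filter(!.data$state %in% exclude_states) |>
    dplyr::mutate(tp_i = match(.data$time_point, tps)) |>
    dplyr::arrange(.data$module, .data$state, .data$tp_i) |>
    dplyr::group_by(.data$module, .data$state) |>
    dplyr::reframe(transition = paste0(tps[seq_len(n_trans)], "/",
                                       tps[seq_len(n_trans) + 1]),
                   delta = diff(.data$ratio))
  out <- deltas |>
    dplyr::group_by(.data$module, .data$transition) |>
    dplyr::mutate(p_value = vapply(seq_along(delta), function(i) {
      one_sample_delta_test(delta, delta[i])
    }, numeric(1))) |>
    dplyr::ungroup()
  if (orientation == "sample_vs_zero") {
    # reverse reading: each state's deltas across modules form the
    # sample, tested against the transition-wide mean delta
    out <- deltas |>
      dplyr::group_by(.data$transition) |>
      dplyr::mutate(overall = mean(.data$delta)) |>
      dplyr::group_by(.data$state, .data$transition) |>
      dplyr::mutate(p_value = one_sample_delta_test(delta, overall[1])) |>
      dplyr::ungroup() |>
      dplyr::select(-"overall")
  }
  if (family == "module") {
    out <- out |>
      dplyr::group_by(.data$module) |>
      dplyr::mutate(p_adjusted = pmin(1, .data$p_value * dplyr::n())) |>
      dplyr::ungroup()
    n_fam <- dplyr::count(out, .data$module)$n
  } else {
    out <- dplyr::mutate(out,
                         p_adjusted = pmin(1, .data$p_value * dplyr::n()))
    n_fam <- nrow(out)
  }
  out <- out |>
    dplyr::select("module", "state", "transition", "delta",
                  "p_value", "p_adjusted") |>
    dplyr::mutate(significant = .data$p_adjusted < alpha)
  attr(out, "family_size") <- n_fam
  attr(out, "alpha") <- alpha
  out
}

# two-sided one-sample t-test of `sample` against null mean `mu`, with
# the degenerate zero-variance contract
one_sample_delta_test <- function(sample, mu) {
  if (length(sample) < 3)
    stop("need at least 3 states in the difference sample")
  if (sd(sample) == 0)
    return(if (isTRUE(all.equal(sample[1], mu))) 1 else 0)
  t.test(sample, mu = mu)$p.value
}

#' Count significant chromatin-state changes at a transition
#'
#' Tally of significant flags across all modules and states for one
#' transition, the all-clusters-confounded summary of temporal
#' remodelling.
#'
#' @param table Output of [temporal_change_tests()].
#' @param transition Transition label, e.g. `"D0/D3"`; all transitions
#'   when `NULL`.
#' @return Tibble with `transition` and `n_significant`.
#' @export
count_significant_changes <- function(table, transition = NULL) {
  wanted <- transition
  tab <- if (is.null(wanted)) table else
    dplyr::filter(table, .data$transition %in% wanted)
  tab |>
    dplyr::group_by(.data$transition) |>
    dplyr::summarise(n_significant = sum(.data$significant),
                     .groups = "drop")
}

#' Pairwise module enrichment comparison matrix
#'
#' Compares global chromatin-state enrichment between expression modules:
#' each module's sample is its gene ratios over all non-excluded states
#' and all time points, and module pairs are compared by a two-sample
#' two-sided Wilcoxon rank-sum test (exact for small untied samples),
#' Bonferroni-corrected over the number of pairs. The direction reports
#' which module has the larger mean ratio.
#'
#' @param ratios Gene-ratio tibble from [gene_ratios()].
#' @param exclude_states States excluded from the samples (default
#'   blank, 1).
#' @return Tibble with `module_a`, `module_b` (a < b), `p_value`,
#'   `p_adjusted`, `direction` (`"a>b"`, `"b>a"` or `"none"`); family
#'   size as attribute.
#' @export
cluster_enrichment_matrix <- function(ratios, exclude_states = 1L) {
  samples <- ratios |>
    dplyr::filter(!.data$state %in% exclude_states) |>
    dplyr::group_by(.data$module) |>
    dplyr::summarise(sample = list(.data$ratio), .groups = "drop")
  if (nrow(samples) < 2) stop("need at least 2 modules")
  pairs <- utils::combn(samples$module, 2)
  n_pairs <- ncol(pairs)
  out <- purrr::map_dfr(seq_len(n_pairs), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    xa <- samples$sample[[match(a, samples$module)]]
    xb <- samples$sample[[match(b, samples$module)]]
    p <- if (identical(xa, xb)) 1 else
      suppressWarnings(wilcox.test(xa, xb)$p.value)
    tibble::tibble(
      module_a = a, module_b = b, p_value = p,
      direction = if (mean(xa) > mean(xb)) "a>b"
                  else if (mean(xb) > mean(xa)) "b>a" else "none")
  }) |>
    dplyr::mutate(p_adjusted = pmin(1, .data$p_value * n_pairs)) |>
    dplyr::select("module_a", "module_b", "p_value", "p_adjusted",
                  "direction")
  attr(out, "family_size") <- n_pairs
  out
}

#' Dynamics scores from temporal-change P-values
#'
#' Summarises temporal chromatin remodelling per expression module or
#' per state as `-log10` of the sum of the group's raw (unadjusted)
#' P-values. Low P-values (frequent significant changes) give high
#' scores; scores can be negative when the summed P exceeds 1 and are
#' deliberately not clamped.
#'
#' @param table Output of [temporal_change_tests()].
#' @param group_by `"module"` or `"state"`.
#' @return Tibble with the grouping column, `n_tests`, `p_sum`, `score`.
#' @export
dynamics_score <- function(table, group_by = c("module", "state")) {
  group_by <- match.arg(group_by)
  if (any(table$p_value == 0))
    stop("zero P-value(s) in the table (numerical underflow); ",
         "apply a minimum-P floor before scoring")
  table |>
    dplyr::group_by(.data[[group_by]]) |>
    dplyr::summarise(n_tests = dplyr::n(),
                     p_sum = sum(.data$p_value),
                     score = -log10(.data$p_sum),
                     .groups = "drop")
}

#' Pairwise dynamics comparison matrix
#'
#' Tests whether one group (module or state) shows greater chromatin
#' dynamics than another: a one-sided Wilcoxon rank-sum test on the two
#' groups' raw temporal-change P-value sets, with the alternative that
#' group `a`'s P-values are smaller (i.e. `a` is more dynamic).
#' Bonferroni correction is over the number of ordered pairs tested.
#' Groups pool P-values across the other dimension and transitions by
#' default; `aggregate = "module_mean"` first averages P-values within
#' each module (relevant when grouping by state).
#'
#' @param table Output of [temporal_change_tests()].
#' @param group_by `"module"` or `"state"`.
#' @param aggregate `"pool"` (default) or `"module_mean"`.
#' @return Tibble with `group_a`, `group_b`, `p_value` (alternative: a
#'   more dynamic than b), `p_adjusted`; family size as attribute.
#' @export
dynamics_comparison_matrix <- function(table,
                                       group_by = c("module", "state"),
                                       aggregate = c("pool",
                                                     "module_mean")) {
  group_by <- match.arg(group_by)
  aggregate <- match.arg(aggregate)
  tab <- table
  if (aggregate == "module_mean" && group_by == "state") {
    tab <- tab |>
      dplyr::group_by(.data$state, .data$module) |>
      dplyr::summarise(p_value = mean(.data$p_value), .groups = "drop")
  }
  groups <- tab |>
    dplyr::group_by(.data[[group_by]]) |>
    dplyr::summarise(sample = list(.data$p_value), .groups = "drop")
  ids <- groups[[group_by]]
  if (any(lengths(groups$sample) < 2))
    stop("each group needs at least 2 P-values")
  grid <- expand.grid(a = ids, b = ids)
  grid <- grid[grid$a != grid$b, ]
  n_fam <- nrow(grid)
  out <- purrr::map_dfr(seq_len(nrow(grid)), function(j) {
    xa <- groups$sample[[match(grid$a[j], ids)]]
    xb <- groups$sample[[match(grid$b[j], ids)]]
    p <- suppressWarnings(
      wilcox.test(xa, xb, alternative = "less")$p.value)
    tibble::tibble(group_a = grid$a[j], group_b = grid$b[j], p_value = p)
  }) |>
    dplyr::mutate(p_adjusted = pmin(1, .data$p_value * n_fam))
  attr(out, "family_size") <- n_fam
  out
}

#' Regression of chromatin complexity on expression level
#'
#' Pearson correlation and least-squares line of the number of distinct
#' chromatin states in a gene's extended region against the gene's
#' log(FPKM + 1), paired over all gene x time-point observations.
#'
#' @param expr Expression tibble.
#' @param state_counts Output of [state_count_per_gene()].
#' @return One-row tibble: `r`, `slope`, `intercept`, `n_obs`.
#' @export
expression_state_regression <- function(expr, state_counts) {
  long <- expr |>
    tidyr::pivot_longer(-"gene_id", names_to = "time_point",
                        values_to = "fpkm") |>
    dplyr::inner_join(state_counts, by = c("gene_id", "time_point"))
  if (nrow(long) < 3) stop("need at least 3 paired observations")
  x <- log1p(long$fpkm)
  y <- long$n_states
  if (var(x) == 0 || var(y) == 0)
    stop("zero variance in expression or state counts")
  fit <- lm(y ~ x)
  tibble::tibble(r = cor(x, y),
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 n_obs = nrow(long))
}
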