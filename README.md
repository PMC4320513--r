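# chromdyn

Chromatin-state dynamics across gene expression modules over a
differentiation time course.

## The problem

During adipogenic differentiation, human pre-adipocytes remodel both
their transcriptome and their chromatin. Combinations of histone
modifications and CTCF define recurrent *chromatin states* — active
and poised enhancers, active, inactive and bivalent promoters,
transcribed gene bodies, and a mark-devoid "blank" state covering most
of the genome. chromdyn is for analysts who want to quantify, across a
time course, how these states load onto genes, how that load differs
between cohorts of co-expressed genes, and which states remodel most
as cells commit to a lineage.

The package implements the full pipeline:

* a **multivariate Bernoulli hidden Markov model** over 200 bp genome
  bins, learned by Baum-Welch from binarized ChIP-seq tracks of all
  time points pooled (emissions e[k, m] = P(mark m | state k);
  row-stochastic transition matrix; scaled forward-backward in
  compiled code), with posterior or Viterbi decoding into per-bin,
  per-time-point state labels;
* **Poisson-background binarization**: a bin is positive for a mark
  when its count reaches the smallest c with P(X >= c; lambda) <= 1e-4;
* **expression modules** by hierarchical clustering of gene
  log(FPKM + 1) time profiles, with silhouette-guided choice of the
  module count;
* **state attribution** over gene bodies extended by a data-derived
  window W (half the averaged 75th-percentile distance from
  state-changing bins to the nearest gene), giving *gene ratios*
  rho(c, s, t) — the fraction of module c's genes carrying state s at
  time t;
* **dynamics statistics**: per-module one-sample t-tests of each
  state's ratio change against the module's overall changes
  (Bonferroni-corrected), significant-change counts per transition,
  dynamics scores `-log10(sum of P)` per module or state, one-sided
  rank-sum comparisons of dynamics between groups, pairwise rank-sum
  enrichment matrices, and the Pearson regression of
  chromatin-signature complexity on log(FPKM + 1);
* a **synthetic-data generator** with planted ground truth (known
  state model, known per-state remodelling rates, known expression
  modules) so every stage is testable without external data.

## Worked example

Simulate a small experiment with planted truth, learn a state model,
attribute states to genes and score state dynamics:

```r
library(chromdyn)

cfg <- synthetic_config(
  n_chromosomes = 2, chromosome_length = 2e6,
  module_spec  = tibble::tibble(archetype = c(1, 3, 5, 8, 12),
                                n_genes = 100),
  seed = 42)
sim <- simulate_experiment(cfg)

fit <- hmm_fit(sim$tracks, n_states = 8, seed = 1, n_restarts = 2)
glance(fit)
#> # A tibble: 1 x 6
#>   n_states n_marks n_obs   logLik n_iter converged
#>      <int>   <int> <int>    <dbl>  <int> <lgl>
#> 1        8       7 80000 -170205.     37 TRUE

perm <- match_states(fit$model, sim$model)
mean(abs(fit$model$emission[perm, ] - sim$model$emission))
#> [1] 0.02257332

pres <- attribute_states(sim$paths, sim$annotation, 1000)
tab  <- temporal_change_tests(gene_ratios(pres, sim$modules))
dynamics_score(tab, group_by = "state")
#> # A tibble: 7 x 4
#>   state n_tests  p_sum  score
#>   <int>   <int>  <dbl>  <dbl>
#> 1     2      15 0.0798  1.10
#> 2     3      15 6.05   -0.782
#> 3     4      15 4.57   -0.660
#> 4     5      15 5.96   -0.775
#> 5     6      15 4.30   -0.633
#> 6     7      15 3.81   -0.581
#> 7     8      15 4.28   -0.632
```

The fitted emissions recover the planted model to within 0.023 mean
absolute error. In the dynamics scores (higher = more remodelling
between time points), state 2 — the planted bivalent-promoter-like
state, the one whose domains resolve during differentiation — stands
far above every other state, while state 3, the planted gene-body
enhancer-like state with a 0.01 flip rate, scores lowest; that is the
planted contrast the statistics are designed to detect. The blank
state (state 1) is excluded from the tests, which is why seven states
are scored.

Plots: `autoplot(fit$model)` draws the emission heat map,
`plot_state_heatmap(ratios, tab)` the per-module gene-ratio maps with
significance dots, `plot_dynamics_score()` and
`plot_state_coverage()` the corresponding summaries.

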