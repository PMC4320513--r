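#' Fit a chromatin-state HMM by Baum-Welch training
#'
#' Learns a K-state multivariate Bernoulli hidden Markov model from
#' binarized mark tracks. All time points are pooled into one training set
#' sharing a single parameter set: each chromosome at each time point is
#' an independent observation sequence (the chain is re-initialised at
#' every sequence start). The E-step runs a scaled forward-backward pass
#' in compiled code; emissions are product-Bernoulli per state.
#'
#' Training restarts `n_restarts` times from seeded random initialisations
#' (emissions uniform on (0.2, 0.8); transitions diagonal-dominant with
#' self-probability 0.9, reflecting the segmental structure of chromatin
#' domains) and keeps the restart with the highest log-likelihood. States
#' of the returned model are re-numbered canonically: by descending
#' expected genome coverage, ties broken lexicographically on the emission
#' vector, so state numbering is stable across runs.
#'
#' @param tracks A binary-mode [mark_track_set()].
#' @param n_states Number of chromatin states K.
#' @param n_iter Maximum EM iterations per restart (default 200).
#' @param tol Relative log-likelihood improvement below which EM stops
#'   (default 1e-6).
#' @param seed Integer seed; restart r uses `seed + r - 1`.
#' @param n_restarts Number of seeded restarts (default 3).
#'
#' @return An object of class `chromdyn_hmm`: list with `model` (a
#'   [chromatin_state_model()]), `loglik_trace` of the best restart,
#'   `restarts` summary tibble, `converged`, and `n_obs`.
#' @seealso [decode_states()], [state_coverage()]
#' @export
hmm_fit <- function(tracks, n_states, n_iter = 200, tol = 1e-6,
                    seed = 1, n_restarts = 3) {
  stopifnot(inherits(tracks, "mark_track_set"))
  if (tracks$mode != "binary")
    stop("hmm_fit() expects binarized tracks; see binarize_tracks()")
  stopifnot(n_states >= 1, n_iter >= 1, n_restarts >= 1)
  stacked <- stack_tracks(tracks)
  if (n_states > nrow(stacked$obs))
    stop("n_states exceeds the number of observations")

  runs <- purrr::map(seq_len(n_restarts), function(r) {
    init <- local_seed(seed + r - 1, random_init(n_states, length(tracks$marks)))
    run_em(stacked, init, n_iter = n_iter, tol = tol)
  })
  logliks <- vapply(runs, function(r) r$loglik, numeric(1))
  best <- runs[[which.max(logliks)]]

  # canonical state ordering: descending expected coverage, then
  # lexicographic emission vector
  coverage <- colSums(best$gamma) / nrow(best$gamma)
  ord <- do.call(order, c(list(-coverage),
                          lapply(seq_len(ncol(best$emission)),
                                 function(j) best$emission[, j])))
  model <- chromatin_state_model(
    emission = best$emission[ord, , drop = FALSE],
    transition = best$transition[ord, ord, drop = FALSE],
    initial = best$initial[ord],
    marks = tracks$marks)

  structure(
    list(model = model,
         loglik_trace = best$trace,
         converged = best$converged,
         n_obs = nrow(stacked$obs),
         expected_coverage = coverage[ord],
         restarts = tibble::tibble(
           restart = seq_len(n_restarts),
           seed = seed + seq_len(n_restarts) - 1,
           loglik = logliks,
           n_iter = vapply(runs, function(r) length(r$trace), integer(1)))),
    class = "chromdyn_hmm")
}

#' @export
print.chromdyn_hmm <- function(x, ...) {
  cat("<chromdyn_hmm> ", x$model$K, " states, ", length(x$model$marks),
      " marks, ", x$n_obs, " observations\n",
      "log-likelihood ", format(max(x$restarts$loglik), digits = 10),
      " after ", length(x$loglik_trace), " EM iterations (",
      nrow(x$restarts), " restart(s))\n", sep = "")
  invisible(x)
}

#' @describeIn hmm_fit Long-form emission probabilities of the fitted
#'   model (state, mark, probability).
#' @param x A `chromdyn_hmm` fit.
#' @param ... Unused.
#' @export
tidy.chromdyn_hmm <- function(x, ...) tidy(x$model)

#' @describeIn hmm_fit One-row fit summary: states, observations, best
#'   log-likelihood, iterations, convergence flag.
#' @export
glance.chromdyn_hmm <- function(x, ...) {
  tibble::tibble(
    n_states = x$model$K,
    n_marks = length(x$model$marks),
    n_obs = x$n_obs,
    logLik = max(x$restarts$loglik),
    n_iter = length(x$loglik_trace),
    converged = x$converged)
}

#' Decode chromatin states from binarized tracks
#'
#' Assigns a state to every bin at every time point under a fitted model.
#' The default is posterior decoding (per-bin argmax of the
#' forward-backward posterior, as in standard chromatin-segmentation
#' practice); Viterbi (jointly most probable path) is available as an
#' option. Posterior ties are broken toward the lower state index so
#' output is deterministic.
#'
#' @param model A [chromatin_state_model()].
#' @param tracks A binary-mode [mark_track_set()] with the model's marks.
#' @param method `"posterior"` (default) or `"viterbi"`.
#' @return A [state_segmentation()].
#' @export
decode_states <- function(model, tracks, method = c("posterior", "viterbi")) {
  method <- match.arg(method)
  check_model_tracks(model, tracks)
  stacked <- stack_tracks(tracks)
  ll <- emission_loglik(stacked$obs, model$emission)
  labels <- if (method == "posterior") {
    fb <- fb_pass(ll, model$transition, model$initial, stacked$seq_starts)
    max.col(fb$gamma, ties.method = "first")
  } else {
    viterbi_path(ll, model$transition, model$initial, stacked$seq_starts)
  }
  states <- matrix(labels, nrow = tracks$bins$n_bins,
                   dimnames = list(NULL, tracks$time_points))
  state_segmentation(states, tracks$bins, model$K)
}

#' Forward-backward state posteriors
#'
#' Per-bin posterior state probabilities under a model, one bin x K matrix
#' per time point. Rows sum to 1.
#'
#' @inheritParams decode_states
#' @return Named list (by time point) of bin x K posterior matrices.
#' @export
state_posterior <- function(model, tracks) {
  check_model_tracks(model, tracks)
  stacked <- stack_tracks(tracks)
  ll <- emission_loglik(stacked$obs, model$emission)
  fb <- fb_pass(ll, model$transition, model$initial, stacked$seq_starts)
  n <- tracks$bins$n_bins
  out <- lapply(seq_along(tracks$time_points), function(i) {
    fb$gamma[(i - 1) * n + seq_len(n), , drop = FALSE]
  })
  names(out) <- tracks$time_points
  out
}

#' Total log-likelihood of tracks under a model
#'
#' @inheritParams decode_states
#' @return The log-likelihood (numeric scalar).
#' @export
hmm_loglik <- function(model, tracks) {
  check_model_tracks(model, tracks)
  stacked <- stack_tracks(tracks)
  ll <- emission_loglik(stacked$obs, model$emission)
  fb_pass(ll, model$transition, model$initial, stacked$seq_starts)$loglik
}

check_model_tracks <- function(model, tracks) {
  stopifnot(inherits(model, "chromatin_state_model"),
            inherits(tracks, "mark_track_set"))
  if (tracks$mode != "binary") stop("tracks must be binary mode")
  if (!identical(model$marks, tracks$marks))
    stop("mark sets of model and tracks differ")
  invisible(TRUE)
}

# stack per-time-point matrices into one observation matrix; every
# chromosome at every time point is an independent sequence
stack_tracks <- function(tracks) {
  obs <- do.call(rbind, tracks$tracks)
  storage.mode(obs) <- "double"
  n <- tracks$bins$n_bins
  starts <- unlist(lapply(seq_along(tracks$time_points), function(i) {
    (i - 1) * n + unname(tracks$bins$offsets) + 1L
  }), use.names = FALSE)
  list(obs = obs, seq_starts = as.integer(starts))
}

# T x K matrix of per-position log emission likelihoods under
# product-Bernoulli emissions
emission_loglik <- function(obs, emission) {
  eps <- 1e-12
  e <- pmin(pmax(emission, eps), 1 - eps)
  obs %*% t(log(e) - log1p(-e)) +
    matrix(rowSums(log1p(-e)), nrow(obs), nrow(e), byrow = TRUE)
}

random_init <- function(K, M) {
  emission <- matrix(runif(K * M, 0.2, 0.8), K, M)
  transition <- matrix(0.1 / max(K - 1, 1), K, K)
  diag(transition) <- if (K == 1) 1 else 0.9
  list(emission = emission, transition = transition,
       initial = rep(1 / K, K))
}

run_em <- function(stacked, init, n_iter, tol) {
  eps <- 1e-6
  emission <- init$emission
  transition <- init$transition
  initial <- init$initial
  trace <- numeric(0)
  converged <- FALSE
  fitted <- NULL
  for (it in seq_len(n_iter)) {
    ll_mat <- emission_loglik(stacked$obs, emission)
    fb <- fb_pass(ll_mat, transition, initial, stacked$seq_starts)
    if (!is.finite(fb$loglik))
      stop("non-finite log-likelihood in E-step at iteration ", it)
    trace <- c(trace, fb$loglik)
    # parameters that produced the recorded likelihood
    fitted <- list(emission = emission, transition = transition,
                   initial = initial, gamma = fb$gamma)
    if (it > 1) {
      prev <- trace[it - 1]
      if (fb$loglik < prev - 1e-8)
        stop("log-likelihood decreased at iteration ", it,
             " (", prev, " -> ", fb$loglik, ")")
      if (abs(fb$loglik - prev) < tol * abs(prev)) {
        converged <- TRUE
        break
      }
    }
    # M-step
    occ <- colSums(fb$gamma)
    emission <- crossprod(fb$gamma, stacked$obs) / occ
    emission <- pmin(pmax(emission, eps), 1 - eps)
    xr <- rowSums(fb$xi)
    keep <- xr > 0
    transition[keep, ] <- fb$xi[keep, , drop = FALSE] / xr[keep]
    transition <- transition / rowSums(transition)
    initial <- fb$init_counts / sum(fb$init_counts)
  }
  c(fitted, list(loglik = trace[length(trace)], trace = trace,
                 converged = converged))
}

# evaluate expr under a temporary RNG state seeded with `seed`
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
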