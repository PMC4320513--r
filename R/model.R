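#' Multivariate Bernoulli chromatin-state model
#'
#' A hidden Markov model over genomic bins in which each of `K` latent
#' chromatin states emits, independently per mark, a binary presence call
#' for each of `M` chromatin marks (histone modifications and CTCF). The
#' model is the one learned by Baum-Welch training on binarized ChIP-seq
#' tracks; its emission matrix is the per-state probability of observing
#' each mark, and its transition matrix encodes the spatial grammar of
#' states along the genome.
#'
#' @param emission K x M matrix of Bernoulli emission probabilities.
#' @param transition K x K row-stochastic transition matrix.
#' @param initial Length-K initial state distribution.
#' @param marks Character vector of M mark names.
#' @param state_labels Optional character vector of K functional labels
#'   (e.g. "active enhancer", "bivalent promoter").
#'
#' @return An object of class `chromatin_state_model`.
#' @examples
#' m <- chromatin_state_model(
#'   emission = rbind(c(0.9, 0.1), c(0.1, 0.8)),
#'   transition = rbind(c(0.95, 0.05), c(0.05, 0.95)),
#'   initial = c(0.5, 0.5), marks = c("H3K4me3", "H3K36me3"))
#' m
#' @export
chromatin_state_model <- function(emission, transition, initial,
                                  marks = NULL, state_labels = NULL) {
  emission <- as.matrix(emission)
  transition <- as.matrix(transition)
  K <- nrow(emission)
  M <- ncol(emission)
  if (!is.null(marks)) stopifnot(length(marks) == M)
  marks <- marks %||% paste0("mark", seq_len(M))
  stopifnot(nrow(transition) == K, ncol(transition) == K,
            length(initial) == K)
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-9))
    stop("transition rows must be non-negative and sum to 1 (tol 1e-9)")
  if (any(initial < 0) || abs(sum(initial) - 1) > 1e-9)
    stop("initial distribution must be non-negative and sum to 1 (tol 1e-9)")
  if (any(emission < 0) || any(emission > 1))
    stop("emission probabilities must lie in [0, 1]")
  eps <- 1e-6   # clamp so log-emissions stay finite
  emission <- pmin(pmax(emission, eps), 1 - eps)
  if (!is.null(state_labels)) stopifnot(length(state_labels) == K)
  dimnames(emission) <- list(paste0("cs", seq_len(K)), marks)
  dimnames(transition) <- list(paste0("cs", seq_len(K)), paste0("cs", seq_len(K)))
  structure(
    list(K = K, marks = marks, emission = emission,
         transition = transition, initial = as.numeric(initial),
         state_labels = state_labels),
    class = "chromatin_state_model")
}

#' @export
print.chromatin_state_model <- function(x, ...) {
  cat("<chromatin_state_model> ", x$K, " states x ", length(x$marks),
      " marks (", paste(x$marks, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @describeIn chromatin_state_model One row per state x mark with the
#'   emission probability (long form, ready for heat-map plotting).
#' @param x A `chromatin_state_model`.
#' @param ... Unused.
#' @export
tidy.chromatin_state_model <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$emission,
                                        responseName = "probability")) |>
    dplyr::rename(state = "Var1", mark = "Var2") |>
    dplyr::mutate(state = as.character(.data$state),
                  mark = as.character(.data$mark))
}

#' @describeIn chromatin_state_model One-row summary: K, number of marks,
#'   mean self-transition probability.
#' @export
glance.chromatin_state_model <- function(x, ...) {
  tibble::tibble(
    n_states = x$K,
    n_marks = length(x$marks),
    mean_self_transition = mean(diag(x$transition)))
}

#' Read or write a chromatin-state model as JSON
#'
#' The on-disk model file stores K, mark names, emission and transition
#' matrices, the initial distribution and optional state labels.
#'
#' @param model A [chromatin_state_model()].
#' @param path File path.
#' @return `write_model_json()` returns `path` invisibly;
#'   `read_model_json()` returns a `chromatin_state_model`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "chromatin_state_model"))
  obj <- list(K = model$K, marks = model$marks,
              emission = unname(model$emission),
              transition = unname(model$transition),
              initial = model$initial,
              state_labels = model$state_labels)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  chromatin_state_model(
    emission = obj$emission, transition = obj$transition,
    initial = obj$initial, marks = obj$marks,
    state_labels = obj$state_labels)
}

#' Match estimated states to reference states
#'
#' Finds the permutation of the estimated model's states minimising the
#' total L1 distance between emission rows (exhaustive over permutations
#' for K <= 8, greedy otherwise). Used to compare a trained model against
#' the generating model, whose state numbering is arbitrary.
#'
#' @param estimated,reference Two [chromatin_state_model()] objects with
#'   equal K and identical mark sets.
#' @return Integer vector `perm` such that estimated state `perm[k]`
#'   corresponds to reference state `k`.
#' @export
match_states <- function(estimated, reference) {
  stopifnot(estimated$K == reference$K,
            identical(estimated$marks, reference$marks))
  K <- reference$K
  cost <- matrix(0, K, K)  # cost[i, j] = L1 gap, reference i vs estimated j
  for (i in seq_len(K))
    for (j in seq_len(K))
      cost[i, j] <- sum(abs(reference$emission[i, ] - estimated$emission[j, ]))
  if (K <= 8) {
    perms <- all_permutations(K)
    totals <- apply(perms, 1, function(p) sum(cost[cbind(seq_len(K), p)]))
    perms[which.min(totals), ]
  } else {
    perm <- integer(K)
    free <- rep(TRUE, K)
    for (i in order(apply(cost, 1, min))) {
      j <- which(free)[which.min(cost[i, free])]
      perm[i] <- j
      free[j] <- FALSE
    }
    perm
  }
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

# reorder a model's states by a permutation (state perm[k] becomes state k)
permute_model <- function(model, perm) {
  chromatin_state_model(
    emission = model$emission[perm, , drop = FALSE],
    transition = model$transition[perm, perm, drop = FALSE],
    initial = model$initial[perm],
    marks = model$marks,
    state_labels = if (!is.null(model$state_labels)) model$state_labels[perm])
}
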