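#' Local field at the network nodes
#'
#' \eqn{h_i = \sum_j W_{ij} x_j}. For non-overlapping signatures the weight
#' matrix is class-blocked (\eqn{\pm p/N}) and the field reduces to running
#' class sums, \eqn{h_i = (p/N)(2 S_{c(i)} - S - x_i)} with
#' \eqn{S_c = \sum_{j \in c} x_j} and \eqn{S = \sum_j x_j}; `method =
#' "class_sum"` uses that shortcut, `"dense"` the full matrix-vector
#' product. Both agree to 1e-12 on valid inputs.
#'
#' @param weights N x N weight matrix.
#' @param state Ternary (or binary) state vector.
#' @param bank Template bank (required for `method = "class_sum"`).
#' @param method `"dense"` or `"class_sum"`.
#' @return Numeric vector of fields, one per gene.
#' @export
local_field <- function(weights, state, bank = NULL,
                        method = c("dense", "class_sum")) {
  method <- match.arg(method)
  if (method == "dense") return(unname(drop(weights %*% state)))
  stopifnot(inherits(bank, "template_bank"))
  if (bank$overlapping)
    stop("class_sum shortcut requires non-overlapping signatures")
  S_c <- vapply(seq_len(bank$p),
                function(c) sum(state[bank$class_of_gene == c]), numeric(1))
  S <- sum(state)
  (bank$p / bank$N) * (2 * S_c[bank$class_of_gene] - S - state)
}

#' Network energy of a state
#'
#' \eqn{E = -\frac{1}{2}\sum_{i,j} W_{ij} x_i x_j}. This is a Lyapunov
#' function of the asynchronous sign-rule dynamics: stored patterns sit in
#' its local minima, and a low initial energy means the state is close to
#' an attractor. Zero (eliminated or absent) coordinates contribute
#' nothing.
#'
#' @param weights N x N weight matrix.
#' @param state State vector in \eqn{\{-1,0,+1\}^N}.
#' @return Scalar energy.
#' @export
state_energy <- function(weights, state) {
  -0.5 * sum(drop(weights %*% state) * state)
}

#' One asynchronous sweep of the classical dynamics
#'
#' Visits every node in `order` and sets \eqn{x_i \leftarrow
#' \mathrm{sign}(h_i)}; a zero field leaves the node unchanged. The energy
#' is non-increasing across the sweep.
#'
#' @param state \eqn{\pm 1} state vector.
#' @param weights Weight matrix.
#' @param order Permutation of `seq_along(state)`; defaults to a fresh
#'   uniform draw from the current RNG stream.
#' @return List with `state` (updated vector) and `flips` (number of
#'   changed nodes).
#' @export
async_sweep_classic <- function(state, weights, order = NULL) {
  if (is.null(order)) order <- sample.int(length(state))
  res <- cpp_sweep_classic(weights, as.integer(state), as.integer(order))
  res$state <- stats::setNames(res$state, names(state))
  res
}

#' One asynchronous sweep of the asymmetric diluted dynamics
#'
#' Ternary states \eqn{x_i \in \{-1, 0, +1\}}. A node at \eqn{-1} with
#' positive field switches to \eqn{+1}; a node at \eqn{+1} with negative
#' field is eliminated (set to 0) instead of switching down, and eliminated
#' nodes never re-enter the dynamics; a zero field changes nothing. The
#' elimination rule suppresses genes carrying a misleading signal rather
#' than inverting them.
#'
#' @inheritParams async_sweep_classic
#' @return List with `state`, `changed` (updated nodes) and `eliminated`
#'   (number of +1 to 0 events in this sweep).
#' @export
async_sweep_asymmetric <- function(state, weights, order = NULL) {
  if (is.null(order)) order <- sample.int(length(state))
  res <- cpp_sweep_asym(weights, as.integer(state), as.integer(order))
  res$state <- stats::setNames(res$state, names(state))
  res
}

#' Match fraction between a state and a class template
#'
#' Fraction of the genes in `active0` (the genes active at t = 0, i.e.
#' after cutoff subsampling and binarization) whose current state equals
#' the template value. Dynamically eliminated genes (now 0) count as
#' mismatches; genes inactive from the start are excluded from the
#' denominator.
#'
#' @param state Current ternary state.
#' @param template \eqn{\pm 1} template vector.
#' @param active0 Logical mask of genes active at t = 0.
#' @return Fraction in \[0, 1\].
#' @export
match_fraction <- function(state, template, active0) {
  if (!any(active0)) stop("no active genes at t = 0 (degenerate sample)")
  sum(state[active0] == template[active0]) / sum(active0)
}

match_fractions <- function(state, templates, active0) {
  colSums(templates[active0, , drop = FALSE] == state[active0]) / sum(active0)
}

#' Evolve a sample state to a class attractor
#'
#' Runs asymmetric sweeps (fresh random order per sweep) up to
#' `config$max_sweeps`. After each sweep the match fraction against every
#' template is evaluated over the genes active at t = 0; the replica
#' converges to the first class reaching `config$match_threshold`
#' (default 0.95). If two classes pass in the same sweep the higher match
#' wins and an exact tie yields no call; if the state stops changing (the
#' asymmetric dynamics cannot cycle) or the sweep budget is exhausted
#' without any class qualifying, the replica is unconverged.
#'
#' @param state0 Initial ternary state (after binarization and cutoff).
#' @param bank Template bank.
#' @param weights Weight matrix from [hebb_weights_modified()].
#' @param config A [hop_config()].
#' @return List of class `replica_outcome`: `converged_class` (label or
#'   `NA`), `match_fraction`, `sweeps`, `eliminated`, `energy_initial`,
#'   `energy_final`, `state`.
#' @export
evolve_to_class <- function(state0, bank, weights, config = hop_config()) {
  x <- as.integer(state0)
  active0 <- x != 0L
  if (!any(active0)) stop("initial state has no active genes")
  e0 <- state_energy(weights, x)
  eliminated <- 0L
  sweeps <- 0L
  converged <- NA_character_
  best_mf <- 0
  repeat {
    if (sweeps >= config$max_sweeps) break
    res <- cpp_sweep_asym(weights, x, sample.int(length(x)))
    x <- res$state
    eliminated <- eliminated + res$eliminated
    sweeps <- sweeps + 1L
    mf <- match_fractions(x, bank$templates, active0)
    best_mf <- max(mf)
    if (best_mf >= config$match_threshold) {
      top <- which(mf == best_mf)
      if (length(top) == 1L) converged <- colnames(bank$templates)[top]
      break # an exact tie between classes is an ambiguous (no-call) outcome
    }
    if (res$changed == 0L) break
  }
  structure(
    list(converged_class = converged, match_fraction = best_mf,
         sweeps = sweeps, eliminated = eliminated,
         energy_initial = e0, energy_final = state_energy(weights, x),
         state = stats::setNames(as.integer(x), bank$gene_index)),
    class = "replica_outcome")
}
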