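#' Random uncorrelated patterns
#'
#' i.i.d. uniform \eqn{\pm 1} entries, used to probe the storage capacity
#' of the classical model.
#'
#' @param N Pattern length (number of spins).
#' @param p Number of patterns.
#' @return N x p integer matrix of -1/+1.
#' @export
random_patterns <- function(N, p) {
  stopifnot(N >= 1, p >= 1)
  matrix(sample(c(-1L, 1L), N * p, replace = TRUE), nrow = N, ncol = p)
}

#' Estimate the storage capacity of the classical Hopfield network
#'
#' For each load ratio \eqn{\alpha = p/N}, stores `round(alpha * N)` random
#' uncorrelated patterns with the classical Hebb rule, initializes the
#' network at each stored pattern, runs asynchronous sign-rule dynamics to
#' a fixed point, and scores a pattern as retrieved when the final overlap
#' \eqn{m = \xi \cdot x / N} with it is at least `overlap_threshold`. The
#' critical ratio is the smallest ratio at which the mean retrieved
#' fraction drops below `retrieved_threshold`; random uncorrelated
#' memories lose retrievability near \eqn{p_c/N \approx 0.138}.
#'
#' @param N Network size (at least 100; finite-size rounding of the
#'   transition shrinks as N grows).
#' @param ratios Ascending load ratios p/N to scan.
#' @param trials Independent repetitions per ratio (fresh patterns each).
#' @param overlap_threshold Overlap defining successful retrieval.
#' @param retrieved_threshold Retrieved-fraction level defining loss of
#'   retrieval.
#' @param max_sweeps Sweep cap per relaxation (fixed points are normally
#'   reached in a handful of sweeps).
#' @return List of class `capacity_estimate`: `critical_ratio`, its
#'   Monte-Carlo standard error `se` (from per-trial critical ratios),
#'   `ratios`, `retrieved` (trials x ratios matrix of retrieved
#'   fractions), `retrieved_mean`, and the call parameters.
#' @export
estimate_capacity <- function(N = 500,
                              ratios = seq(0.10, 0.18, by = 0.01),
                              trials = 20,
                              overlap_threshold = 0.95,
                              retrieved_threshold = 0.5,
                              max_sweeps = 100) {
  stopifnot(N >= 100, trials >= 1, !is.unsorted(ratios))
  frac <- matrix(NA_real_, nrow = trials, ncol = length(ratios))
  for (t in seq_len(trials)) {
    for (r in seq_along(ratios)) {
      p <- max(1L, as.integer(round(ratios[r] * N)))
      xi <- random_patterns(N, p)
      W <- hebb_weights_classic(xi)
      got <- 0L
      for (mu in seq_len(p)) {
        res <- cpp_evolve_classic(W, xi[, mu], as.integer(max_sweeps))
        if (sum(res$state * xi[, mu]) / N >= overlap_threshold) got <- got + 1L
      }
      frac[t, r] <- got / p
    }
  }
  means <- colMeans(frac)
  crit_of <- function(f) {
    i <- which(f < retrieved_threshold)[1]
    if (is.na(i)) NA_real_ else ratios[i]
  }
  critical <- crit_of(means)
  per_trial <- apply(frac, 1, crit_of)
  se <- if (sum(!is.na(per_trial)) > 1)
    sd(per_trial, na.rm = TRUE) / sqrt(sum(!is.na(per_trial))) else NA_real_
  structure(
    list(critical_ratio = critical, se = se, ratios = ratios,
         retrieved = frac, retrieved_mean = means, per_trial = per_trial,
         N = N, trials = trials, overlap_threshold = overlap_threshold,
         retrieved_threshold = retrieved_threshold),
    class = "capacity_estimate")
}

#' @export
print.capacity_estimate <- function(x, ...) {
  cat(sprintf(
    "capacity_estimate: N = %d, %d trials\n  critical p/N = %s (MC se %s)\n",
    x$N, x$trials, format(x$critical_ratio),
    format(signif(x$se, 3))))
  print(data.frame(ratio = x$ratios,
                   retrieved = round(x$retrieved_mean, 3)), row.names = FALSE)
  invisible(x)
}

#' Minimal network size for error-free pattern storage
#'
#' A single bit of a stored pattern is unstable with probability
#' \eqn{P_{error} = \frac{1}{2}[1 - \mathrm{erf}(\sqrt{N/2p})]}, so
#' requiring error-free recall of a whole pattern,
#' \eqn{(1 - P_{error})^N > 0.99}, leads (via the asymptotic expansion of
#' erf) to the self-consistent bound \eqn{N > p \ln(N p / 0.0002\pi)}.
#' The bound is solved by fixed-point iteration; for the practically
#' relevant class counts \eqn{2 \ll p \ll 6} the threshold size lands
#' between roughly 70 and 100 genes, which is why the default signature
#' cutoff keeps the working network comfortably above it.
#'
#' @param p Number of stored classes.
#' @param tol Convergence tolerance of the fixed-point iteration.
#' @return The minimal integer N strictly satisfying the bound.
#' @export
storage_bound_size <- function(p, tol = 1e-10) {
  stopifnot(p >= 1)
  rhs <- function(n) p * log(n * p / (0.0002 * pi))
  n <- max(10, 2 * p)
  for (it in 1:200) {
    n_new <- rhs(n)
    if (abs(n_new - n) < tol) break
    n <- n_new
  }
  N <- floor(n)
  while (!(N > rhs(N))) N <- N + 1L
  as.integer(N)
}

#' Analytic probability of error-free recall
#'
#' \eqn{(1 - P_{error})^N} with
#' \eqn{P_{error} = \frac{1}{2}[1 - \mathrm{erf}(\sqrt{N/2p})]}: the
#' probability that none of the N bits of a stored pattern is unstable.
#'
#' @param N Network size.
#' @param p Number of stored patterns.
#' @return Probability in (0, 1).
#' @export
recall_probability <- function(N, p) {
  p_err <- 0.5 * (1 - erf(sqrt(N / (2 * p))))
  (1 - p_err)^N
}
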