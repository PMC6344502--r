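#' Specification of a synthetic class-structured cohort
#'
#' The generator draws per-gene log2 ratios: for a sample of class c, its
#' own signature genes are Normal(+effect, sigma), the other signature
#' genes Normal(-effect, sigma), and pure-noise genes Normal(0, sigma);
#' each signature gene's sign is then corrupted (value negated)
#' independently with probability `flip_prob`. Defaults emulate a moderate
#' three-class problem with imbalanced signatures whose pairwise sizes
#' keep every template a stable attractor of the asymmetric dynamics.
#'
#' @param p Number of classes.
#' @param signature_sizes Integer vector of \eqn{N_\mu}, length `p`.
#' @param n_noise_genes Genes outside every signature (filtered out by the
#'   classifier, present to exercise the filtering step).
#' @param samples_per_class Samples drawn for each class.
#' @param effect Mean absolute log2-ratio shift of signature genes
#'   (default 1.5, a clear ~3-fold signal).
#' @param sigma Gaussian noise sd (default 0.5).
#' @param flip_prob Per-gene sign-corruption probability in \[0, 0.5\];
#'   0.5 destroys all class signal.
#' @param mixture Optional named numeric vector of class weights; if
#'   given, every sample's per-gene mean is the convex combination of the
#'   class means and `samples_per_class[1]` samples are drawn (labels are
#'   the dominant class).
#' @param seed Seed making the generator a pure function of the spec.
#' @return List of class `synth_spec`.
#' @export
synth_spec <- function(p = 3,
                       signature_sizes = c(60, 80, 100),
                       n_noise_genes = 200,
                       samples_per_class = rep(10, p),
                       effect = 1.5,
                       sigma = 0.5,
                       flip_prob = 0,
                       mixture = NULL,
                       seed = 1) {
  stopifnot(p >= 2, length(signature_sizes) == p, all(signature_sizes >= 1),
            effect > 0, sigma >= 0, flip_prob >= 0, flip_prob <= 0.5,
            length(samples_per_class) == p || !is.null(mixture))
  structure(list(p = as.integer(p),
                 signature_sizes = as.integer(signature_sizes),
                 n_noise_genes = as.integer(n_noise_genes),
                 samples_per_class = as.integer(samples_per_class),
                 effect = effect, sigma = sigma, flip_prob = flip_prob,
                 mixture = mixture, seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate disjoint synthetic signatures
#'
#' @param spec A [synth_spec()].
#' @return A [signature_set()] with classes `C1..Cp` and gene names
#'   `C<k>_g<i>`; deterministic under the spec's seed.
#' @export
make_signatures <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  genes <- lapply(seq_len(spec$p), function(k) {
    sprintf("C%d_g%03d", k, seq_len(spec$signature_sizes[k]))
  })
  names(genes) <- paste0("C", seq_len(spec$p))
  signature_set(genes)
}

#' Simulate a class-structured expression cohort
#'
#' @param spec A [synth_spec()].
#' @param signatures Optional [signature_set()]; defaults to
#'   [make_signatures()] on the same spec (the signatures the samples are
#'   generated to follow).
#' @return List with `expression` (genes x samples matrix of log2 ratios,
#'   signature genes first, then noise genes), `labels` (true class per
#'   sample), `signatures`.
#' @export
simulate_cohort <- function(spec, signatures = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  if (is.null(signatures)) signatures <- make_signatures(spec)
  classes <- signatures$classes
  sig_genes <- unlist(signatures$genes, use.names = FALSE)
  noise_genes <- if (spec$n_noise_genes > 0)
    sprintf("noise_g%04d", seq_len(spec$n_noise_genes)) else character(0)
  genes <- c(sig_genes, noise_genes)
  memb <- rep(seq_along(classes), times = lengths(signatures$genes))

  class_mean <- function(k) {
    mu <- ifelse(memb == k, spec$effect, -spec$effect)
    c(mu, rep(0, spec$n_noise_genes))
  }

  if (is.null(spec$mixture)) {
    labels <- rep(classes, times = spec$samples_per_class)
    means <- lapply(seq_along(classes), class_mean)
    mean_of <- function(j) means[[match(labels[j], classes)]]
  } else {
    w <- spec$mixture / sum(spec$mixture)
    labels <- rep(classes[which.max(w)], spec$samples_per_class[1])
    mix_mean <- Reduce(`+`, Map(function(k, wk) wk * class_mean(k),
                                seq_along(classes), w))
    mean_of <- function(j) mix_mean
  }
  n_samples <- length(labels)
  expr <- matrix(NA_real_, nrow = length(genes), ncol = n_samples,
                 dimnames = list(genes, sprintf("S%03d", seq_len(n_samples))))
  n_sig <- length(sig_genes)
  for (j in seq_len(n_samples)) {
    v <- rnorm(length(genes), mean = mean_of(j), sd = spec$sigma)
    if (spec$flip_prob > 0) {
      flip <- runif(n_sig) < spec$flip_prob
      v[seq_len(n_sig)][flip] <- -v[seq_len(n_sig)][flip]
    }
    expr[, j] <- v
  }
  list(expression = expr, labels = labels, signatures = signatures)
}
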