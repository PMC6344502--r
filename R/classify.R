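#' Classifier configuration
#'
#' @param gamma Signature-size cutoff \eqn{\Gamma}: classes larger than
#'   this are randomly subsampled to `gamma` genes per replica. Default
#'   200, chosen so that the working network stays well above the
#'   error-free storage bound (see [storage_bound_size()]) while keeping
#'   classes balanced.
#' @param replicas M, number of cutoff-resampling replicas entering the
#'   majority vote (default 100). When no class exceeds `gamma` there is
#'   nothing to resample and a single replica is run.
#' @param match_threshold Fraction of initially active genes that must
#'   match a template for convergence (default 0.95).
#' @param n_permutations Size of the per-sample permutation null for the
#'   energy p-value (default 1000). Set to 0 to skip significance.
#' @param null_replicas Replicas used when classifying each permuted
#'   sample (default: same as `replicas`).
#' @param max_sweeps Sweep cap per replica; the asymmetric dynamics cannot
#'   cycle, so this is a safety bound, not a tuning knob.
#' @param seed Master seed; every random stream (replica subsampling,
#'   sweep orders, permutations) is derived from it deterministically.
#'   `NULL` draws one from the session RNG and reports it.
#' @param ratio_mode `"precomputed_log2ratio"`: matrix entries are already
#'   log2 ratios and are binarized by sign. `"gene_median_log2ratio"`:
#'   entries are intensities; each gene is binarized by the sign of its
#'   value minus the gene's cohort median.
#' @param secondary Compute the secondary class (requires at least 3
#'   classes)?
#' @return List of class `hop_config`.
#' @export
hop_config <- function(gamma = 200L,
                       replicas = 100L,
                       match_threshold = 0.95,
                       n_permutations = 1000L,
                       null_replicas = replicas,
                       max_sweeps = 100L,
                       seed = NULL,
                       ratio_mode = c("precomputed_log2ratio",
                                      "gene_median_log2ratio"),
                       secondary = TRUE) {
  ratio_mode <- match.arg(ratio_mode)
  stopifnot(gamma >= 1, replicas >= 1, null_replicas >= 1, max_sweeps >= 1,
            match_threshold > 0, match_threshold <= 1, n_permutations >= 0)
  structure(
    list(gamma = as.integer(gamma), replicas = as.integer(replicas),
         match_threshold = match_threshold,
         n_permutations = as.integer(n_permutations),
         null_replicas = as.integer(null_replicas),
         max_sweeps = as.integer(max_sweeps),
         seed = if (is.null(seed)) NULL else as.integer(seed),
         ratio_mode = ratio_mode, secondary = isTRUE(secondary)),
    class = "hop_config")
}

#' Restrict an expression matrix to the signature genes
#'
#' Genes in no signature are dropped; signature genes absent from the
#' matrix are retained as missing rows (they binarize to 0). Per-class
#' coverage (fraction of signature genes measured) is attached as the
#' `"coverage"` attribute, and a class with no measured gene at all is an
#' error.
#'
#' @param expr Numeric matrix, genes x samples, with row and column names.
#' @param signatures A [signature_set()].
#' @return Matrix with rows exactly `build_template_bank(signatures)$gene_index`.
#' @export
filter_to_signature_genes <- function(expr, signatures) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  if (anyDuplicated(rownames(expr)))
    stop("duplicated gene identifiers in expression matrix")
  if (anyDuplicated(colnames(expr)))
    stop("duplicated sample identifiers in expression matrix")
  bank <- build_template_bank(signatures)
  out <- matrix(NA_real_, nrow = bank$N, ncol = ncol(expr),
                dimnames = list(bank$gene_index, colnames(expr)))
  hit <- intersect(bank$gene_index, rownames(expr))
  out[hit, ] <- expr[hit, ]
  coverage <- vapply(signatures$classes, function(cl) {
    mean(signatures$genes[[cl]] %in% rownames(expr))
  }, numeric(1))
  missing_cl <- names(coverage)[coverage == 0]
  if (length(missing_cl) > 0L)
    stop("no signature gene measured for class(es): ",
         paste(missing_cl, collapse = ", "))
  attr(out, "coverage") <- coverage
  out
}

#' Binarize one sample into the ternary initial state
#'
#' `precomputed_log2ratio` mode: \eqn{x_i^0 = \mathrm{sign}(A_i)}.
#' `gene_median_log2ratio` mode: \eqn{x_i^0 = \mathrm{sign}(A_i -
#' \mathrm{median}_i)} against the per-gene cohort medians in `reference`.
#' Missing genes, zero values and exact ties binarize to 0, so that an
#' absent gene plays no role in the dynamics.
#'
#' @param values Numeric vector aligned to the template-bank gene index.
#' @param ratio_mode See [hop_config()].
#' @param reference Per-gene reference (cohort medians), required in
#'   `gene_median_log2ratio` mode.
#' @return Integer vector in \eqn{\{-1,0,+1\}}, same names as `values`.
#' @export
binarize_sample <- function(values,
                            ratio_mode = c("precomputed_log2ratio",
                                           "gene_median_log2ratio"),
                            reference = NULL) {
  ratio_mode <- match.arg(ratio_mode)
  if (ratio_mode == "gene_median_log2ratio") {
    if (is.null(reference))
      stop("gene_median_log2ratio mode needs per-gene cohort medians",
           " (a multi-sample reference)")
    stopifnot(length(reference) == length(values))
    v <- values - reference
  } else {
    v <- values
  }
  x <- as.integer(sign(v))
  x[is.na(x)] <- 0L
  stats::setNames(x, names(values))
}

#' Random cutoff subsampling of oversized signatures
#'
#' Classes of size at most `gamma` keep all genes; larger classes get a
#' uniform without-replacement subset of exactly `gamma` genes. Called
#' afresh for every replica; genes not selected are forced to state 0 in
#' that replica's input.
#'
#' @param signatures A [signature_set()].
#' @param gamma Cutoff.
#' @return Named list (per class) of retained gene vectors.
#' @export
gamma_select <- function(signatures, gamma) {
  stopifnot(inherits(signatures, "signature_set"), gamma >= 1)
  lapply(signatures$genes, function(g) {
    if (length(g) <= gamma) g else sample(g, gamma)
  })
}

# logical keep-mask over the bank's gene index for one replica
gamma_mask <- function(bank, signatures, gamma) {
  kept <- unlist(gamma_select(signatures, gamma), use.names = FALSE)
  bank$gene_index %in% kept
}

#' Classify one sample by M-replica majority vote
#'
#' The sample's ternary state is rebuilt for each replica with a fresh
#' random cutoff subsample (genes outside the subsample set to 0) and
#' evolved to a class attractor; the class winning the plurality of the M
#' replica votes (over classes plus "none") is the primary call. A "none"
#' plurality or an exact tie between classes yields `"unclassified"`, as
#' does an all-zero initial state. When no class exceeds the cutoff the
#' replicas would be identical, so a single replica is run.
#'
#' @param values Numeric vector aligned to the bank's gene index.
#' @param bank Template bank.
#' @param weights Weight matrix from [hebb_weights_modified()].
#' @param signatures The signature set the bank was built from.
#' @param config A [hop_config()].
#' @param reference Cohort medians for `gene_median_log2ratio` mode.
#' @return List of class `sample_call`: `primary` (class label or
#'   `"unclassified"`), `vote_fractions` (named, classes plus `none`,
#'   summing to 1), `replicas` (number actually run), `outcomes` (list of
#'   [evolve_to_class()] results), `state0` (full binarized state).
#' @export
classify_sample <- function(values, bank, weights, signatures,
                            config = hop_config(), reference = NULL) {
  x_full <- binarize_sample(values, config$ratio_mode, reference)
  classes <- signatures$classes
  vote_levels <- c(classes, "none")
  if (all(x_full == 0L)) {
    warning("sample has an all-zero initial state; returning unclassified")
    vf <- stats::setNames(c(rep(0, length(classes)), 1), vote_levels)
    return(structure(list(primary = "unclassified", vote_fractions = vf,
                          replicas = 0L, outcomes = list(), state0 = x_full),
                     class = "sample_call"))
  }
  needs_resampling <- any(signatures$sizes > config$gamma)
  M <- if (needs_resampling) config$replicas else 1L
  outcomes <- vector("list", M)
  votes <- character(M)
  for (m in seq_len(M)) {
    x0 <- x_full
    if (needs_resampling) x0[!gamma_mask(bank, signatures, config$gamma)] <- 0L
    if (all(x0 == 0L)) {
      votes[m] <- "none"
      outcomes[m] <- list(NULL)
      next
    }
    out <- evolve_to_class(x0, bank, weights, config)
    outcomes[[m]] <- out
    votes[m] <- if (is.na(out$converged_class)) "none" else out$converged_class
  }
  tab <- table(factor(votes, levels = vote_levels))
  vf <- as.numeric(tab) / M
  names(vf) <- vote_levels
  class_votes <- vf[classes]
  top <- max(class_votes)
  primary <-
    if (top == 0 || vf[["none"]] >= top) "unclassified"
    else if (sum(class_votes == top) > 1L) "unclassified"
    else classes[which.max(class_votes)]
  structure(list(primary = primary, vote_fractions = vf, replicas = M,
                 outcomes = outcomes, state0 = x_full),
            class = "sample_call")
}

#' Secondary class of a classified sample
#'
#' Removes the primary class and all genes of its signature, rebuilds the
#' (p - 1)-class network on the remaining genes, and reruns the
#' classification. Characterizes samples that are a mixture of classes;
#' defined only for problems with at least 3 classes.
#'
#' @param values Named numeric vector over the full gene index (names are
#'   gene identifiers).
#' @param signatures Original signature set.
#' @param primary Primary class label from [classify_sample()].
#' @param config A [hop_config()].
#' @param reference Cohort medians over the full gene index (optional).
#' @return Class label, or `NA_character_` if the reduced problem is
#'   unclassified.
#' @export
secondary_class <- function(values, signatures, primary,
                            config = hop_config(), reference = NULL) {
  stopifnot(inherits(signatures, "signature_set"))
  if (identical(primary, "unclassified") || is.na(primary))
    stop("secondary class is undefined for an unclassified sample")
  if (!primary %in% signatures$classes) stop("unknown primary class: ", primary)
  if (length(signatures$classes) < 3L)
    stop("secondary class requires at least 3 classes")
  drop_genes <- signatures$genes[[primary]]
  reduced <- lapply(signatures$genes[setdiff(signatures$classes, primary)],
                    function(g) setdiff(g, drop_genes))
  if (any(lengths(reduced) == 0L))
    stop("removing the primary signature empties another class")
  red_sig <- signature_set(reduced)
  red_bank <- build_template_bank(red_sig)
  red_W <- hebb_weights_modified(red_bank)
  v <- values[red_bank$gene_index]
  r <- if (is.null(reference)) NULL else reference[red_bank$gene_index]
  call <- classify_sample(v, red_bank, red_W, red_sig, config, r)
  if (identical(call$primary, "unclassified")) NA_character_ else call$primary
}

#' Classify every sample of an expression matrix
#'
#' The full pipeline: restrict the matrix to signature genes, then for
#' each sample independently run the replica-vote classification, record
#' the initial-state network energy, build the permutation null and
#' empirical p-value (unless `n_permutations = 0`), and call the secondary
#' class for classified samples when at least 3 classes are present.
#' Benjamini-Hochberg FDR is computed across the classified samples of
#' the run. Each sample's random streams are derived from the master seed
#' and its own identifier, so a sample's call does not depend on which
#' other samples are in the matrix (except through the cohort medians in
#' `gene_median_log2ratio` mode).
#'
#' @param expr Numeric matrix, genes x samples (row/column names required).
#' @param signatures A [signature_set()].
#' @param config A [hop_config()].
#' @return A `data.frame` (one row per sample) with columns `sample_id`,
#'   `primary_class`, `vote_fraction_primary`, `secondary_class`,
#'   `unclassified`, `energy_initial`, `p_value`, `fdr`,
#'   `n_null_retained`, and one `vote_<class>` column per class plus
#'   `vote_none`. The effective master seed is attached as attribute
#'   `"seed"`.
#' @examples
#' spec <- synth_spec(samples_per_class = c(3, 3, 3), seed = 7)
#' sim <- simulate_cohort(spec)
#' cfg <- hop_config(n_permutations = 50, seed = 1)
#' res <- hop_classify(sim$expression, sim$signatures, cfg)
#' table(res$primary_class, sim$labels)
#' @export
hop_classify <- function(expr, signatures, config = hop_config()) {
  stopifnot(inherits(signatures, "signature_set"),
            inherits(config, "hop_config"))
  bank <- build_template_bank(signatures)
  weights <- hebb_weights_modified(bank)
  fx <- filter_to_signature_genes(expr, signatures)
  seed <- config$seed
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1L)
    message("no seed supplied; using generated master seed ", seed)
  }
  reference <- NULL
  if (config$ratio_mode == "gene_median_log2ratio") {
    if (ncol(fx) < 2L)
      stop("gene_median_log2ratio mode needs a multi-sample matrix to",
           " define per-gene cohort medians")
    reference <- apply(fx, 1, median, na.rm = TRUE)
    reference[is.nan(reference)] <- NA_real_
  }
  classes <- signatures$classes
  n <- ncol(fx)
  rows <- vector("list", n)
  for (j in seq_len(n)) {
    id <- colnames(fx)[j]
    v <- fx[, j]
    set.seed(derive_seed(seed, paste0("sample:", id)))
    call <- suppressWarnings(classify_sample(v, bank, weights, signatures,
                                             config, reference))
    classified <- !identical(call$primary, "unclassified")
    e0 <- state_energy(weights, call$state0)
    p_value <- NA_real_
    n_ret <- NA_integer_
    if (classified && config$n_permutations > 0L) {
      set.seed(derive_seed(seed, paste0("null:", id)))
      null <- permutation_null(v, bank, weights, signatures, config, reference)
      pv <- empirical_pvalue(e0, null, call$primary)
      p_value <- pv$p_value
      n_ret <- pv$n_retained
    }
    sec <- NA_character_
    if (classified && length(classes) >= 3L && config$secondary) {
      set.seed(derive_seed(seed, paste0("secondary:", id)))
      sec <- suppressWarnings(
        secondary_class(v, signatures, call$primary, config, reference))
    }
    vf <- call$vote_fractions
    row <- data.frame(
      sample_id = id,
      primary_class = call$primary,
      vote_fraction_primary = if (classified) vf[[call$primary]] else NA_real_,
      secondary_class = sec,
      unclassified = !classified,
      energy_initial = e0,
      p_value = p_value,
      fdr = NA_real_,
      n_null_retained = n_ret,
      stringsAsFactors = FALSE)
    for (cl in classes) row[[paste0("vote_", cl)]] <- vf[[cl]]
    row$vote_none <- vf[["none"]]
    rows[[j]] <- row
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  has_p <- !is.na(res$p_value)
  if (any(has_p)) res$fdr[has_p] <- p.adjust(res$p_value[has_p], method = "BH")
  attr(res, "seed") <- seed
  attr(res, "coverage") <- attr(fx, "coverage")
  res
}
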