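#' Build the template bank for a signature set
#'
#' The network is defined on the ordered union of all signature genes
#' (class order, first occurrence kept), of size \eqn{N}. Each class
#' \eqn{\mu} is stored as a template \eqn{\xi^\mu \in \{-1,+1\}^N} whose
#' i-th component is +1 iff gene i belongs to the signature of class
#' \eqn{\mu}. For mutually non-overlapping signatures \eqn{N = \sum_\mu
#' N_\mu} and the templates are pairwise distinct.
#'
#' @param signatures A [signature_set()].
#' @return A list of class `template_bank` with elements `gene_index`
#'   (character, length N), `templates` (N x p matrix of -1/+1, one column
#'   per class), `class_of_gene` (integer index of the first class
#'   containing each gene), `p`, `N`, `sizes`, and `overlapping` (logical:
#'   any gene shared across classes).
#' @export
build_template_bank <- function(signatures) {
  stopifnot(inherits(signatures, "signature_set"))
  p <- length(signatures$classes)
  ov <- overlap_genes(signatures)
  if (length(ov) > 0L)
    warning("signatures overlap in ", length(ov),
            " gene(s); templates are no longer a partition and the weight",
            " matrix departs from the +/- p/N block form")
  gene_index <- unique(unlist(signatures$genes, use.names = FALSE))
  N <- length(gene_index)
  templates <- matrix(-1L, nrow = N, ncol = p,
                      dimnames = list(gene_index, signatures$classes))
  class_of_gene <- integer(N)
  for (mu in seq_len(p)) {
    idx <- match(signatures$genes[[mu]], gene_index)
    templates[idx, mu] <- 1L
    unset <- class_of_gene[idx] == 0L
    class_of_gene[idx[unset]] <- mu
  }
  structure(
    list(gene_index = gene_index, templates = templates,
         class_of_gene = class_of_gene, p = p, N = N,
         sizes = signatures$sizes, overlapping = length(ov) > 0L),
    class = "template_bank")
}

#' @export
print.template_bank <- function(x, ...) {
  cat("template_bank: p =", x$p, "classes, N =", x$N, "genes",
      if (x$overlapping) "(overlapping signatures)" else "", "\n")
  invisible(x)
}

#' Classical Hebb-rule weight matrix
#'
#' \eqn{W_{ij} = \frac{1}{N}\sum_\mu \xi^\mu_i \xi^\mu_j} for \eqn{i \ne j},
#' with the diagonal forced to zero (no self-interaction). Makes the
#' patterns fixed points of the sign-rule dynamics as long as the load
#' \eqn{p/N} is below the storage capacity.
#'
#' @param patterns Matrix with one \eqn{\pm 1} pattern per column (or a
#'   list of equal-length \eqn{\pm 1} vectors).
#' @return Symmetric N x N numeric matrix with zero diagonal.
#' @export
hebb_weights_classic <- function(patterns) {
  if (is.list(patterns)) {
    len <- unique(lengths(patterns))
    if (length(len) != 1L) stop("patterns have unequal lengths")
    patterns <- do.call(cbind, patterns)
  }
  patterns <- as.matrix(patterns)
  if (ncol(patterns) < 1L) stop("at least one pattern is required")
  if (!all(patterns %in% c(-1, 1))) stop("patterns must be +/-1 valued")
  N <- nrow(patterns)
  W <- tcrossprod(patterns) / N
  diag(W) <- 0
  W
}

#' Modified Hebb-rule weight matrix for class templates
#'
#' \eqn{W_{ij} = \frac{p}{2N}\left(\sum_\mu \xi^\mu_i \xi^\mu_j + 2 - p\right)}
#' for \eqn{i \ne j}, diagonal zero. For non-overlapping signatures this is
#' a binary matrix: \eqn{W_{ij} = p/N} when genes i and j belong to the same
#' class and \eqn{-p/N} otherwise, which removes the interference caused by
#' the strong anticorrelation of partition-style templates.
#'
#' @param bank A [build_template_bank()] result.
#' @return Symmetric N x N numeric matrix with zero diagonal.
#' @export
hebb_weights_modified <- function(bank) {
  stopifnot(inherits(bank, "template_bank"))
  p <- bank$p
  N <- bank$N
  W <- (p / (2 * N)) * (tcrossprod(bank$templates) + 2 - p)
  diag(W) <- 0
  dimnames(W) <- list(bank$gene_index, bank$gene_index)
  W
}

# +/- p/N block shortcut, valid only for non-overlapping signatures;
# retained as the cross-check for the general formula above
modified_weights_block <- function(bank) {
  same <- outer(bank$class_of_gene, bank$class_of_gene, "==")
  W <- matrix(-bank$p / bank$N, bank$N, bank$N)
  W[same] <- bank$p / bank$N
  diag(W) <- 0
  dimnames(W) <- list(bank$gene_index, bank$gene_index)
  W
}

#' Ternary template state for one class
#'
#' Maps a stored \eqn{\pm 1} template to the ternary state space used by
#' the asymmetric dynamics (no zeros: every gene is active).
#'
#' @param bank A template bank.
#' @param class Class label or index.
#' @return Integer vector in \eqn{\{-1,+1\}^N} named by gene.
#' @export
template_state <- function(bank, class) {
  stopifnot(inherits(bank, "template_bank"))
  if (is.character(class)) class <- match(class, colnames(bank$templates))
  if (is.na(class) || class < 1L || class > bank$p) stop("unknown class")
  stats::setNames(as.integer(bank$templates[, class]), bank$gene_index)
}
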