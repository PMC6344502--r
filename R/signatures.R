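#' Gene-signature set
#'
#' A signature set holds one gene list per class. Signatures are the fixed
#' input of the classifier: each class \eqn{\mu} contributes \eqn{N_\mu}
#' genes, and the network is built on the union of all signature genes.
#'
#' @param genes Named list of character vectors; names are class labels,
#'   elements are the gene identifiers of each signature.
#' @return An object of class `signature_set` with elements `classes`,
#'   `genes` (named list) and `sizes` (integer vector \eqn{N_\mu}).
#' @examples
#' sig <- signature_set(list(A = c("g1", "g2", "g3"), B = c("g4", "g5", "g6")))
#' sig$sizes
#' @export
signature_set <- function(genes) {
  if (!is.list(genes) || is.null(names(genes)) || any(names(genes) == ""))
    stop("'genes' must be a named list of gene vectors (one per class)")
  if (length(genes) < 2L)
    stop("at least 2 classes are required (got ", length(genes), ")")
  genes <- lapply(genes, as.character)
  for (cl in names(genes)) {
    g <- genes[[cl]]
    if (length(g) < 1L) stop("class '", cl, "' has an empty signature")
    if (any(!nzchar(g)) || anyNA(g))
      stop("class '", cl, "' contains empty or missing gene identifiers")
    if (anyDuplicated(g))
      stop("class '", cl, "' contains duplicated genes: ",
           paste(unique(g[duplicated(g)]), collapse = ", "))
  }
  structure(
    list(classes = names(genes), genes = genes,
         sizes = stats::setNames(lengths(genes), names(genes))),
    class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat("signature_set:", length(x$classes), "classes,",
      sum(x$sizes), "genes (with multiplicity)\n")
  for (cl in x$classes)
    cat(sprintf("  %-12s N = %d\n", cl, x$sizes[[cl]]))
  invisible(x)
}

# genes appearing in more than one signature (overlapping signatures are
# tolerated but change the weight matrix away from the +/- p/N block form)
overlap_genes <- function(signatures) {
  all <- unlist(signatures$genes, use.names = FALSE)
  unique(all[duplicated(all)])
}

#' Read gene signatures from a GMT file
#'
#' Standard GMT: one gene set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. One class per line; at
#' least two lines are required. Genes duplicated within a line are dropped
#' with a warning.
#'
#' @param path Path to a GMT file.
#' @return A [signature_set()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("GMT file must contain at least 2 gene sets (classes): ", path)
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("GMT line with no genes: '", substr(ln, 1, 40), "...'")
    name <- f[1]
    g <- f[-(1:2)]
    g <- g[nzchar(g)]
    if (length(g) == 0L) stop("GMT set '", name, "' has no genes")
    if (anyDuplicated(g)) {
      warning("GMT set '", name, "': dropping duplicated genes")
      g <- unique(g)
    }
    if (name %in% names(sets)) stop("duplicated GMT set name: ", name)
    sets[[name]] <- g
  }
  signature_set(sets)
}

#' Write a signature set to a GMT file
#'
#' @param signatures A [signature_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(signatures, path) {
  stopifnot(inherits(signatures, "signature_set"))
  lines <- vapply(signatures$classes, function(cl) {
    paste(c(cl, cl, signatures$genes[[cl]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
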