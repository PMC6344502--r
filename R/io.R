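#' Read an expression matrix from delimited text
#'
#' First column gene identifiers, header row sample identifiers; the
#' delimiter (tab or comma) is auto-detected from the header line.
#' Non-numeric cells become missing with a warning; duplicated gene rows
#' are an error.
#'
#' @param path Path to a TSV/CSV file.
#' @return Numeric matrix, genes x samples.
#' @export
read_expression <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty expression file: ", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, quote = "",
                   check.names = FALSE, colClasses = "character",
                   comment.char = "")
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("expression file has no data: ", path)
  genes <- df[[1]]
  if (anyDuplicated(genes))
    stop("duplicated gene rows in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  raw <- as.matrix(df[, -1, drop = FALSE])
  vals <- raw
  suppressWarnings(storage.mode(vals) <- "double")
  n_bad <- sum(is.na(vals) & !is.na(raw) & !raw %in% c("NA", ""))
  if (n_bad > 0)
    warning(n_bad, " non-numeric cell(s) set to missing in ", path)
  rownames(vals) <- genes
  vals
}

#' Write an expression matrix as TSV
#'
#' @param expr Numeric matrix, genes x samples.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a classification results table as TSV
#'
#' @param results `data.frame` from [hop_classify()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
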