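#' Construct an expression matrix
#'
#' Wraps a genes-by-samples numeric matrix with validated identifiers and a
#' declared unit (`"raw"` read counts or `"normalized"` reads). All
#' downstream stages operate on this container.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   unique non-empty row and column names.
#' @param kind `"raw"` (non-negative integral counts) or `"normalized"`
#'   (non-negative reals).
#' @return An object of class `expr_matrix` (a numeric matrix with a
#'   `kind` attribute).
#' @examples
#' m <- matrix(c(10L, 0L, 5L, 7L, 2L, 1L), nrow = 3,
#'             dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' expression_matrix(m, "raw")
#' @export
expression_matrix <- function(values, kind = c("raw", "normalized")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    abort("`values` must be a numeric matrix")
  g <- rownames(values); s <- colnames(values)
  if (is.null(g) || is.null(s))
    abort("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(g))
    abort("duplicate gene identifier(s): %s",
          paste(unique(g[duplicated(g)]), collapse = ", "))
  if (anyDuplicated(s))
    abort("duplicate sample identifier(s): %s",
          paste(unique(s[duplicated(s)]), collapse = ", "))
  if (any(!is.finite(values)))
    abort("expression values must all be finite (missing values are not permitted)")
  if (any(values < 0))
    abort("expression values must be non-negative")
  if (kind == "raw" && any(values != round(values)))
    abort("raw counts must be integral; found fractional value(s)")
  structure(values, kind = kind, class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix [%s]: %d genes x %d samples\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  nr <- min(5L, nrow(x)); nc <- min(5L, ncol(x))
  print(unclass(x)[seq_len(nr), seq_len(nc), drop = FALSE])
  if (nrow(x) > nr || ncol(x) > nc) cat("...\n")
  invisible(x)
}

#' Expression unit of a matrix
#' @param x An `expr_matrix`.
#' @return `"raw"` or `"normalized"`.
#' @export
expr_kind <- function(x) attr(x, "kind") %||% "normalized"

#' Read a tab-separated expression matrix
#'
#' Expects genes in rows: first column gene identifiers, header row sample
#' identifiers. Lines starting with `#` are ignored. Missing or
#' non-numeric cells are rejected (never imputed), and duplicate gene
#' identifiers are a hard error naming the offender.
#'
#' @param path File path.
#' @param kind Declared unit of the values, `"raw"` or `"normalized"`.
#' @param transpose Set `TRUE` if the file stores samples in rows.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, kind = c("raw", "normalized"),
                                   transpose = FALSE) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort("expression file not found: %s", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "#", quote = "")
  if (ncol(raw) < 2L) abort("expression file needs a gene column plus >= 1 sample column")
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    abort("duplicate gene identifier in %s: %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = ncol(raw) - 1L,
                 dimnames = list(ids, colnames(raw)[-1L]))
  for (j in seq_len(ncol(vals))) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad))
      abort("non-numeric value '%s' at row %d (gene %s), column '%s' of %s",
            col[bad[1L]], bad[1L], ids[bad[1L]], colnames(vals)[j], path)
    vals[, j] <- num
  }
  if (transpose) vals <- t(vals)
  expression_matrix(vals, kind)
}

#' Write an expression matrix as tab-separated text
#'
#' Values are serialized at full double precision so that
#' `read_expression_matrix()` reproduces them exactly.
#'
#' @param x An `expr_matrix` (or plain named numeric matrix).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  if (is.null(rownames(x)) || is.null(colnames(x)))
    abort("matrix must carry gene and sample identifiers")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(x)), collapse = "\t"), con)
  for (i in seq_len(nrow(x))) {
    writeLines(paste(c(rownames(x)[i], fmt_full(x[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}
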