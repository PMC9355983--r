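#' Construct a gene set
#'
#' @param name Set name.
#' @param genes Non-empty character vector of unique gene symbols.
#' @param description Free-text description.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, genes, description = "") {
  genes <- as.character(genes)
  if (!length(genes)) abort("gene set '%s' is empty", name)
  if (anyDuplicated(genes))
    abort("gene set '%s' has duplicate genes", name)
  structure(list(name = name, description = description, genes = genes),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene set '%s' (%d genes)\n", x$name, length(x$genes)))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name TAB description TAB gene TAB ...`.
#' Duplicate genes within a line are dropped with a warning; a line with
#' fewer than three fields is a hard error reported with its line number.
#'
#' @param path GMT file path.
#' @return A list of [gene_set()] objects (empty list for an empty file).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  sets <- list()
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) next
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      abort("GMT line %d has %d field(s); need name, description and >= 1 gene",
            i, length(fields))
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warn("GMT line %d ('%s'): %d duplicate gene entr%s removed",
           i, fields[1L], sum(duplicated(genes)),
           if (sum(duplicated(genes)) == 1L) "y" else "ies")
      genes <- unique(genes)
    }
    sets[[length(sets) + 1L]] <- gene_set(fields[1L], genes, fields[2L])
  }
  sets
}

#' Construct an up/down gene signature
#'
#' A signature pairs genes expected to be elevated under pathway activation
#' with genes expected to be suppressed; the two lists must be disjoint.
#'
#' @param up_genes Character vector of up-regulated genes.
#' @param down_genes Character vector of down-regulated genes.
#' @param name Signature name.
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(up_genes, down_genes, name = "signature") {
  up <- as.character(up_genes); down <- as.character(down_genes)
  if (!length(up) || !length(down))
    abort("signature '%s': both up and down gene lists must be non-empty", name)
  if (anyDuplicated(up) || anyDuplicated(down))
    abort("signature '%s': gene lists must be unique", name)
  both <- intersect(up, down)
  if (length(both))
    abort("signature '%s': up and down lists overlap (%s)",
          name, paste(both, collapse = ", "))
  structure(list(name = name, up_genes = up, down_genes = down),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene signature '%s': %d up, %d down\n",
              x$name, length(x$up_genes), length(x$down_genes)))
  cat("  up:  ", paste(x$up_genes, collapse = " "), "\n")
  cat("  down:", paste(x$down_genes, collapse = " "), "\n")
  invisible(x)
}

#' The packaged NOTCH activation signature
#'
#' Twenty-one NOTCH target genes expected to be elevated in
#' NOTCH-activated tumors (canonical pathway targets such as the HES/HEY
#' family, NRARP, MYC, CDK6, CCND1 and KIT) and four genes expected to be
#' suppressed (LXN, RAPGEF3, TMEM154, LGR6). Shipped as a GMT under
#' `inst/extdata` so users can swap in their own curation.
#'
#' @return A [gene_signature()] with 21 up genes and 4 down genes.
#' @export
notch_signature <- function() {
  path <- system.file("extdata", "notch_signature.gmt", package = "notchcaller",
                      mustWork = TRUE)
  sets <- read_gmt(path)
  names(sets) <- vapply(sets, `[[`, "", "name")
  gene_signature(sets[["NOTCH21_UP"]]$genes, sets[["NOTCH21_DOWN"]]$genes,
                 name = "NOTCH21")
}

#' Read and validate a tumor growth table
#'
#' CSV with columns `animal`, `group`, `day`, `width`, `length` and
#' optionally `volume` (mm^3). Enforced invariants: one measurement per
#' animal per day, each animal in exactly one group and measured on at
#' least two distinct days, strictly positive caliper dimensions.
#'
#' @param path CSV file path.
#' @return A `growth_table` data frame with columns `animal_id`, `group`,
#'   `day`, `width`, `length` (and `volume` when present in the file).
#' @export
read_growth_table <- function(path) {
  if (!file.exists(path)) abort("growth table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal", "group", "day", "width", "length")
  missing <- setdiff(need, names(df))
  if (length(missing))
    abort("growth table missing column(s): %s", paste(missing, collapse = ", "))
  out <- data.frame(animal_id = as.character(df$animal),
                    group = as.character(df$group),
                    day = df$day, width = df$width, length = df$length,
                    stringsAsFactors = FALSE)
  if ("volume" %in% names(df)) out$volume <- df$volume
  as_growth_table(out)
}

#' Validate an in-memory growth table
#'
#' @param df Data frame with columns `animal_id`, `group`, `day`, `width`,
#'   `length` and optionally `volume`.
#' @return The validated `growth_table`.
#' @export
as_growth_table <- function(df) {
  need <- c("animal_id", "group", "day", "width", "length")
  missing <- setdiff(need, names(df))
  if (length(missing))
    abort("growth table missing column(s): %s", paste(missing, collapse = ", "))
  if (any(!is.finite(df$day)) || any(df$day < 0) || any(df$day != round(df$day)))
    abort("`day` must be non-negative integers")
  if (any(!is.finite(df$width)) || any(df$width <= 0))
    abort("`width` must be positive (mm)")
  if (any(!is.finite(df$length)) || any(df$length <= 0))
    abort("`length` must be positive (mm)")
  key <- paste(df$animal_id, df$day, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE]
    abort("duplicate (animal, day) measurement: animal %s day %s",
          d$animal_id[1L], d$day[1L])
  }
  gpa <- tapply(df$group, df$animal_id, function(g) length(unique(g)))
  if (any(gpa > 1L))
    abort("animal(s) assigned to more than one group: %s",
          paste(names(gpa)[gpa > 1L], collapse = ", "))
  dpa <- tapply(df$day, df$animal_id, function(d) length(unique(d)))
  if (any(dpa < 2L))
    abort("animal(s) with fewer than two measurement days: %s",
          paste(names(dpa)[dpa < 2L], collapse = ", "))
  class(df) <- c("growth_table", "data.frame")
  df
}

#' Validate an in-memory qPCR Ct table
#'
#' Each (sample, condition) must carry exactly one reference-gene Ct row
#' (`is_reference = TRUE`); all Ct values must be finite.
#'
#' @param df Data frame with columns `sample_id`, `condition` (`"control"`
#'   or `"treated"`), `gene`, `ct`, `is_reference`.
#' @return The validated `ct_table`.
#' @export
as_ct_table <- function(df) {
  need <- c("sample_id", "condition", "gene", "ct", "is_reference")
  missing <- setdiff(need, names(df))
  if (length(missing))
    abort("Ct table missing column(s): %s", paste(missing, collapse = ", "))
  if (!all(df$condition %in% c("control", "treated")))
    abort("`condition` must be 'control' or 'treated'")
  if (any(!is.finite(df$ct))) abort("all Ct values must be finite")
  key <- paste(df$sample_id, df$condition, sep = "\r")
  nref <- tapply(df$is_reference, key, sum)
  bad <- names(nref)[nref != 1L]
  if (length(bad))
    abort("each (sample, condition) needs exactly one reference-gene Ct; violated for: %s",
          paste(gsub("\r", "/", bad), collapse = ", "))
  class(df) <- c("ct_table", "data.frame")
  df
}

#' Read a qPCR Ct table from CSV
#' @param path CSV with columns `sample_id`, `condition`, `gene`, `ct`,
#'   `is_reference`.
#' @return A validated `ct_table`.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) abort("Ct table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("is_reference" %in% names(df)) df$is_reference <- as.logical(df$is_reference)
  as_ct_table(df)
}

#' Write a result table as TSV or JSON
#'
#' Column order is preserved; floating-point columns are rounded to
#' `digits` significant digits before serialization so both formats carry
#' the same values.
#'
#' @param table A data frame.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @param digits Significant digits for numeric columns (default 6).
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path, format = c("tsv", "json"), digits = 6) {
  format <- match.arg(format)
  if (!is.data.frame(table)) abort("`table` must be a data frame")
  for (j in seq_along(table)) {
    if (is.double(table[[j]])) table[[j]] <- signif(table[[j]], digits)
  }
  ok <- tryCatch(suppressWarnings({
    if (format == "tsv") {
      utils::write.table(table, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    } else {
      jsonlite::write_json(table, path, dataframe = "rows", digits = NA,
                           auto_unbox = TRUE, pretty = TRUE)
    }
    TRUE
  }), error = function(e) FALSE)
  if (!ok) abort("cannot write results to %s", path)
  invisible(path)
}
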