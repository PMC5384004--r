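#' Read a genes-by-samples expression table
#'
#' Reads a tab-separated expression table with gene identifiers in the first
#' column and one header row of sample identifiers.  Values are expected on
#' the log2 scale (the downstream Cox-filter model treats a 1-unit change as
#' a doubling of expression).
#'
#' @param path Path to a tab-separated text file.
#' @param transpose Logical; set `TRUE` when the file stores samples in rows
#'   and genes in columns.
#' @return A numeric matrix (genes x samples) with unique, non-empty
#'   `rownames` (genes) and `colnames` (samples), no missing values.
#' @export
read_expression <- function(path, transpose = FALSE) {
  if (!file.exists(path))
    stop("expression file '", path, "' not found")
  raw <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t",
                      check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e)
      stop("expression file '", path, "' is empty or unreadable: ",
           conditionMessage(e)))
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("expression file '", path, "' is empty or has no sample columns")
  ids <- as.character(raw[[1L]])
  body <- raw[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      stop("non-numeric expression value at row ", bad[1L],
           ", column '", colnames(body)[j], "' of '", path, "'")
    }
  }
  x <- as.matrix(body)
  rownames(x) <- ids
  if (transpose) x <- t(x)
  validate_expression(x)
}

#' @keywords internal
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix needs gene rownames and sample colnames")
  dup <- rownames(x)[duplicated(rownames(x))]
  if (length(dup))
    stop("duplicate gene id in expression matrix: '", dup[1L], "'")
  dup <- colnames(x)[duplicated(colnames(x))]
  if (length(dup))
    stop("duplicate sample id in expression matrix: '", dup[1L], "'")
  if (any(!is.finite(x)))
    stop("expression matrix contains missing or non-finite values")
  x
}

#' Write an expression matrix as tab-separated text
#'
#' Inverse of [read_expression()]; the first column is named `gene_id`.
#'
#' @param x Numeric genes-by-samples matrix with dimnames.
#' @param path Output path.
#' @export
write_expression <- function(x, path) {
  validate_expression(x)
  # %.17g so that write -> read is the identity at full double precision
  chr <- matrix(sprintf("%.17g", x), nrow(x), ncol(x))
  lines <- c(paste(c("gene_id", colnames(x)), collapse = "\t"),
             paste(rownames(x), apply(chr, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical table (sample, follow-up time, event, subtype)
#'
#' Expects a tab-separated file with a header and columns `sample_id`,
#' `time`, `event`, `subtype`.  Subtype labels are matched
#' case-insensitively against `AC` and `SCC`.
#'
#' @param path Path to a tab-separated text file.
#' @return A `data.frame` with columns `sample_id` (character), `time`
#'   (positive numeric), `event` (0/1 integer) and `subtype` (factor with
#'   levels `AC`, `SCC`).
#' @export
read_clinical <- function(path) {
  if (!file.exists(path))
    stop("clinical file '", path, "' not found")
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event", "subtype")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("clinical file '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  validate_clinical(df[need])
}

#' @keywords internal
validate_clinical <- function(df) {
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in clinical table: '",
         df$sample_id[duplicated(df$sample_id)][1L], "'")
  df$time <- as.numeric(df$time)
  if (any(!is.finite(df$time)) || any(df$time <= 0))
    stop("clinical 'time' must be finite and > 0")
  ev <- as.numeric(df$event)
  if (any(!ev %in% c(0, 1)))
    stop("clinical 'event' must be 0 (censored) or 1 (death observed)")
  df$event <- as.integer(ev)
  sub <- toupper(trimws(as.character(df$subtype)))
  bad <- setdiff(unique(sub), c("AC", "SCC"))
  if (length(bad))
    stop("unknown subtype label '", bad[1L], "' (expected AC or SCC)")
  df$subtype <- factor(sub, levels = c("AC", "SCC"))
  rownames(df) <- NULL
  df
}

#' Write a clinical table as tab-separated text
#'
#' Inverse of [read_clinical()].
#'
#' @param clinical Clinical `data.frame`.
#' @param path Output path.
#' @export
write_clinical <- function(clinical, path) {
  clinical <- validate_clinical(clinical)
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Parses the MSigDB-style GMT dialect: one set per line,
#' `set_name<TAB>description<TAB>gene1<TAB>gene2...`.  Duplicate genes
#' within a set are removed (first occurrence kept); gene symbols are taken
#' verbatim (case-sensitive, no alias resolution).
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of gene symbols, in file
#'   order, with a `description` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path))
    stop("GMT file '", path, "' not found")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("GMT file '", path, "' is empty")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop("GMT line ", which(nf < 3L)[1L], " has fewer than 3 fields")
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene-set name in GMT: '", nm[duplicated(nm)][1L], "'")
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  if (any(lengths(sets) == 0L))
    stop("GMT line ", which(lengths(sets) == 0L)[1L], " defines an empty set")
  names(sets) <- nm
  attr(sets, "description") <- stats::setNames(vapply(parts, `[[`, "", 2L), nm)
  sets
}

#' Write a gene-set collection in GMT format
#'
#' @param sets Named list of character vectors (optionally with a
#'   `description` attribute as produced by [read_gmt()]).
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("gene sets must have unique names")
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], unique(sets[[nm]])), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Align an expression matrix with a clinical table on shared samples
#'
#' Samples present in only one of the two inputs are dropped with a
#' warning; an empty intersection is an error.  Column order of the
#' expression matrix (restricted to shared samples) is preserved.
#'
#' @param expr Genes-by-samples numeric matrix.
#' @param clinical Clinical `data.frame` as from [read_clinical()].
#' @return A list with components `expr` and `clinical`, sample-aligned
#'   (clinical rows in expression column order).
#' @export
align_cohort <- function(expr, clinical) {
  expr <- validate_expression(expr)
  clinical <- validate_clinical(clinical)
  shared <- intersect(colnames(expr), clinical$sample_id)
  if (!length(shared))
    stop("no samples shared between expression and clinical tables")
  drop_e <- setdiff(colnames(expr), shared)
  drop_c <- setdiff(clinical$sample_id, shared)
  if (length(drop_e) || length(drop_c))
    warning(length(drop_e), " expression-only and ", length(drop_c),
            " clinical-only sample(s) dropped during alignment")
  keep <- colnames(expr)[colnames(expr) %in% shared]
  expr <- expr[, keep, drop = FALSE]
  clinical <- clinical[match(keep, clinical$sample_id), , drop = FALSE]
  rownames(clinical) <- NULL
  list(expr = expr, clinical = clinical)
}
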