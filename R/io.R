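#' Protein-name to gene-symbol alias table
#'
#' Several immune checkpoint genes are best known by their protein names
#' (PD-1, PD-L1, PD-L2, CTLA-4, LAG-3, TIM-3) while expression matrices carry
#' HGNC gene symbols (PDCD1, CD274, PDCD1LG2, CTLA4, LAG3, HAVCR2).  The
#' loaders apply this table so gene sets written with either naming convention
#' match the matrix.
#'
#' @return Named character vector mapping alias to canonical gene symbol.
#' @export
#' @examples
#' gene_aliases()[["PD-1"]]
gene_aliases <- function() {
  c(
    "PD-1"   = "PDCD1",
    "PD1"    = "PDCD1",
    "PD-L1"  = "CD274",
    "PDL1"   = "CD274",
    "PD-L2"  = "PDCD1LG2",
    "PDL2"   = "PDCD1LG2",
    "CTLA-4" = "CTLA4",
    "LAG-3"  = "LAG3",
    "TIM-3"  = "HAVCR2",
    "TIM3"   = "HAVCR2"
  )
}

#' Resolve gene aliases to canonical symbols
#'
#' @param genes Character vector of gene symbols or protein aliases.
#' @return Character vector with known aliases replaced by gene symbols;
#'   unrecognised names are returned unchanged (after whitespace trimming).
#' @export
resolve_gene_aliases <- function(genes) {
  genes <- trimws(genes)
  al <- gene_aliases()
  hit <- genes %in% names(al)
  genes[hit] <- unname(al[genes[hit]])
  genes
}

#' Validate an expression matrix
#'
#' An expression matrix is a numeric matrix of non-negative, finite,
#' linear-scale values with unique gene symbols as row names and unique
#' sample identifiers as column names, at least 2 genes and 1 sample.
#'
#' @param m Numeric matrix, genes in rows, samples in columns.
#' @return `m`, invisibly, if valid; otherwise an error naming the offending
#'   gene and sample.
#' @export
validate_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix must have gene row names and sample column names",
         call. = FALSE)
  }
  if (nrow(m) < 2L || ncol(m) < 1L) {
    stop("expression matrix needs at least 2 genes and 1 sample", call. = FALSE)
  }
  dup_g <- unique(rownames(m)[duplicated(rownames(m))])
  if (length(dup_g)) {
    stop("duplicated gene symbol(s): ", paste(dup_g, collapse = ", "),
         call. = FALSE)
  }
  dup_s <- unique(colnames(m)[duplicated(colnames(m))])
  if (length(dup_s)) {
    stop("duplicated sample id(s): ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "negative or non-finite value for gene '%s', sample '%s'",
      rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]
    ), call. = FALSE)
  }
  invisible(m)
}

#' Read a gene-by-sample expression matrix from tab-separated text
#'
#' Expects the first row to hold sample identifiers and the first column gene
#' symbols; all values must be non-negative finite numbers on a linear scale.
#'
#' @param path Path to a TSV file.
#' @param resolve_aliases Apply [gene_aliases()] to row names (default TRUE).
#' @return Numeric matrix (genes x samples) passing
#'   [validate_expression_matrix()].
#' @export
read_expression_matrix <- function(path, resolve_aliases = TRUE) {
  df <- tryCatch(
    read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
               stringsAsFactors = FALSE),
    error = function(e) {
      stop(sprintf("failed to parse '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  if (ncol(df) < 2L) {
    stop(sprintf("'%s': expected gene column plus at least one sample", path),
         call. = FALSE)
  }
  genes <- trimws(as.character(df[[1L]]))
  if (resolve_aliases) genes <- resolve_gene_aliases(genes)
  vals <- df[, -1L, drop = FALSE]
  non_num <- !vapply(vals, is.numeric, logical(1L))
  if (any(non_num)) {
    # locate the first offending cell for the error message
    col <- names(vals)[which(non_num)[1L]]
    bad_row <- which(is.na(suppressWarnings(as.numeric(vals[[col]]))))[1L]
    stop(sprintf("'%s': non-numeric value at line %d, sample '%s'",
                 path, bad_row + 1L, col), call. = FALSE)
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  validate_expression_matrix(m)
  m
}

#' Write an expression matrix as tab-separated text
#'
#' @param m Expression matrix (genes x samples).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  validate_expression_matrix(m)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.  Duplicate genes within a
#' line are collapsed with a warning.
#'
#' @param path Path to a GMT file.
#' @param resolve_aliases Apply [gene_aliases()] to member genes.
#' @return Named list of gene sets; each element is a list with `name`,
#'   `description` and `genes` (character vector).
#' @export
read_gmt <- function(path, resolve_aliases = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("'%s' line %d: expected at least 3 tab-separated fields",
                   path, i), call. = FALSE)
    }
    genes <- trimws(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (resolve_aliases) genes <- resolve_gene_aliases(genes)
    if (anyDuplicated(genes)) {
      warning(sprintf("'%s' line %d ('%s'): duplicate genes collapsed",
                      path, i, fields[[1L]]), call. = FALSE)
      genes <- unique(genes)
    }
    if (!length(genes)) {
      stop(sprintf("'%s' line %d: gene set '%s' is empty", path, i,
                   fields[[1L]]), call. = FALSE)
    }
    sets[[i]] <- list(name = fields[[1L]], description = fields[[2L]],
                      genes = genes)
  }
  names(sets) <- vapply(sets, `[[`, character(1L), "name")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets List of gene sets as returned by [read_gmt()], or a named list
#'   of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (is.character(s)) {
      s <- list(name = names(sets)[[i]], description = "", genes = s)
    }
    paste(c(s$name, s$description, s$genes), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample metadata table
#'
#' A TSV with a header; must contain a `sample_id` column.  Recognised
#' optional columns: `tissue`, `condition` (tumor/normal), `arm`
#' (anti-PD-1 / anti-CTLA-4 / none), `response`
#' (responder / non-responder / not-applicable), `pathology_score` (ordinal
#' 0-3), `true_infiltration` (synthetic cohorts only).
#'
#' @param path Path to a TSV file.
#' @return A data.frame, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) {
    stop(sprintf("'%s': metadata requires a 'sample_id' column", path),
         call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop(sprintf("'%s': duplicated sample_id values", path), call. = FALSE)
  }
  df
}

#' Write a sample metadata table
#'
#' @param meta Data.frame with a `sample_id` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict matrices to their common gene universe
#'
#' Mirrors the restriction of heterogeneous datasets to a shared protein-coding
#' universe before any cross-dataset scoring: every returned matrix contains
#' exactly the genes present in all inputs, in the gene order of the first
#' matrix; sample columns are untouched.
#'
#' @param matrices List of >= 2 expression matrices.
#' @return List of matrices restricted to the common genes.
#' @export
intersect_universe <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 2L) {
    stop("need at least 2 matrices", call. = FALSE)
  }
  for (m in matrices) validate_expression_matrix(m)
  common <- Reduce(intersect, lapply(matrices, rownames))
  if (length(common) < 2L) {
    stop("gene universe intersection has fewer than 2 genes", call. = FALSE)
  }
  message(sprintf("common gene universe: %d genes", length(common)))
  # keep the first matrix's ordering for all outputs
  common <- rownames(matrices[[1L]])[rownames(matrices[[1L]]) %in% common]
  lapply(matrices, function(m) m[common, , drop = FALSE])
}

#' Combine two expression tables, preferring the first on sample overlap
#'
#' When a cohort is assembled from two tables that may share patients, the
#' row from the primary table wins; genes are restricted to those present in
#' both tables.
#'
#' @param primary,secondary Expression matrices.
#' @return Combined matrix over the common genes; all primary samples plus
#'   secondary samples not already present.
#' @export
combine_cohorts <- function(primary, secondary) {
  validate_expression_matrix(primary)
  validate_expression_matrix(secondary)
  common <- intersect(rownames(primary), rownames(secondary))
  if (length(common) < 2L) {
    stop("fewer than 2 genes shared between the two tables", call. = FALSE)
  }
  extra <- setdiff(colnames(secondary), colnames(primary))
  out <- cbind(primary[common, , drop = FALSE],
               secondary[common, extra, drop = FALSE])
  validate_expression_matrix(out)
  out
}
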