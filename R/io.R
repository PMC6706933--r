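#' Construct a screen count container
#'
#' Bundles a guide-by-sample matrix of sequencing read counts with the
#' guide-to-gene mapping and (optionally) the assignment of samples to the
#' control and treated arms. This is the object every scoring function in the
#' package consumes.
#'
#' @param guide_id Character vector of unique guide (gRNA) identifiers, one
#'   per row of `counts`.
#' @param gene Character vector of gene symbols, parallel to `guide_id`.
#'   Identifiers are treated as opaque case-sensitive strings; no symbol
#'   normalization is performed.
#' @param counts Numeric matrix of non-negative read counts, guides in rows
#'   and samples in columns. Column names are the sample names.
#' @param control_samples,treated_samples Optional character vectors naming
#'   the columns of `counts` belonging to the untreated control arm and the
#'   drug-treated arm. In a paired design the i-th control sample is the
#'   matched partner of the i-th treated sample.
#'
#' @return An object of class `screen_counts`: a list with elements
#'   `guide_id`, `gene`, `counts`, `sample_names`, `control_samples`,
#'   `treated_samples`.
#' @export
screen_counts <- function(guide_id, gene, counts, control_samples = NULL,
                          treated_samples = NULL) {
  guide_id <- as.character(guide_id)
  gene <- as.character(gene)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"

  if (length(guide_id) != nrow(counts) || length(gene) != nrow(counts))
    stop("guide_id, gene and counts rows must have equal length")
  dup <- unique(guide_id[duplicated(guide_id)])
  if (length(dup) > 0)
    stop("duplicate guide_id values: ", paste(dup, collapse = ", "))
  if (is.null(colnames(counts)))
    stop("counts must have column (sample) names")
  if (anyNA(counts))
    stop("counts contain missing values")
  bad <- which(counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("negative count at row ", bad[1, 1], " (guide '",
         guide_id[bad[1, 1]], "'), sample '", colnames(counts)[bad[1, 2]], "'")

  for (arm in list(control_samples, treated_samples)) {
    if (!is.null(arm)) {
      missing <- setdiff(arm, colnames(counts))
      if (length(missing) > 0)
        stop("sample column(s) not found: ", paste(missing, collapse = ", "),
             "; available: ", paste(colnames(counts), collapse = ", "))
    }
  }

  rownames(counts) <- guide_id
  structure(
    list(guide_id = guide_id, gene = gene, counts = counts,
         sample_names = colnames(counts),
         control_samples = control_samples,
         treated_samples = treated_samples),
    class = "screen_counts"
  )
}

#' @export
print.screen_counts <- function(x, ...) {
  cat("screen_counts:", nrow(x$counts), "guides,",
      length(unique(x$gene)), "genes,", ncol(x$counts), "samples\n")
  if (!is.null(x$control_samples))
    cat("  control:", paste(x$control_samples, collapse = ", "), "\n")
  if (!is.null(x$treated_samples))
    cat("  treated:", paste(x$treated_samples, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.screen_counts <- function(x) dim(x$counts)

#' Read a tab-delimited guide count table
#'
#' Reads the standard screen count format: a header row, one row per guide,
#' a guide identifier column, a gene symbol column and one integer read-count
#' column per sequenced sample. Columns not named in `sample_columns` are
#' ignored, so tables carrying extra annotation columns are accepted as-is.
#'
#' @param path Path to a UTF-8, tab-separated file with a header row.
#' @param gene_column Name of the gene symbol column (default `"GENE"`).
#' @param sample_columns Character vector of count column names, in the order
#'   they should be kept. `NULL` keeps every column other than the guide and
#'   gene columns.
#' @param guide_column Name of the guide identifier column. `NULL` (default)
#'   uses the first column of the file.
#' @param control_samples,treated_samples Optional arm assignments, passed on
#'   to [screen_counts()].
#'
#' @return A [screen_counts] object. Guides with all-zero counts are retained;
#'   any filtering is an explicit option of the scoring functions (the
#'   pseudocount already guards against division by zero).
#' @export
read_count_table <- function(path, gene_column = "GENE", sample_columns = NULL,
                             guide_column = NULL, control_samples = NULL,
                             treated_samples = NULL) {
  if (!file.exists(path))
    stop("input file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  if (is.null(guide_column)) guide_column <- colnames(tab)[1]
  for (col in c(guide_column, gene_column, sample_columns)) {
    if (!col %in% colnames(tab))
      stop("column '", col, "' not found in ", path,
           "; available: ", paste(colnames(tab), collapse = ", "))
  }
  if (is.null(sample_columns))
    sample_columns <- setdiff(colnames(tab), c(guide_column, gene_column))
  if (length(sample_columns) == 0)
    stop("no sample columns in ", path)

  counts <- matrix(NA_real_, nrow(tab), length(sample_columns),
                   dimnames = list(NULL, sample_columns))
  for (col in sample_columns) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (anyNA(v)) {
      row <- which(is.na(v))[1]
      stop("non-numeric count '", tab[[col]][row], "' in column '", col,
           "', row ", row)
    }
    if (any(v < 0)) {
      row <- which(v < 0)[1]
      stop("negative count ", v[row], " in column '", col, "', row ", row)
    }
    counts[, col] <- v
  }

  screen_counts(guide_id = tab[[guide_column]], gene = tab[[gene_column]],
                counts = counts, control_samples = control_samples,
                treated_samples = treated_samples)
}

#' Read a gene-set file
#'
#' One gene symbol per line; blank lines and lines starting with `#` are
#' ignored, as is anything after a `#` on a line.
#'
#' @param path Path to the gene-set file.
#' @param name Optional set name; defaults to the file name.
#' @return An object of class `gene_set`: a list with `name` and a unique
#'   character vector `members`.
#' @export
read_gene_set <- function(path, name = NULL) {
  if (!file.exists(path))
    stop("gene-set file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  members <- unique(lines[nzchar(lines)])
  if (length(members) == 0)
    stop("gene set in ", path, " is empty")
  gene_set(members, name = if (is.null(name)) basename(path) else name)
}

#' Construct a gene set
#'
#' @param members Character vector of gene symbols (made unique).
#' @param name Set name.
#' @return A `gene_set` object.
#' @export
gene_set <- function(members, name = "gene_set") {
  members <- unique(as.character(members))
  members <- members[nzchar(members)]
  if (length(members) == 0) stop("gene set members must be non-empty")
  structure(list(name = name, members = members), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set '", x$name, "': ", length(x$members), " genes\n", sep = "")
  invisible(x)
}

# canonical gene-result column order; extra columns (e.g. drugGS posterior sd)
# are written after these
.gene_result_columns <- c("GENE", "sumZ", "numObs", "normZ",
                          "pval_synth", "rank_synth", "fdr_synth",
                          "pval_supp", "rank_supp", "fdr_supp")

#' Write a gene-level result table
#'
#' Writes the stable tab-delimited output contract: header
#' `GENE sumZ numObs normZ pval_synth rank_synth fdr_synth pval_supp
#' rank_supp fdr_supp`, one row per gene, rows ordered by ascending normZ
#' (most synergistic first), floating values with at least six significant
#' digits. Any additional columns in `results` are appended after the
#' canonical ones.
#'
#' @param results A `gene_results` data frame as returned by [drugz()] or
#'   [druggs()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_results <- function(results, path) {
  if (is.null(results) || nrow(results) == 0)
    stop("results must be non-empty")
  missing <- setdiff(.gene_result_columns, colnames(results))
  if (length(missing) > 0)
    stop("results lack required column(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(colnames(results), .gene_result_columns)
  results <- results[order(results$normZ, results$GENE),
                     c(.gene_result_columns, extra), drop = FALSE]
  out <- results
  for (col in colnames(out)) {
    if (is.double(out[[col]]))
      out[[col]] <- formatC(out[[col]], digits = 8, format = "g")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read back a gene-level result table
#'
#' Inverse of [write_gene_results()]; used by the enrichment command line to
#' score previously written (or externally produced) result tables.
#'
#' @param path Path to a tab-delimited gene result file.
#' @return A `gene_results` data frame.
#' @export
read_gene_results <- function(path) {
  if (!file.exists(path))
    stop("results file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(.gene_result_columns, colnames(tab))
  if (length(missing) > 0)
    stop("results file lacks required column(s): ",
         paste(missing, collapse = ", "))
  class(tab) <- c("gene_results", "data.frame")
  tab
}
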