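#' Genes called at an FDR threshold in one direction
#'
#' @param results A `gene_results` data frame from [drugz()] or [druggs()].
#' @param direction `"synergy"` (negative-normZ tail) or `"suppressor"`
#'   (positive tail).
#' @param fdr_threshold Threshold in (0, 1]. Genes with the chosen
#'   direction's FDR strictly below the threshold are returned; a threshold
#'   of 1 returns every gene.
#' @return Character vector of gene symbols ordered by that direction's rank
#'   (most significant first).
#' @export
hits_at_fdr <- function(results, direction = c("synergy", "suppressor"),
                        fdr_threshold = 0.05) {
  direction <- match.arg(direction)
  if (!is.numeric(fdr_threshold) || fdr_threshold <= 0 || fdr_threshold > 1)
    stop("fdr_threshold must lie in (0, 1]")
  fdr_col <- if (direction == "synergy") "fdr_synth" else "fdr_supp"
  rank_col <- if (direction == "synergy") "rank_synth" else "rank_supp"
  sel <- if (fdr_threshold >= 1) rep(TRUE, nrow(results))
         else results[[fdr_col]] < fdr_threshold
  hits <- results[sel, , drop = FALSE]
  hits$GENE[order(hits[[rank_col]])]
}

#' Hypergeometric over-representation of an annotated set in a hit list
#'
#' Upper-tail hypergeometric probability of seeing at least the observed
#' number of annotated genes among the hits, drawing without replacement
#' from the universe. Only annotated genes present in the universe count as
#' the annotated pool.
#'
#' @param hits Character vector of hit genes (must be a subset of
#'   `universe`).
#' @param annotated A [gene_set] or character vector of annotated genes.
#' @param universe Character vector of all scored genes.
#' @return The enrichment p-value `P[X >= k]`.
#' @export
hypergeom_enrichment <- function(hits, annotated, universe) {
  if (inherits(annotated, "gene_set")) annotated <- annotated$members
  universe <- unique(as.character(universe))
  if (length(universe) == 0)
    stop("universe is empty")
  hits <- unique(as.character(hits))
  outside <- setdiff(hits, universe)
  if (length(outside) > 0)
    stop("hit gene(s) not in universe: ", paste(outside, collapse = ", "))
  pool <- intersect(annotated, universe)
  k <- length(intersect(hits, pool))
  stats::phyper(k - 1, m = length(pool), n = length(universe) - length(pool),
                k = length(hits), lower.tail = FALSE)
}

#' Hit counts and enrichment across a ladder of FDR thresholds
#'
#' For each threshold: the number of hits in the chosen direction, how many
#' of them belong to the annotated set, and the hypergeometric enrichment
#' p-value of that overlap against the universe of all scored genes. This is
#' the standard benchmark of hit quality: a good scorer produces hit lists
#' that stay strongly enriched for the expected pathway as the threshold is
#' relaxed.
#'
#' @param results A `gene_results` data frame.
#' @param annotated A [gene_set] or character vector of annotated genes.
#' @param thresholds Ascending numeric vector of FDR thresholds in (0, 1].
#' @param direction `"synergy"` or `"suppressor"`.
#' @return An `enrichment_report` data frame with columns `fdr_threshold`,
#'   `n_hits`, `n_hits_in_set`, `pval`, `neg_log10_p`.
#' @export
enrichment_curve <- function(results, annotated, thresholds = c(0.01, 0.05, 0.1, 0.25, 0.5),
                             direction = c("synergy", "suppressor")) {
  direction <- match.arg(direction)
  if (is.unsorted(thresholds))
    stop("thresholds must be sorted ascending")
  if (inherits(annotated, "gene_set")) annotated <- annotated$members
  universe <- unique(results$GENE)
  pool <- intersect(annotated, universe)

  rows <- lapply(thresholds, function(th) {
    hits <- hits_at_fdr(results, direction, th)
    p <- hypergeom_enrichment(hits, pool, universe)
    data.frame(fdr_threshold = th, n_hits = length(hits),
               n_hits_in_set = length(intersect(hits, pool)),
               pval = p, neg_log10_p = -log10(p))
  })
  report <- do.call(rbind, rows)
  class(report) <- c("enrichment_report", "data.frame")
  report
}

#' Write an enrichment report
#'
#' @param report An `enrichment_report` from [enrichment_curve()].
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_enrichment_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
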