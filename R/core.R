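#' Configuration for the drugZ scoring pipeline
#'
#' @param pseudocount Positive real added to normalized reads in both the
#'   numerator and denominator of the fold change (default 5). Keeps the log
#'   ratio finite for guides that drop to zero reads.
#' @param norm_target Total read count each sample is scaled to before fold
#'   changes are taken (default 1e7 reads).
#' @param window_size Number of guides, ranked by control read count, whose
#'   fold changes are pooled to estimate each guide's fold-change standard
#'   deviation (default 1000). Must be at least 2.
#' @param monotone_filter If `TRUE` (default) the estimated standard
#'   deviation is constrained to be non-decreasing as control read count
#'   decreases, via a running maximum down the abundance ranking.
#' @param paired If `TRUE` (default) each treated sample is compared to its
#'   positionally matched control sample, giving one fold-change column per
#'   replicate. If `FALSE`, the mean of the normalized treated columns is
#'   compared to the mean of the normalized control columns (single fold
#'   change).
#' @param min_control_reads Guides whose raw control reads fall below this
#'   threshold in a replicate are dropped from that replicate (default 0,
#'   i.e. no filtering — all-zero guides are retained).
#' @param remove_genes Optional character vector of gene symbols to exclude
#'   from the analysis.
#'
#' @return A `drugz_config` list.
#' @export
drugz_config <- function(pseudocount = 5, norm_target = 1e7,
                         window_size = 1000, monotone_filter = TRUE,
                         paired = TRUE, min_control_reads = 0,
                         remove_genes = NULL) {
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be > 0")
  if (!is.numeric(norm_target) || norm_target <= 0)
    stop("norm_target must be > 0")
  if (!is.numeric(window_size) || window_size < 2)
    stop("window_size must be an integer >= 2")
  if (min_control_reads < 0)
    stop("min_control_reads must be >= 0")
  structure(
    list(pseudocount = pseudocount, norm_target = norm_target,
         window_size = as.integer(window_size),
         monotone_filter = isTRUE(monotone_filter), paired = isTRUE(paired),
         min_control_reads = min_control_reads,
         remove_genes = remove_genes),
    class = "drugz_config"
  )
}

#' Depth-normalize a read-count column
#'
#' Scales a sample's counts so their total equals `norm_target` reads,
#' removing library-size differences between samples before fold changes are
#' taken.
#'
#' @param x Numeric vector of raw counts for one sample.
#' @param norm_target Target total (default 1e7).
#' @param sample Sample name, used in the error message for an all-zero
#'   column.
#' @return Numeric vector summing to `norm_target`.
#' @export
normalize_counts <- function(x, norm_target = 1e7, sample = "sample") {
  total <- sum(x)
  if (!is.finite(total) || total <= 0)
    stop("cannot normalize '", sample, "': total read count is ", total)
  x * (norm_target / total)
}

#' Log2 fold change of treated over control with a pseudocount
#'
#' `fc_i = log2((treated_i + pseudocount) / (control_i + pseudocount))` on
#' depth-normalized reads. The pseudocount keeps every fold change finite.
#'
#' @param treated_norm,control_norm Normalized read vectors of equal length.
#' @param pseudocount Positive real (default 5).
#' @return Numeric vector of log2 fold changes.
#' @export
compute_fold_change <- function(treated_norm, control_norm, pseudocount = 5) {
  if (length(treated_norm) != length(control_norm))
    stop("treated and control columns differ in length (",
         length(treated_norm), " vs ", length(control_norm), ")")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  log2((treated_norm + pseudocount) / (control_norm + pseudocount))
}

#' Empirical-Bayes fold-change standard deviation
#'
#' Guides are ranked by control read count (descending, ties broken by `ids`
#' for determinism). Each guide's fold-change standard deviation is estimated
#' as the root mean square — about zero, not about the window mean — of the
#' fold changes of the `window_size` guides nearest to it in the ranking.
#' Windows are centered on the guide's rank and clamped at both ends of the
#' ranking, so edge guides share the first or last full window. With
#' `monotone_filter = TRUE` a running maximum down the ranking enforces that
#' the estimate never decreases as read count decreases (low-count guides are
#' never assigned less variance than better-measured ones).
#'
#' If a window's fold changes are all zero the raw estimate is zero; such
#' values are replaced by the smallest positive estimate in the sample so the
#' downstream Z-score stays defined. In a wholly null sample (all fold
#' changes zero) the zeros are returned unchanged and the caller is expected
#' to treat the guides as null.
#'
#' @param fc Numeric vector of log2 fold changes.
#' @param control_norm Numeric vector of normalized control reads, parallel
#'   to `fc`.
#' @param window_size Window width N in guides (>= 2). Samples with fewer
#'   than N guides use a single window containing every guide.
#' @param monotone_filter Apply the running-maximum constraint (default
#'   `TRUE`).
#' @param ids Optional vector used to break ties in the ranking (default: the
#'   original row position, which makes the stable sort deterministic).
#' @return Numeric vector of standard-deviation estimates in the original
#'   row order.
#' @export
estimate_eb_std <- function(fc, control_norm, window_size = 1000,
                            monotone_filter = TRUE, ids = NULL) {
  n <- length(fc)
  if (length(control_norm) != n)
    stop("fc and control_norm differ in length")
  if (window_size < 2)
    stop("window_size must be >= 2")
  if (is.null(ids)) ids <- seq_len(n)

  ord <- order(-control_norm, ids)
  fc_sorted <- fc[ord]
  N <- min(as.integer(window_size), n)
  half <- N %/% 2

  csum2 <- cumsum(fc_sorted^2)
  ranks <- seq_len(n)
  start <- pmin(pmax(ranks - half, 1L), n - N + 1L)
  end <- start + N - 1L
  winsum <- csum2[end] - c(0, csum2)[start]
  std_sorted <- sqrt(pmax(winsum, 0) / N)

  if (isTRUE(monotone_filter)) std_sorted <- cummax(std_sorted)

  pos <- std_sorted[std_sorted > 0]
  if (length(pos) > 0 && any(std_sorted == 0))
    std_sorted[std_sorted == 0] <- min(pos)

  out <- numeric(n)
  out[ord] <- std_sorted
  out
}

#' Guide-level Z-scores
#'
#' `z_i = fc_i / eb_std_i`. Errors rather than returning infinities if any
#' standard deviation is non-positive; the degenerate all-zero case is
#' resolved by the caller (see [estimate_eb_std()]).
#'
#' @param fc Numeric vector of log2 fold changes.
#' @param eb_std Numeric vector of positive standard-deviation estimates.
#' @return Numeric vector of Z-scores.
#' @export
guide_zscores <- function(fc, eb_std) {
  if (length(fc) != length(eb_std))
    stop("fc and eb_std differ in length")
  if (any(eb_std <= 0))
    stop("eb_std must be positive for every guide (",
         sum(eb_std <= 0), " non-positive value(s))")
  fc / eb_std
}

#' Aggregate guide Z-scores into gene-level normZ
#'
#' Sums every guide-replicate Z-score belonging to a gene into `sumZ` and
#' normalizes by the square root of the number of summed terms:
#' `normZ = sumZ / sqrt(numObs)`. Under the null, independent standard-normal
#' guide scores therefore yield standard-normal gene scores regardless of
#' guide number.
#'
#' @param z Numeric vector of guide Z-scores (all guides, all replicates).
#' @param genes Character vector of gene symbols parallel to `z`.
#' @return A data frame with columns `GENE`, `sumZ`, `numObs`, `normZ`, one
#'   row per gene, ordered by gene symbol. Terms with missing `z` are dropped;
#'   a gene losing all its terms is excluded with a warning.
#' @export
gene_normZ <- function(z, genes) {
  if (length(z) != length(genes))
    stop("z and genes differ in length")
  genes <- as.character(genes)
  keep <- !is.na(z)
  all_genes <- unique(genes)
  z <- z[keep]
  genes <- genes[keep]
  lost <- setdiff(all_genes, unique(genes))
  if (length(lost) > 0)
    warning("gene(s) with no remaining guide observations excluded: ",
            paste(lost, collapse = ", "))
  if (length(z) == 0)
    stop("no guide observations left to aggregate")
  f <- factor(genes)
  sumZ <- as.numeric(tapply(z, f, sum))
  numObs <- as.integer(tapply(z, f, length))
  data.frame(GENE = levels(f), sumZ = sumZ, numObs = numObs,
             normZ = sumZ / sqrt(numObs), stringsAsFactors = FALSE)
}

#' Two-directional p-values, ranks and FDRs from normZ
#'
#' Gene scores are referred to the standard normal in both directions:
#' synergy/synthetic lethality (guides depleted under drug, negative normZ)
#' uses the lower tail, `pval_synth = pnorm(normZ)`; suppressor/resistance
#' (guides enriched under drug, positive normZ) uses the upper tail,
#' `pval_supp = 1 - pnorm(normZ)`. Each direction is independently ranked
#' (rank 1 = most significant; ties broken by gene symbol) and
#' Benjamini-Hochberg adjusted across all genes.
#'
#' @param gene_tab Data frame with columns `GENE` and `normZ` (as returned
#'   by [gene_normZ()]).
#' @return `gene_tab` with columns `pval_synth`, `rank_synth`, `fdr_synth`,
#'   `pval_supp`, `rank_supp`, `fdr_supp` appended, carrying class
#'   `gene_results`.
#' @export
pvalues_and_fdr <- function(gene_tab) {
  if (nrow(gene_tab) == 0)
    stop("gene table is empty")
  g <- nrow(gene_tab)
  gene_tab$pval_synth <- stats::pnorm(gene_tab$normZ)
  gene_tab$pval_supp <- stats::pnorm(gene_tab$normZ, lower.tail = FALSE)

  rank_of <- function(p) {
    r <- integer(g)
    r[order(p, gene_tab$GENE)] <- seq_len(g)
    r
  }
  gene_tab$rank_synth <- rank_of(gene_tab$pval_synth)
  gene_tab$fdr_synth <- stats::p.adjust(gene_tab$pval_synth, method = "BH")
  gene_tab$rank_supp <- rank_of(gene_tab$pval_supp)
  gene_tab$fdr_supp <- stats::p.adjust(gene_tab$pval_supp, method = "BH")

  cols <- c(intersect(.gene_result_columns, colnames(gene_tab)),
            setdiff(colnames(gene_tab), .gene_result_columns))
  gene_tab <- gene_tab[, cols, drop = FALSE]
  class(gene_tab) <- c("gene_results", "data.frame")
  gene_tab
}

# Resolve control/treated sample names from explicit arguments or from the
# roles stored on the screen object.
.resolve_arms <- function(screen, control_samples, treated_samples) {
  if (is.null(control_samples)) control_samples <- screen$control_samples
  if (is.null(treated_samples)) treated_samples <- screen$treated_samples
  if (is.null(control_samples) || is.null(treated_samples))
    stop("control and treated sample names must be given (either on the ",
         "screen_counts object or as arguments)")
  for (arm in list(control_samples, treated_samples)) {
    missing <- setdiff(arm, screen$sample_names)
    if (length(missing) > 0)
      stop("sample column(s) not found: ", paste(missing, collapse = ", "),
           "; available: ", paste(screen$sample_names, collapse = ", "))
  }
  list(control = control_samples, treated = treated_samples)
}

# Shared front half of drugZ and drugGS: normalization, fold change,
# empirical-Bayes std and guide Z-scores. Returns one row per retained
# guide-replicate observation.
.guide_z_table <- function(screen, config, control_samples = NULL,
                           treated_samples = NULL) {
  arms <- .resolve_arms(screen, control_samples, treated_samples)
  ctrl <- arms$control
  trt <- arms$treated

  keep <- rep(TRUE, length(screen$gene))
  if (!is.null(config$remove_genes))
    keep <- !(screen$gene %in% config$remove_genes)
  guide_id <- screen$guide_id[keep]
  gene <- screen$gene[keep]
  counts <- screen$counts[keep, , drop = FALSE]
  if (nrow(counts) == 0)
    stop("no guides left after remove_genes filtering")

  norm <- counts
  for (s in c(ctrl, trt))
    norm[, s] <- normalize_counts(counts[, s], config$norm_target, sample = s)

  if (config$paired) {
    if (length(ctrl) != length(trt))
      stop("paired mode requires equal numbers of control (", length(ctrl),
           ") and treated (", length(trt), ") samples; ",
           "use unpaired mode for asymmetric designs")
    comparisons <- lapply(seq_along(ctrl), function(r) {
      list(replicate = r,
           control_raw = counts[, ctrl[r]],
           control_norm = norm[, ctrl[r]],
           treated_norm = norm[, trt[r]])
    })
  } else {
    comparisons <- list(list(
      replicate = 1L,
      control_raw = rowMeans(counts[, ctrl, drop = FALSE]),
      control_norm = rowMeans(norm[, ctrl, drop = FALSE]),
      treated_norm = rowMeans(norm[, trt, drop = FALSE])))
  }

  rows <- lapply(comparisons, function(cmp) {
    sel <- cmp$control_raw >= config$min_control_reads
    if (!any(sel)) return(NULL)
    fc <- compute_fold_change(cmp$treated_norm[sel], cmp$control_norm[sel],
                              config$pseudocount)
    eb_std <- estimate_eb_std(fc, cmp$control_norm[sel],
                              window_size = config$window_size,
                              monotone_filter = config$monotone_filter,
                              ids = guide_id[sel])
    # wholly null comparison: every window RMS is zero, guides stay null
    z <- if (all(eb_std == 0)) rep(0, length(fc)) else guide_zscores(fc, eb_std)
    data.frame(guide_id = guide_id[sel], gene = gene[sel],
               replicate = cmp$replicate,
               control_norm = cmp$control_norm[sel],
               treated_norm = cmp$treated_norm[sel],
               fc = fc, eb_std = eb_std, z = z,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    stop("no guides pass min_control_reads = ", config$min_control_reads,
         " in any comparison")
  do.call(rbind, rows)
}

# Cross-gene calibration of gene scores so that the normal-theory p-values
# are valid: centre on the median and scale by the normal-consistent MAD.
# Robust estimates keep genuine hits (which may be a sizeable minority of
# genes at several sigma) from inflating the scale and deflating their own
# significance. Falls back to mean/sd when the MAD is degenerate; a wholly
# degenerate vector (all scores identical, e.g. a treated arm identical to
# its control) is returned unchanged so null genes stay null.
.standardize_scores <- function(x) {
  ctr <- stats::median(x)
  s <- stats::mad(x, center = ctr)
  if (!is.finite(s) || s == 0) {
    ctr <- mean(x)
    s <- stats::sd(x)
  }
  if (!is.finite(s) || s == 0) return(x)
  (x - ctr) / s
}

#' Score a drug-modifier screen with drugZ
#'
#' Runs the full pipeline: depth normalization of every sample, per-replicate
#' (paired) or mean-vs-mean (unpaired) log2 fold changes with a pseudocount,
#' empirical-Bayes fold-change standard deviations borrowed from guides with
#' similar control read counts, guide Z-scores, gene-level aggregation to
#' `sumZ / sqrt(numObs)`, and two-directional normal-theory p-values with
#' Benjamini-Hochberg FDR.
#'
#' The reported `normZ` is the gene score standardized across genes (centred,
#' unit variance). The raw aggregate is recoverable as
#' `sumZ / sqrt(numObs)`; the standardization calibrates the score against
#' the screen itself so that p-values read off the standard normal are valid
#' — the raw aggregate has a small negative bias and slightly less than unit
#' variance under the null, because a guide's fold change and its control
#' read count are anti-correlated through the shared control noise.
#'
#' Negative normZ marks synergistic / synthetic-lethal interactions (guide
#' dropout is stronger under drug); positive normZ marks suppressor /
#' resistance interactions (guides enriched under drug).
#'
#' @param screen A [screen_counts] object.
#' @param config A [drugz_config()].
#' @param control_samples,treated_samples Sample names for the two arms;
#'   default to the roles stored on `screen`. In paired mode the i-th entries
#'   form replicate pair i.
#' @return A `gene_results` data frame, one row per gene, ordered by
#'   ascending normZ, with columns `GENE`, `sumZ`, `numObs`, `normZ`,
#'   `pval_synth`, `rank_synth`, `fdr_synth`, `pval_supp`, `rank_supp`,
#'   `fdr_supp`.
#' @seealso [druggs()] for the Gibbs-sampling scorer, [write_gene_results()]
#'   for the output format.
#' @examples
#' sim <- simulate_screen(sim_config(n_genes = 50, seed = 1))
#' res <- drugz(sim$screen, drugz_config(window_size = 50))
#' head(res)
#' @export
drugz <- function(screen, config = drugz_config(), control_samples = NULL,
                  treated_samples = NULL) {
  stopifnot(inherits(screen, "screen_counts"))
  gz <- .guide_z_table(screen, config, control_samples, treated_samples)
  tab <- gene_normZ(gz$z, gz$gene)
  tab$normZ <- .standardize_scores(tab$normZ)
  res <- pvalues_and_fdr(tab)
  res <- res[order(res$normZ, res$GENE), , drop = FALSE]
  rownames(res) <- NULL
  res
}
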