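#' Configuration for the synthetic-screen simulator
#'
#' The defaults describe a scaled-down paired chemogenetic knockout screen:
#' a pooled library with several guides per gene, three replicates each split
#' into a control and a drug-treated population, overdispersed sequencing
#' counts, a minority of genes carrying a planted drug interaction, and a
#' further minority with a drug-independent fitness defect shared by both
#' arms.
#'
#' @param n_genes Number of genes (default 1000).
#' @param guides_per_gene Guides targeting each gene (default 4).
#' @param n_replicates Replicates; each contributes one control and one
#'   treated sample, positionally paired (default 3).
#' @param frac_synergy,frac_suppressor Fractions of genes with a planted
#'   synergistic (treated depletion) or suppressor (treated enrichment)
#'   interaction (defaults 0.05 each; together at most 0.5).
#' @param effect_size Mean log2 shift applied to the treated arm of
#'   interacting genes; negative for synergy (default -2). Suppressor genes
#'   receive the mirrored shift `-effect_size`. Each guide draws its own
#'   effect from `Normal(effect, |effect|/4)`, so guides of one gene are
#'   correlated but not identical.
#' @param fitness_frac,fitness_effect Fraction of (otherwise null) genes
#'   with a drug-independent log2 fitness shift applied to BOTH arms, and
#'   its mean magnitude (defaults 0.1 and -1: a moderate knockout dropout).
#' @param dispersion Negative-binomial overdispersion of the counts
#'   (variance = mu + dispersion * mu^2; default 0.25). Zero gives Poisson
#'   counts.
#' @param depth Mean sequencing reads per guide (default 500).
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   screens.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 1000, guides_per_gene = 4, n_replicates = 3,
                       frac_synergy = 0.05, frac_suppressor = 0.05,
                       effect_size = -2, fitness_frac = 0.1,
                       fitness_effect = -1, dispersion = 0.25, depth = 500,
                       seed = NULL) {
  if (n_genes < 1 || guides_per_gene < 1 || n_replicates < 1)
    stop("n_genes, guides_per_gene and n_replicates must be >= 1")
  if (frac_synergy < 0 || frac_suppressor < 0 ||
      frac_synergy + frac_suppressor > 0.5)
    stop("frac_synergy + frac_suppressor must lie in [0, 0.5]")
  if (fitness_frac < 0 || fitness_frac > 1)
    stop("fitness_frac must lie in [0, 1]")
  if (depth <= 0) stop("depth must be > 0")
  if (dispersion < 0) stop("dispersion must be >= 0")
  structure(
    list(n_genes = as.integer(n_genes),
         guides_per_gene = as.integer(guides_per_gene),
         n_replicates = as.integer(n_replicates),
         frac_synergy = frac_synergy, frac_suppressor = frac_suppressor,
         effect_size = effect_size, fitness_frac = fitness_frac,
         fitness_effect = fitness_effect, dispersion = dispersion,
         depth = depth, seed = seed),
    class = "sim_config"
  )
}

# NB draws with mean mu and variance mu + dispersion*mu^2; Poisson at 0
.rcounts <- function(n, mu, dispersion) {
  if (dispersion == 0) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate a paired chemogenetic screen with known ground truth
#'
#' Each guide receives a log-normal latent abundance (scaled to mean 1).
#' Control counts are negative-binomial draws around `depth * abundance`,
#' independently per replicate. Treated counts share the latent abundance,
#' apply the gene's fitness shift to both arms and the drug-interaction log2
#' shift (with per-guide jitter) to the treated arm only. Gene labels are
#' assigned at random: `synergy`, `suppressor`, `fitness_only` (fitness shift
#' but no interaction) or `null`.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{screen}{a [screen_counts] object with samples
#'       `CTRL_1..CTRL_R, DRUG_1..DRUG_R` and arm roles set;}
#'     \item{truth}{a data frame `GENE`, `label`, `effect` giving each
#'       gene's planted label and mean realized per-guide treated-arm log2
#'       shift (0 for null and fitness_only genes);}
#'     \item{guide_effects}{numeric vector of per-guide realized interaction
#'       shifts, named by guide.}
#'   }
#' @export
simulate_screen <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  G <- config$n_genes
  gpg <- config$guides_per_gene
  R <- config$n_replicates
  n_guides <- G * gpg

  genes <- sprintf("GENE_%04d", seq_len(G))
  guide_id <- paste0(rep(genes, each = gpg), "_g", rep(seq_len(gpg), G))
  guide_gene <- rep(genes, each = gpg)

  n_syn <- round(config$frac_synergy * G)
  n_supp <- round(config$frac_suppressor * G)
  n_fit <- round(config$fitness_frac * G)
  if (n_syn + n_supp + n_fit > G)
    stop("planted fractions exceed the number of genes")
  shuffled <- sample(genes)
  label <- stats::setNames(rep("null", G), genes)
  label[shuffled[seq_len(n_syn)]] <- "synergy"
  label[shuffled[n_syn + seq_len(n_supp)]] <- "suppressor"
  label[shuffled[n_syn + n_supp + seq_len(n_fit)]] <- "fitness_only"

  abundance <- stats::rlnorm(n_guides, meanlog = 0, sdlog = 1)
  abundance <- abundance / mean(abundance)

  jitter_sd <- abs(config$effect_size) / 4
  guide_label <- label[guide_gene]
  guide_effect <- numeric(n_guides)
  is_syn <- guide_label == "synergy"
  is_supp <- guide_label == "suppressor"
  guide_effect[is_syn] <- stats::rnorm(sum(is_syn), config$effect_size,
                                       jitter_sd)
  guide_effect[is_supp] <- stats::rnorm(sum(is_supp), -config$effect_size,
                                        jitter_sd)

  fit_sd <- abs(config$fitness_effect) / 4
  guide_fitness <- numeric(n_guides)
  has_fit <- guide_label == "fitness_only"
  guide_fitness[has_fit] <- stats::rnorm(sum(has_fit), config$fitness_effect,
                                         fit_sd)

  mu_ctrl <- config$depth * abundance * 2^guide_fitness
  mu_trt <- mu_ctrl * 2^guide_effect

  counts <- matrix(0, n_guides, 2 * R,
                   dimnames = list(guide_id,
                                   c(paste0("CTRL_", seq_len(R)),
                                     paste0("DRUG_", seq_len(R)))))
  for (r in seq_len(R)) {
    counts[, r] <- .rcounts(n_guides, mu_ctrl, config$dispersion)
    counts[, R + r] <- .rcounts(n_guides, mu_trt, config$dispersion)
  }

  screen <- screen_counts(
    guide_id = guide_id, gene = guide_gene, counts = counts,
    control_samples = paste0("CTRL_", seq_len(R)),
    treated_samples = paste0("DRUG_", seq_len(R))
  )

  effect <- as.numeric(tapply(guide_effect, guide_gene, mean)[genes])
  truth <- data.frame(GENE = genes, label = unname(label[genes]),
                      effect = effect, stringsAsFactors = FALSE)

  list(screen = screen,
       truth = truth,
       guide_effects = stats::setNames(guide_effect, guide_id))
}

#' Write a screen count table and its truth sidecar
#'
#' Serializes a simulated screen in the tab-delimited count format accepted
#' by [read_count_table()] (columns `GUIDE`, `GENE`, then one column per
#' sample) and, optionally, the ground-truth table.
#'
#' @param sim A list as returned by [simulate_screen()].
#' @param counts_path Output path for the count table.
#' @param truth_path Optional output path for the truth table.
#' @return `counts_path`, invisibly.
#' @export
write_sim_screen <- function(sim, counts_path, truth_path = NULL) {
  screen <- sim$screen
  tab <- data.frame(GUIDE = screen$guide_id, GENE = screen$gene,
                    screen$counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(truth_path))
    utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(counts_path)
}
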