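#' Configuration for the drugGS Gibbs sampler
#'
#' Per gene, the guide Z-scores are modelled as draws from a normal
#' distribution with unknown mean `mu` and precision `tau = 1/sigma^2`. The
#' prior is semi-conjugate: `mu ~ Normal(mu_prior, 1/tau_prior)` and
#' `tau ~ Gamma(a_prior, rate = b_prior)`. The sampler alternates the two
#' full conditionals and reports the posterior mean of `mu` as the gene
#' score.
#'
#' @param n_samples Number of Gibbs draws S per gene (default 1000, minimum
#'   100).
#' @param mu_prior Prior mean of `mu` (default 0: no interaction).
#' @param tau_prior Prior precision attached to `mu_prior` (default 0.001,
#'   weakly informative).
#' @param a_prior,b_prior Shape and rate of the Gamma prior on `tau`
#'   (default 0.5 each, weakly informative).
#' @param burn_in Fraction of the S draws discarded from the front before
#'   the posterior mean is taken (default 0.1; set to 0 to average every
#'   draw).
#' @param strict_update If `TRUE`, the Gamma rate update omits the factor
#'   1/2 on the sum of squared deviations (`b_prior + sum((z - mu)^2)`)
#'   instead of the standard conjugate form `b_prior + sum((z - mu)^2)/2`.
#'   Only the standard form matches the analytic posterior; the strict form
#'   halves the inferred variance and is provided for comparison.
#' @param seed Optional integer seed for reproducible draws.
#' @return A `gibbs_config` list.
#' @export
gibbs_config <- function(n_samples = 1000, mu_prior = 0, tau_prior = 0.001,
                         a_prior = 0.5, b_prior = 0.5, burn_in = 0.1,
                         strict_update = FALSE, seed = NULL) {
  if (!is.numeric(n_samples) || n_samples < 100)
    stop("n_samples must be >= 100")
  if (tau_prior <= 0 || a_prior <= 0 || b_prior <= 0)
    stop("tau_prior, a_prior and b_prior must be > 0")
  if (burn_in < 0 || burn_in >= 1)
    stop("burn_in must be in [0, 1)")
  structure(
    list(n_samples = as.integer(n_samples), mu_prior = mu_prior,
         tau_prior = tau_prior, a_prior = a_prior, b_prior = b_prior,
         burn_in = burn_in, strict_update = isTRUE(strict_update),
         seed = seed),
    class = "gibbs_config"
  )
}

#' Gibbs-sample the posterior of one gene's mean Z-score
#'
#' Alternates the two full conditionals of the semi-conjugate normal model:
#' `mu | tau, z ~ Normal((n*ybar*tau + mu_prior*tau_prior)/(n*tau + tau_prior),
#' 1/(n*tau + tau_prior))` and
#' `tau | mu, z ~ Gamma(a_prior + n/2, rate = b_prior + sum((z - mu)^2)/2)`.
#' Chains start at the data (`mu = mean(z)`, `tau = 1`). The gene score is
#' the mean of the retained `mu` draws.
#'
#' @param z Numeric vector of the gene's guide Z-scores across guides and
#'   replicates (length >= 1).
#' @param config A [gibbs_config()]. If its `seed` is non-`NULL` the RNG is
#'   seeded before sampling, making the draws bit-reproducible.
#' @return A `gene_posterior` list: `n`, `mu_samples`, `tau_samples`,
#'   `score` (posterior mean of `mu` after burn-in) and `post_sd` (posterior
#'   standard deviation of `mu`).
#' @export
gibbs_gene <- function(z, config = gibbs_config()) {
  z <- z[!is.na(z)]
  n <- length(z)
  if (n == 0)
    stop("gene has no guide Z-scores")
  if (!is.null(config$seed)) set.seed(config$seed)

  S <- config$n_samples
  ybar <- mean(z)
  mu0 <- config$mu_prior
  tau0 <- config$tau_prior
  a_upd <- config$a_prior + n / 2
  ss_scale <- if (config$strict_update) 1 else 0.5

  mu_samples <- numeric(S)
  tau_samples <- numeric(S)
  mu <- ybar
  tau <- 1
  for (k in seq_len(S)) {
    prec <- n * tau + tau0
    mu <- stats::rnorm(1, (n * ybar * tau + mu0 * tau0) / prec,
                       1 / sqrt(prec))
    b_upd <- config$b_prior + ss_scale * sum((z - mu)^2)
    tau <- stats::rgamma(1, shape = a_upd, rate = b_upd)
    mu_samples[k] <- mu
    tau_samples[k] <- tau
  }

  keep <- seq.int(floor(config$burn_in * S) + 1L, S)
  structure(
    list(n = n, mu_samples = mu_samples, tau_samples = tau_samples,
         score = mean(mu_samples[keep]),
         post_sd = stats::sd(mu_samples[keep])),
    class = "gene_posterior"
  )
}

#' Score a drug-modifier screen with drugGS
#'
#' Shares the whole front end with [drugz()] — normalization, fold change,
#' empirical-Bayes variance, guide Z-scores — but replaces the closed-form
#' gene aggregation with per-gene Gibbs sampling of the posterior mean guide
#' Z-score ([gibbs_gene()]). The posterior means are standardized across
#' genes (centred, unit variance) so that the same two-directional
#' normal-theory p-value and FDR machinery as [drugz()] applies.
#'
#' @inheritParams drugz
#' @param gibbs A [gibbs_config()]. Its `seed` seeds the whole run once;
#'   genes are then sampled in alphabetical order, so identical inputs and
#'   seed give identical output.
#' @return A `gene_results` data frame as from [drugz()], ordered by
#'   ascending normZ, with two extra columns: `mu_post` (raw posterior mean
#'   of the gene's mean guide Z-score) and `post_sd` (its posterior standard
#'   deviation). `normZ` holds the cross-gene standardized score.
#' @export
druggs <- function(screen, config = drugz_config(), gibbs = gibbs_config(),
                   control_samples = NULL, treated_samples = NULL) {
  stopifnot(inherits(screen, "screen_counts"))
  gz <- .guide_z_table(screen, config, control_samples, treated_samples)

  if (!is.null(gibbs$seed)) set.seed(gibbs$seed)
  gene_conf <- gibbs
  gene_conf$seed <- NULL
  genes <- sort(unique(gz$gene))
  zsplit <- split(gz$z, gz$gene)[genes]

  post <- lapply(zsplit, gibbs_gene, config = gene_conf)
  mu_post <- vapply(post, `[[`, numeric(1), "score")
  post_sd <- vapply(post, `[[`, numeric(1), "post_sd")

  tab <- data.frame(
    GENE = genes,
    sumZ = vapply(zsplit, sum, numeric(1)),
    numObs = lengths(zsplit),
    normZ = .standardize_scores(mu_post),
    stringsAsFactors = FALSE
  )
  res <- pvalues_and_fdr(tab)
  res$mu_post <- mu_post
  res$post_sd <- post_sd
  res <- res[order(res$normZ, res$GENE), , drop = FALSE]
  rownames(res) <- NULL
  res
}
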