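test_that("normalization scales every sample to the target depth", {
  expect_equal(normalize_counts(c(1, 2, 3, 4), 1e7),
               c(1e6, 2e6, 3e6, 4e6))
  set.seed(42)
  for (i in 1:5) {
    x <- rpois(200, lambda = sample(50:500, 1))
    expect_equal(sum(normalize_counts(x, 1e7)), 1e7)
  }
  expect_error(normalize_counts(rep(0, 10), sample = "T0_ctrl"), "T0_ctrl")
})

test_that("fold change follows the pseudocounted log2 ratio", {
  expect_equal(compute_fold_change(5, 5, 5), 0)
  expect_equal(compute_fold_change(15, 5, 5), 1) # log2(20/10)
  expect_equal(compute_fold_change(0, 0, 5), 0)  # pseudocount guards zeros
  expect_true(all(is.finite(compute_fold_change(c(0, 1e7), c(1e7, 0), 5))))
  expect_error(compute_fold_change(1:3, 1:4), "length")
})

test_that("eb_std is the windowed RMS about zero", {
  # constant fold changes: RMS about zero is |c| for every guide
  fc <- rep(-1.5, 20)
  expect_equal(estimate_eb_std(fc, 20:1, window_size = 5), rep(1.5, 20))
  # two-guide window: sqrt((9 + 16) / 2)
  expect_equal(estimate_eb_std(c(3, 4), c(10, 5), window_size = 2),
               rep(sqrt(12.5), 2))
})

test_that("eb_std matches the brute-force window oracle in original order", {
  set.seed(7)
  for (case in 1:5) {
    n <- sample(30:80, 1)
    N <- sample(4:20, 1)
    fc <- rnorm(n, sd = 0.8)
    cn <- rgamma(n, 2, 0.01)
    for (mono in c(TRUE, FALSE)) {
      expect_equal(estimate_eb_std(fc, cn, N, monotone_filter = mono),
                   eb_std_brute(fc, cn, N, monotone = mono))
    }
  }
})

test_that("monotone filter is a running maximum down the control ranking", {
  set.seed(11)
  fc <- rnorm(100)
  cn <- runif(100, 1, 1000)
  raw <- estimate_eb_std(fc, cn, 10, monotone_filter = FALSE)
  filt <- estimate_eb_std(fc, cn, 10, monotone_filter = TRUE)
  ord <- order(-cn)
  expect_equal(filt[ord], cummax(raw[ord]))
  expect_false(is.unsorted(filt[ord]))
  # hand case: raw per-rank stds [2, 1.5, 2.5] must become [2, 2, 2.5]
  expect_equal(cummax(c(2, 1.5, 2.5)), c(2, 2, 2.5))
  expect_error(estimate_eb_std(fc, cn, 1), "window_size")
})

test_that("ties in control reads are broken deterministically by id", {
  fc <- c(0.5, -2, 0.1, 1)
  cn <- c(10, 10, 10, 10)
  a <- estimate_eb_std(fc, cn, 2, ids = c("g1", "g2", "g3", "g4"))
  b <- estimate_eb_std(rev(fc), cn, 2, ids = c("g4", "g3", "g2", "g1"))
  expect_equal(a, rev(b))
})

test_that("zero windows borrow the smallest positive estimate", {
  fc <- c(0, 0, 3, 4)
  cn <- c(100, 90, 10, 5) # the two zero-fc guides share an all-zero window
  std <- estimate_eb_std(fc, cn, 2, monotone_filter = FALSE)
  expect_true(all(std > 0))
  expect_equal(std[1], min(std[std > 0]))
})

test_that("guide Z-scores are fold change over eb_std", {
  expect_equal(guide_zscores(1.0, 0.5), 2.0)
  expect_equal(guide_zscores(0, 3.7), 0)
  expect_error(guide_zscores(1, 0), "positive")
})

test_that("gene aggregation sums Z and divides by sqrt(n)", {
  one <- gene_normZ(2, "geneA")
  expect_equal(one$normZ, 2)
  expect_equal(one$numObs, 1L)

  four <- gene_normZ(rep(1, 4), rep("geneA", 4))
  expect_equal(four$sumZ, 4)
  expect_equal(four$normZ, 2) # 4 / sqrt(4)
})

test_that("normZ of i.i.d. standard-normal terms is standard normal", {
  set.seed(19)
  n_genes <- 10000
  terms_per_gene <- sample(3:12, n_genes, replace = TRUE)
  genes <- rep(sprintf("g%05d", seq_len(n_genes)), terms_per_gene)
  z <- rnorm(length(genes))
  tab <- gene_normZ(z, genes)
  expect_lt(abs(mean(tab$normZ)), 0.05)
  expect_lt(abs(sd(tab$normZ) - 1), 0.05)
})

test_that("two-directional p-values and BH behave as expected", {
  tab <- data.frame(GENE = c("a", "b", "c"), normZ = c(0, -1.6449, 1.6449))
  res <- pvalues_and_fdr(tab)
  expect_equal(res$pval_synth[1], 0.5)
  expect_equal(res$pval_supp[1], 0.5)
  expect_equal(res$pval_synth[2], 0.05, tolerance = 1e-4)
  expect_equal(res$pval_supp[3], 0.05, tolerance = 1e-4)
  # FDR never drops below its own p-value, ranks are permutations
  expect_true(all(res$fdr_synth >= res$pval_synth))
  expect_true(all(res$fdr_supp >= res$pval_supp))
  expect_setequal(res$rank_synth, 1:3)
  expect_setequal(res$rank_supp, 1:3)
  # textbook BH step-up: [.01 .02 .03 .04] -> all .04
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  expect_equal(bh_brute(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
})

test_that("a treated arm identical to its control is entirely null", {
  counts <- matrix(rep(c(100, 250, 600, 50), 4), ncol = 4,
                   dimnames = list(NULL, c("C1", "C2", "T1", "T2")))
  sc <- screen_counts(paste0("g", 1:4), c("a", "a", "b", "b"), counts,
                      control_samples = c("C1", "C2"),
                      treated_samples = c("T1", "T2"))
  res <- drugz(sc, drugz_config(window_size = 4))
  expect_equal(res$normZ, rep(0, 2))
  expect_equal(res$pval_synth, rep(0.5, 2))
  expect_equal(res$pval_supp, rep(0.5, 2))
  expect_equal(res$fdr_synth, rep(0.5, 2))
})

test_that("strong planted synergy genes dominate the negative tail", {
  sim <- simulate_screen(sim_config(seed = 1))
  res <- drugz(sim$screen)
  syn <- sim$truth$GENE[sim$truth$label == "synergy"]
  top75 <- res$GENE[order(res$normZ)][1:75]
  expect_gte(length(intersect(syn, top75)), 45)
})

test_that("normZ is invariant to guide order and replicate order", {
  sim <- simulate_screen(sim_config(n_genes = 150, seed = 5))
  sc <- sim$screen
  base <- drugz(sc, drugz_config(window_size = 200))

  set.seed(2)
  perm <- sample(nrow(sc$counts))
  shuffled <- screen_counts(sc$guide_id[perm], sc$gene[perm],
                            sc$counts[perm, ],
                            control_samples = sc$control_samples,
                            treated_samples = sc$treated_samples)
  res_perm <- drugz(shuffled, drugz_config(window_size = 200))
  expect_equal(res_perm$normZ, base$normZ)
  expect_equal(res_perm$GENE, base$GENE)

  # reordering replicate pairs consistently leaves paired results unchanged
  res_swap <- drugz(sc, drugz_config(window_size = 200),
                    control_samples = c("CTRL_3", "CTRL_1", "CTRL_2"),
                    treated_samples = c("DRUG_3", "DRUG_1", "DRUG_2"))
  expect_equal(res_swap$normZ, base$normZ)

  # unpaired mode is invariant to arbitrary within-arm order
  base_u <- drugz(sc, drugz_config(window_size = 200, paired = FALSE))
  res_u <- drugz(sc, drugz_config(window_size = 200, paired = FALSE),
                 control_samples = c("CTRL_2", "CTRL_3", "CTRL_1"),
                 treated_samples = c("DRUG_3", "DRUG_2", "DRUG_1"))
  expect_equal(res_u$normZ, base_u$normZ)
})

test_that("scaling all raw counts leaves results unchanged", {
  sim <- simulate_screen(sim_config(n_genes = 100, seed = 9))
  sc <- sim$screen
  doubled <- screen_counts(sc$guide_id, sc$gene, sc$counts * 2,
                           control_samples = sc$control_samples,
                           treated_samples = sc$treated_samples)
  cfg <- drugz_config(window_size = 100)
  # depth normalization precedes the pseudocount, so scaling is exactly
  # absorbed and the fold changes do not move at all
  expect_equal(drugz(doubled, cfg)$normZ, drugz(sc, cfg)$normZ)
})

test_that("paired and unpaired modes rank genes concordantly", {
  sim <- simulate_screen(sim_config(seed = 1))
  rp <- drugz(sim$screen)
  ru <- drugz(sim$screen, drugz_config(paired = FALSE))
  m <- merge(rp[, c("GENE", "normZ")], ru[, c("GENE", "normZ")], by = "GENE")
  expect_gte(cor(m$normZ.x, m$normZ.y, method = "spearman"), 0.9)
})

test_that("config filters drop guides and genes as requested", {
  sim <- simulate_screen(sim_config(n_genes = 100, seed = 13))
  drop_genes <- sim$truth$GENE[1:5]
  res <- drugz(sim$screen,
               drugz_config(window_size = 100, remove_genes = drop_genes))
  expect_false(any(drop_genes %in% res$GENE))
  expect_equal(nrow(res), 95)

  # an aggressive min_control_reads filter removes low-abundance guides
  res_all <- drugz(sim$screen, drugz_config(window_size = 50))
  res_f <- drugz(sim$screen, drugz_config(window_size = 50,
                                          min_control_reads = 400))
  expect_lt(sum(res_f$numObs), sum(res_all$numObs))
  # a gene losing every observation is excluded with a warning
  expect_warning(tab <- gene_normZ(c(1, NA, NA), c("a", "b", "b")),
                 "excluded")
  expect_equal(tab$GENE, "a")
})

test_that("paired mode refuses asymmetric arms and points at unpaired", {
  sim <- simulate_screen(sim_config(n_genes = 50, seed = 21))
  err <- expect_error(
    drugz(sim$screen, drugz_config(window_size = 50),
          control_samples = c("CTRL_1", "CTRL_2", "CTRL_3"),
          treated_samples = c("DRUG_1", "DRUG_2")))
  expect_match(conditionMessage(err), "unpaired")
  # unpaired tolerates the same asymmetry
  res <- drugz(sim$screen, drugz_config(window_size = 50, paired = FALSE),
               control_samples = c("CTRL_1", "CTRL_2", "CTRL_3"),
               treated_samples = c("DRUG_1", "DRUG_2"))
  expect_equal(nrow(res), 50)
})

test_that("configuration is validated", {
  expect_error(drugz_config(pseudocount = 0), "pseudocount")
  expect_error(drugz_config(window_size = 1), "window_size")
  expect_error(drugz_config(norm_target = -1), "norm_target")
})
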