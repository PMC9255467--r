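test_that("random-effects synthesis reduces to single-study values", {
  tab <- make_deg_table("G1", fc = 1, se = 0.5)
  res <- rem_meta(list(s1 = tab))
  expect_equal(res$rem_fc, 1)
  expect_equal(res$rem_se, 0.5, tolerance = 1e-12)
  expect_equal(res$rem_p, tab$P.Value, tolerance = 1e-12)
  expect_equal(res$tau_sq, 0)
})

test_that("homogeneous studies combine with zero heterogeneity", {
  tab <- make_deg_table(c("G1", "G2"), fc = c(1, -0.4), se = c(0.5, 0.2))
  res <- rem_meta(list(s1 = tab, s2 = tab))
  expect_equal(res$tau_sq, c(0, 0))
  expect_equal(res$rem_fc, c(1, -0.4))
  expect_equal(res$rem_se, c(0.5, 0.2) / sqrt(2), tolerance = 1e-12)
  expect_error(rem_meta(list(s1 = within(tab, CI.R <- CI.L - 1))), "CI.R")
})

test_that("DerSimonian-Laird estimates match metafor on heterogeneous studies", {
  skip_if_not_installed("metafor")
  set.seed(6)
  k <- 6
  fc <- rnorm(k, 1, 0.6)
  se <- runif(k, 0.2, 0.5)
  tabs <- lapply(seq_len(k), function(i) make_deg_table("G1", fc[i], se[i]))
  names(tabs) <- paste0("s", seq_len(k))
  res <- rem_meta(tabs)
  ref <- metafor::rma(yi = fc, vi = se^2, method = "DL")
  expect_equal(res$rem_fc, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(res$rem_se, ref$se, tolerance = 1e-10)
  expect_equal(res$tau_sq, ref$tau2, tolerance = 1e-10)
  expect_equal(res$rem_p, ref$pval, tolerance = 1e-10)
})

test_that("random-effects recovery: low bias and sane tau2 at 8 studies", {
  set.seed(77)
  n_rep <- 200
  k <- 8
  tau2 <- 0.1
  v <- runif(k, 0.02, 0.08)
  # each "gene" is one replicate meta-analysis of the same generative model
  tabs <- lapply(seq_len(k), function(i)
    make_deg_table(sprintf("R%03d", seq_len(n_rep)),
                   fc = rnorm(n_rep, 1.5, sqrt(tau2 + v[i])),
                   se = sqrt(v[i])))
  names(tabs) <- paste0("s", seq_len(k))
  res <- rem_meta(tabs)
  expect_lt(abs(mean(res$rem_fc) - 1.5), 0.1)
  expect_lt(abs(mean(res$tau_sq) - tau2) / tau2, 0.5)
})

test_that("vote counting tallies studies and sign consistency", {
  up_tab <- make_deg_table("G1", fc = 2, se = 0.3)
  dn_tab <- make_deg_table("G1", fc = -2, se = 0.3)
  res5 <- vc_meta(stats::setNames(rep(list(up_tab), 5), paste0("s", 1:5)))
  expect_equal(res5$ndiff, 5)
  expect_equal(res5$sign_consistency, 5)

  mixed <- c(rep(list(up_tab), 2), rep(list(dn_tab), 2))
  names(mixed) <- paste0("s", 1:4)
  res4 <- vc_meta(mixed)
  expect_equal(res4$ndiff, 4)
  expect_equal(res4$sign_consistency, 0)
})

test_that("null vote counts follow the binomial tail", {
  set.seed(5)
  n_genes <- 2000
  tabs <- lapply(1:16, function(i)
    data.frame(gene = sprintf("G%04d", seq_len(n_genes)),
               log2FC = rnorm(n_genes), P.Value = runif(n_genes),
               stringsAsFactors = FALSE))
  names(tabs) <- paste0("s", 1:16)
  vc <- vc_meta(tabs)
  obs <- mean(vc$ndiff >= 3)
  expected <- stats::pbinom(2, 16, 0.05, lower.tail = FALSE)
  se <- sqrt(expected * (1 - expected) / n_genes)
  expect_lt(abs(obs - expected), 4 * se)
})

test_that("inverse cumulative distribution counts genes at each threshold", {
  vc <- data.frame(ndiff = c(1, 1, 2, 3))
  icd <- inverse_cumulative_distribution(vc)
  expect_equal(icd$k, 1:3)
  expect_equal(icd$n_genes, c(4L, 2L, 1L))

  expect_equal(nrow(inverse_cumulative_distribution(data.frame(ndiff = c(0, 0)))), 0)

  set.seed(8)
  icd2 <- inverse_cumulative_distribution(
    data.frame(ndiff = sample(0:10, 100, replace = TRUE)))
  expect_true(all(diff(icd2$n_genes) <= 0))
})

test_that("Fisher combining has its closed-form identities and null calibration", {
  one <- ca_meta(list(s1 = make_deg_table("G1", 0.5, 0.3, p = 0.04)))
  expect_equal(one$fisher_p, 0.04, tolerance = 1e-12)

  sure <- lapply(1:3, function(i) make_deg_table("G1", 0, 1, p = 1))
  names(sure) <- paste0("s", 1:3)
  res <- ca_meta(sure)
  expect_equal(res$fisher_stat, 0)
  expect_equal(res$fisher_p, 1)

  set.seed(9)
  n_genes <- 2000
  tabs <- lapply(1:16, function(i)
    data.frame(gene = sprintf("G%04d", seq_len(n_genes)),
               log2FC = rnorm(n_genes), P.Value = runif(n_genes)))
  names(tabs) <- paste0("s", 1:16)
  null_ca <- ca_meta(tabs)
  expect_gt(stats::ks.test(null_ca$fisher_p, "punif")$p.value, 0.01)
})

test_that("top-percentile extraction ranks and counts correctly", {
  set.seed(10)
  summ <- data.frame(gene = sprintf("G%03d", 1:800),
                     rem_fc = rnorm(800), rem_p = runif(800),
                     stringsAsFactors = FALSE)
  all_back <- top_perturbed(summ, "REM", meta_config(metathr = 1))
  expect_equal(nrow(all_back), 800)
  top8 <- top_perturbed(summ, "REM", meta_config(metathr = 0.01))
  expect_equal(nrow(top8), 8)
  expect_identical(top8$gene, summ$gene[order(summ$rem_p)][1:8])
})

test_that("planted shared genes dominate the REM top percentile", {
  cfg <- simulation_config(n_studies = 8, genes_per_study = 2000,
                           samples_per_group = 10, deg_fraction = 0.01,
                           effect_size_log2fc = 2, seed = 19)
  tabs <- lapply(generate_collection(cfg), run_dex)
  rem <- rem_meta(tabs)
  top <- top_perturbed(rem, "REM", meta_config(metathr = 0.01))
  pl <- planted_genes(cfg)
  expect_gte(sum(pl$gene %in% top$gene), 18)
})

test_that("set compilation removes redundancy and checks regulation", {
  a <- data.frame(gene = c("A", "B", "C"), regulation = "up", source = "REM")
  b <- data.frame(gene = c("D", "E", "F", "G"), regulation = "down",
                  source = "VC")
  expect_equal(nrow(compile_union(list(a, b))), 7)
  expect_equal(nrow(compile_union(list(a, a))), 3)
  conflict <- data.frame(gene = "A", regulation = "down", source = "CA")
  expect_error(compile_union(list(a, conflict)), "conflicting regulation.*A")
})
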