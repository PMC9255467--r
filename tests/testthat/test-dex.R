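test_that("scale heuristic transforms linear matrices and leaves log ones", {
  m_log <- matrix(c(0, 5.2, 12.3, 8), 2)
  expect_identical(maybe_log2(m_log), m_log)
  expect_identical(maybe_log2(matrix(0, 3, 3)), matrix(0, 3, 3))
  m_lin <- matrix(c(0, 1, 3, 255), 2)
  expect_equal(maybe_log2(m_lin), matrix(c(0, 1, 2, 8), 2))
  expect_error(maybe_log2(matrix(c(-1, 2), 1), scale = "linear"),
               "negative")
})

test_that("batch removal is exact on balanced shifts and preserves the group effect", {
  set.seed(1)
  x <- matrix(rnorm(50 * 8), 50, 8)
  group <- rep(c("case", "control"), 4)
  expect_identical(remove_batch_effect(x, rep("B1", 8), group), x)

  batch <- rep(c("B1", "B2"), each = 4)  # balanced across groups

  # noise-free in the batch direction: per-gene batch means are equal, so a
  # pure +3 shift on B2 is estimated and removed exactly
  base <- matrix(rnorm(50), 50, 8) [, rep(1, 8)] + 2 * (col(x) %% 2)
  shifted_base <- base + 3 * (col(base) > 4)
  expect_lt(max(abs(remove_batch_effect(shifted_base, batch, group) - base)),
            1e-9)

  # on any matrix, adding a pure batch shift changes nothing after removal
  shifted <- x + 3 * (col(x) > 4)
  expect_lt(max(abs(remove_batch_effect(shifted, batch, group) -
                      remove_batch_effect(x, batch, group))), 1e-9)

  # agrees with the reference implementation up to a per-gene constant
  ref <- limma::removeBatchEffect(shifted, batch = batch,
                                  design = stats::model.matrix(~ factor(group)))
  centered <- function(m) m - rowMeans(m)
  expect_lt(max(abs(centered(remove_batch_effect(shifted, batch, group)) -
                      centered(ref))), 1e-9)

  # group-difference estimates unchanged by removal on a balanced design
  cfg <- simulation_config(n_studies = 1, genes_per_study = 300,
                           samples_per_group = 6, batch_count = 2,
                           batch_sd = 1, seed = 14)
  st <- generate_study(cfg, 1)
  f_raw <- fit_linear_model(st$matrix, st$group)
  f_cor <- fit_linear_model(remove_batch_effect(st$matrix, st$batch, st$group),
                            st$group)
  expect_lt(max(abs(f_raw$log2FC - f_cor$log2FC)), 1e-9)

  expect_error(remove_batch_effect(x, group, group), "confounded")
})

test_that("PCA batch diagnostic flags strong batch separation only", {
  x0 <- matrix(5, 20, 6)
  d0 <- batch_diagnostic(x0, rep(c("a", "b"), 3))
  expect_false(d0$flag)

  set.seed(2)
  x <- matrix(rnorm(100 * 6), 100, 6)
  batch <- rep(c("a", "b"), each = 3)
  x_shift <- x + 10 * (col(x) > 3)
  expect_true(batch_diagnostic(x_shift, batch)$flag)

  flags <- vapply(1:10, function(s) {
    cfg <- simulation_config(n_studies = 1, genes_per_study = 200,
                             samples_per_group = 5, batch_count = 0, seed = s)
    st <- generate_study(cfg, 1)
    batch_diagnostic(st$matrix, rep(c("a", "b"), 5))$flag
  }, TRUE)
  expect_false(any(flags))
})

test_that("expression filter applies the median rule then the detection rule", {
  x <- matrix(rep(1:4, each = 4), 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  kept <- median_filter(x)
  expect_identical(rownames(kept), c("g3", "g4"))  # cutoff 2.5, >= rule

  const <- matrix(2, 3, 4, dimnames = list(paste0("g", 1:3), NULL))
  expect_equal(nrow(median_filter(const)), 3)  # all tie at the cutoff

  # g2 survives the median rule (cutoff 4.5) but is expressed in exactly 2
  # samples, so the strict "> 2" detection rule removes it
  y <- rbind(g1 = c(5, 5, 5, 5), g2 = c(0, 0, 9, 9), g3 = c(1, 1, 1, 1))
  expect_identical(rownames(median_filter(y)), "g1")

  expect_error(median_filter(matrix(0, 2, 4)), "detection_floor")
})

test_that("two-group linear fit matches hand computation", {
  x <- rbind(g1 = c(2, 2, 1, 1), g2 = c(3, 1, 1, 1))
  group <- c("case", "case", "control", "control")
  fit <- fit_linear_model(x, group)
  expect_equal(fit$log2FC, c(1, 1))
  expect_equal(fit$s2, c(0, 1))
  expect_equal(fit$df, c(2, 2))
  expect_equal(fit$stderr, c(0, 1))

  swapped <- fit_linear_model(x, rev(group))
  expect_equal(swapped$log2FC, -fit$log2FC)
  expect_equal(swapped$s2, fit$s2)

  expect_error(fit_linear_model(x, c("case", rep("control", 3))),
               "at least 2 samples")
})

test_that("moderation collapses to the common-variance t when variances are equal", {
  set.seed(3)
  x <- matrix(rnorm(40 * 10), 40, 10,
              dimnames = list(paste0("g", 1:40), NULL))
  group <- rep(c("case", "control"), each = 5)
  fit <- fit_linear_model(x, group)
  fit$s2 <- rep(0.5, 40)  # no variance heterogeneity -> d0 = Inf
  mod <- ebayes_moderate(fit)
  expect_true(is.infinite(attr(mod, "prior")$d0))
  t_common <- fit$log2FC / (sqrt(attr(mod, "prior")$s0_sq) *
                              sqrt(1 / 5 + 1 / 5))
  expect_equal(mod$t, t_common, tolerance = 1e-6)
})

test_that("shrinkage moves extreme variances toward the prior", {
  fits <- data.frame(gene = c("big", "small"), log2FC = c(1, 1),
                     s2 = c(25, 0.001), df = c(8, 8),
                     stderr = NA, stringsAsFactors = FALSE)
  attr(fits, "n_case") <- 5; attr(fits, "n_control") <- 5
  mod <- ebayes_moderate(fits, prior = list(d0 = 4, s0_sq = 0.25))
  cc <- sqrt(2 / 5)
  t_ord <- fits$log2FC / (sqrt(fits$s2) * cc)
  expect_gt(abs(mod$t[1]), abs(t_ord[1]))  # large variance shrunk down
  expect_lt(abs(mod$t[2]), abs(t_ord[2]))  # tiny variance pulled up
})

test_that("moderated statistics agree with the reference empirical-Bayes fit", {
  cfg <- simulation_config(n_studies = 1, genes_per_study = 500,
                           samples_per_group = 6, deg_fraction = 0.05,
                           batch_count = 0, seed = 17)
  st <- generate_study(cfg, 1)
  mod <- ebayes_moderate(fit_linear_model(st$matrix, st$group))
  design <- stats::model.matrix(~ factor(st$group, levels = c("control", "case")))
  ref <- limma::eBayes(limma::lmFit(st$matrix, design))
  expect_equal(attr(mod, "prior")$d0, ref$df.prior, tolerance = 1e-8)
  expect_equal(attr(mod, "prior")$s0_sq, ref$s2.prior, tolerance = 1e-8)
  expect_equal(mod$t, unname(ref$t[, 2]), tolerance = 1e-8)
  expect_equal(mod$P.Value, unname(ref$p.value[, 2]), tolerance = 1e-8)
})

test_that("trigamma inversion converges and errors are informative", {
  for (x in c(1e-4, 0.01, 0.5, 2, 50)) {
    expect_equal(trigamma(metadeg:::trigamma_inverse(x)), x, tolerance = 1e-6)
  }
  expect_error(metadeg:::trigamma_inverse(-1), "positive")
  expect_error(fit_variance_prior(c(0, 0, 0), 4), "all sample variances")
})

test_that("BH adjustment matches the brute-force step-up rule", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(4)
  for (i in 1:1000) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_adjust(p), brute_bh(p))
  }
})

test_that("DEG status uses strict thresholds", {
  tab <- data.frame(log2FC = c(1.0, -0.6, 3, 1.2, -0.5),
                    adj.P.Val = c(0.01, 0.04, 0.05, 0.049, 0.01))
  out <- call_degs(tab)
  expect_identical(out$status, c("ns", "down", "ns", "up", "ns"))
})

test_that("confidence intervals cover planted effects at the nominal rate", {
  cfg <- simulation_config(n_studies = 1, genes_per_study = 5000,
                           samples_per_group = 10, deg_fraction = 0.1,
                           effect_size_log2fc = 2, batch_count = 0, seed = 7)
  st <- generate_study(cfg, 1)
  pl <- planted_genes(cfg)
  true_fc <- stats::setNames(rep(0, length(st$gene_ids)), st$gene_ids)
  true_fc[pl$gene] <- pl$sign * 2
  mod <- ebayes_moderate(fit_linear_model(st$matrix, st$group))
  cover <- mean(mod$CI.L <= true_fc[mod$gene] & true_fc[mod$gene] <= mod$CI.R)
  expect_lt(abs(cover - 0.95), 0.02)
})

test_that("tissue Venn regions match brute-force set arithmetic", {
  mk <- function(genes) data.frame(gene = genes, status = "up",
                                   stringsAsFactors = FALSE)
  tabs <- list(s1 = mk("A"), s2 = mk("B"))
  v <- tissue_venn(tabs, c(s1 = "t1", s2 = "t2"))
  expect_equal(v$per_tissue$specific, c(1, 1))
  expect_equal(v$per_tissue$shared, c(0, 0))

  tabs2 <- list(s1 = mk(c("A", "B")), s2 = mk(c("A", "B")))
  v2 <- tissue_venn(tabs2, c(s1 = "t1", s2 = "t2"))
  expect_equal(unname(v2$regions["t1&t2"]), 2L)

  # 3-tissue toy with known overlaps
  tabs3 <- list(s1 = mk(c("A", "B", "C")), s2 = mk(c("B", "C", "D")),
                s3 = mk(c("C", "E")))
  v3 <- tissue_venn(tabs3, c(s1 = "x", s2 = "y", s3 = "z"))
  sets <- list(x = c("A", "B", "C"), y = c("B", "C", "D"), z = c("C", "E"))
  genes <- unique(unlist(sets))
  brute <- table(vapply(genes, function(g)
    paste(names(sets)[vapply(sets, function(s) g %in% s, TRUE)],
          collapse = "&"), ""))
  expect_equal(v3$regions[sort(names(brute))],
               stats::setNames(as.integer(brute[sort(names(brute))]),
                               sort(names(brute))))
  expect_equal(sum(v3$regions), length(genes))
  expect_error(tissue_venn(tabs3, c(s1 = "x", s2 = "y")), "mapped")
})
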