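# Per-study preprocessing and moderated differential expression. The
# statistical core (variance-prior estimation by moment matching on log
# variances, posterior-variance shrinkage, moderated t) is implemented here;
# batch removal delegates to limma::removeBatchEffect and BH adjustment to
# stats::p.adjust.

#' Log2-transform a matrix judged to be on the linear scale
#'
#' Microarray matrices deposited in public repositories are sometimes
#' already log-scale and sometimes linear. Heuristic (`scale = "auto"`): a
#' matrix is judged linear-scale and transformed elementwise with
#' `log2(x + 1)` when its maximum exceeds 30 and it is non-negative; log2
#' intensities essentially never exceed ~20, while negative entries can only
#' arise on a log-like scale. Otherwise the matrix is returned unchanged.
#' `scale = "linear"` forces the transform (negative values are then an
#' error); `scale = "log2"` forces a no-op.
#'
#' @param x numeric matrix.
#' @param scale `"auto"` (heuristic), `"linear"` or `"log2"`.
#' @return matrix on the log2 scale.
#' @export
maybe_log2 <- function(x, scale = c("auto", "linear", "log2")) {
  scale <- match.arg(scale)
  if (scale == "log2") return(x)
  if (scale == "auto" &&
      (max(x, na.rm = TRUE) <= 30 || any(x < 0, na.rm = TRUE)))
    return(x)
  if (any(x < 0, na.rm = TRUE))
    stop("matrix judged linear-scale contains negative values")
  log2(x + 1)
}

#' Remove batch effects while preserving the group effect
#'
#' Per gene, batch coefficients are estimated by least squares jointly with
#' the group effect and only the batch component is subtracted, so group
#' differences are untouched. Batch uses treatment coding (the first batch
#' level is the reference), so samples of the reference batch are returned
#' unchanged; this differs from [limma::removeBatchEffect()]'s sum-to-zero
#' convention only by a per-gene constant. With a single batch level the
#' matrix is returned unchanged. A design in which batch is confounded with
#' group is refused.
#'
#' @param x genes x samples matrix (log2 scale).
#' @param batch per-sample batch labels.
#' @param group per-sample group labels.
#' @return corrected matrix.
#' @export
remove_batch_effect <- function(x, batch, group) {
  batch <- as.factor(batch)
  if (nlevels(batch) < 2) return(x)
  design <- stats::model.matrix(~ factor(group))
  bmat <- stats::model.matrix(~batch)[, -1, drop = FALSE]
  full <- cbind(design, bmat)
  if (qr(full)$rank < ncol(full))
    stop("batch is confounded with group: batch levels {",
         paste(levels(batch), collapse = ", "),
         "} are not estimable jointly with the group effect")
  beta <- qr.coef(qr(full), t(x))  # coefficients x genes
  batch_cols <- seq(ncol(design) + 1, ncol(full))
  x - t(bmat %*% beta[batch_cols, , drop = FALSE])
}

#' Principal-components batch diagnostic
#'
#' PCA on the transposed expression matrix (samples as observations); for
#' each of the top two components the between-batch variance fraction of the
#' scores is computed, and a flag is raised when the PC1 fraction
#' exceeds 0.5.
#'
#' @param x genes x samples matrix.
#' @param batch per-sample batch labels.
#' @return list with `scores` (samples x 2), `batch_fraction` (length 2),
#'   and `flag`.
#' @export
batch_diagnostic <- function(x, batch) {
  if (ncol(x) < 3) stop("need at least 3 samples")
  batch <- as.factor(batch)
  keep <- apply(x, 1, stats::var) > 0
  if (!any(keep)) {
    return(list(scores = matrix(0, ncol(x), 2), batch_fraction = c(0, 0),
                flag = FALSE))
  }
  pc <- stats::prcomp(t(x[keep, , drop = FALSE]), center = TRUE)
  k <- min(2, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  frac <- apply(scores, 2, function(s) {
    tot <- sum((s - mean(s))^2)
    if (tot == 0) return(0)
    between <- sum(tapply(s, batch, function(v) length(v) * (mean(v) - mean(s))^2))
    between / tot
  })
  if (k < 2) frac <- c(frac, 0)
  list(scores = scores, batch_fraction = unname(frac),
       flag = unname(frac[1]) > 0.5)
}

#' Low-expression gene filter
#'
#' Two sequential steps: (1) retain genes whose per-gene median expression
#' is at or above the median of all per-gene medians (ties kept, so a
#' constant matrix passes intact); (2) among those, retain genes expressed
#' (above `detection_floor`) in more than `min_samples` samples.
#'
#' @param x genes x samples matrix (log2 scale).
#' @param detection_floor expression value above which a gene counts as
#'   expressed in a sample (default 0 on the `log2(x+1)` scale).
#' @param min_samples a gene must be expressed in strictly more than this
#'   many samples (default 2).
#' @param center per-gene summary used in step 1, `"median"` or `"mean"`.
#' @return filtered matrix.
#' @export
median_filter <- function(x, detection_floor = 0, min_samples = 2,
                          center = c("median", "mean")) {
  if (nrow(x) < 1) stop("need at least one gene")
  center <- match.arg(center)
  m <- if (center == "median") apply(x, 1, stats::median) else rowMeans(x)
  x1 <- x[m >= stats::median(m), , drop = FALSE]
  expressed <- rowSums(x1 > detection_floor) > min_samples
  out <- x1[expressed, , drop = FALSE]
  if (nrow(out) == 0)
    stop("no genes survive the expression filter; review detection_floor/min_samples")
  out
}

#' Per-gene two-group linear model
#'
#' Ordinary least squares with a case-vs-control contrast:
#' `log2FC = mean(case) - mean(control)`, pooled residual variance, residual
#' degrees of freedom `n_case + n_control - 2`.
#'
#' @param x genes x samples matrix.
#' @param group per-sample labels; values must include `case_label` and
#'   `control_label`, each with at least 2 samples.
#' @param case_label,control_label group level names.
#' @return data frame with columns `gene`, `log2FC`, `s2` (pooled residual
#'   variance), `df`, `stderr`, plus attributes `n_case`/`n_control`.
#' @export
fit_linear_model <- function(x, group, case_label = "case",
                             control_label = "control") {
  is_case <- group == case_label
  is_ctrl <- group == control_label
  n1 <- sum(is_case); n0 <- sum(is_ctrl)
  if (n1 < 2 || n0 < 2)
    stop("each group needs at least 2 samples (case = ", n1,
         ", control = ", n0, ")")
  xc <- x[, is_case, drop = FALSE]
  x0 <- x[, is_ctrl, drop = FALSE]
  m1 <- rowMeans(xc); m0 <- rowMeans(x0)
  ss1 <- rowSums((xc - m1)^2)
  ss0 <- rowSums((x0 - m0)^2)
  df <- n1 + n0 - 2
  s2 <- (ss1 + ss0) / df
  fit <- data.frame(gene = rownames(x), log2FC = m1 - m0, s2 = s2, df = df,
                    stderr = sqrt(s2 * (1 / n1 + 1 / n0)),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(fit, "n_case") <- n1
  attr(fit, "n_control") <- n0
  fit
}

#' Invert the trigamma function
#'
#' Newton iteration solving `trigamma(y) = x`, following the standard
#' empirical-Bayes hyperparameter recipe.
#'
#' @param x positive value(s).
#' @param tol convergence tolerance on the relative step.
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   iteration count.
#' @return y with `trigamma(y) = x`.
#' @keywords internal
trigamma_inverse <- function(x, tol = 1e-8, max_iter = 50) {
  if (any(x <= 0)) stop("trigamma_inverse needs positive input")
  y <- 0.5 + 1 / x
  for (i in seq_len(max_iter)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (max(abs(dif / y)) < tol) return(y)
  }
  stop("trigamma inversion did not converge in ", max_iter, " iterations")
}

#' Estimate the variance prior (d0, s0^2) by moment matching
#'
#' Matches the first two moments of the log sample variances to the
#' log-F/scaled-inverse-chi-square model: with `e_g = log(s_g^2) -
#' digamma(df_g/2) + log(df_g/2)`, `mean(e)` identifies `s0^2` and the
#' excess of `var(e)` over `mean(trigamma(df_g/2))` identifies `d0` through
#' the trigamma function. A non-positive excess yields `d0 = Inf` (no
#' evidence of variance heterogeneity beyond sampling noise).
#'
#' @param s2 per-gene sample variances.
#' @param df per-gene residual degrees of freedom (recycled if scalar).
#' @return list with `d0` and `s0_sq`.
#' @export
fit_variance_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (!any(ok)) stop("all sample variances are zero; cannot estimate the variance prior")
  if (sum(ok) < 10)
    warning("fewer than 10 positive variances; hyperparameter estimates will be unstable")
  s2 <- s2[ok]; df <- df[ok]
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  excess <- stats::var(e) - mean(trigamma(df / 2))
  if (is.finite(excess) && excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Empirical-Bayes moderated t-statistics
#'
#' Shrinks per-gene variances toward the estimated prior:
#' `s2_post = (d0 * s0^2 + df * s2) / (d0 + df)`; the moderated t is
#' `log2FC / (sqrt(s2_post) * c)` with `c = sqrt(1/n_case + 1/n_control)`,
#' two-sided p from a Student-t with `d0 + df` degrees of freedom, and a 95%
#' confidence interval `log2FC +/- t_{0.975, d0+df} * sqrt(s2_post) * c`.
#'
#' @param fits output of [fit_linear_model()] (needs >= 10 genes for stable
#'   hyperparameter estimation).
#' @param prior optional list `(d0, s0_sq)` overriding the estimated prior.
#' @return the fits data frame with added columns `t`, `P.Value`, `CI.L`,
#'   `CI.R`, `s2_post`, `df_total`; the estimated prior is attached as
#'   attribute `"prior"`.
#' @export
ebayes_moderate <- function(fits, prior = NULL) {
  if (is.null(prior)) prior <- fit_variance_prior(fits$s2, fits$df)
  d0 <- prior$d0; s0 <- prior$s0_sq
  s2_post <- if (is.infinite(d0)) rep(s0, nrow(fits)) else
    (d0 * s0 + fits$df * fits$s2) / (d0 + fits$df)
  df_total <- d0 + fits$df
  cc <- sqrt(1 / attr(fits, "n_case") + 1 / attr(fits, "n_control"))
  se <- sqrt(s2_post) * cc
  t_mod <- fits$log2FC / se
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  half <- stats::qt(0.975, df = df_total) * se
  out <- fits
  out$t <- t_mod
  out$P.Value <- p
  out$CI.L <- fits$log2FC - half
  out$CI.R <- fits$log2FC + half
  out$s2_post <- s2_post
  out$df_total <- df_total
  attr(out, "prior") <- prior
  attr(out, "n_case") <- attr(fits, "n_case")
  attr(out, "n_control") <- attr(fits, "n_control")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (delegates to [stats::p.adjust()] after input
#' validation).
#'
#' @param p p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify genes as up/down/ns
#'
#' Strict thresholds: up if `log2FC > fc_up` and `adj.P.Val < alpha`; down
#' if `log2FC < fc_down` and `adj.P.Val < alpha`; otherwise `ns`.
#'
#' @param table data frame with `log2FC` and `adj.P.Val`.
#' @param fc_up,fc_down,alpha thresholds (defaults 1, -0.5, 0.05).
#' @return the table with a `status` column.
#' @export
call_degs <- function(table, fc_up = 1, fc_down = -0.5, alpha = 0.05) {
  status <- rep("ns", nrow(table))
  status[table$log2FC > fc_up & table$adj.P.Val < alpha] <- "up"
  status[table$log2FC < fc_down & table$adj.P.Val < alpha] <- "down"
  table$status <- status
  table
}

#' One study through the full differential-expression stage
#'
#' Sequence: [maybe_log2()], optional [remove_batch_effect()] (when the
#' study has >= 2 batch levels), [median_filter()], [fit_linear_model()],
#' [ebayes_moderate()], [bh_adjust()], [call_degs()].
#'
#' @param study an `expression_study` (see [generate_study()] /
#'   [read_study()]).
#' @param batch_correct correct batch effects when batch labels are present.
#' @param filter apply the low-expression filter.
#' @param fc_up,fc_down,alpha DEG thresholds, see [call_degs()].
#' @param detection_floor,min_samples filter parameters, see
#'   [median_filter()].
#' @return DEG table with columns `gene`, `log2FC`, `CI.L`, `CI.R`, `t`,
#'   `P.Value`, `adj.P.Val`, `status`; the estimated variance prior and the
#'   study id are attached as attributes.
#' @export
run_dex <- function(study, batch_correct = TRUE, filter = TRUE,
                    fc_up = 1, fc_down = -0.5, alpha = 0.05,
                    detection_floor = 0, min_samples = 2) {
  x <- maybe_log2(study$matrix)
  if (batch_correct && !is.null(study$batch) &&
      length(unique(study$batch)) >= 2)
    x <- remove_batch_effect(x, study$batch, study$group)
  if (filter)
    x <- median_filter(x, detection_floor = detection_floor,
                       min_samples = min_samples)
  fits <- fit_linear_model(x, study$group)
  mod <- ebayes_moderate(fits)
  mod$adj.P.Val <- bh_adjust(mod$P.Value)
  mod <- call_degs(mod, fc_up = fc_up, fc_down = fc_down, alpha = alpha)
  out <- mod[, c("gene", "log2FC", "CI.L", "CI.R", "t", "P.Value",
                 "adj.P.Val", "status")]
  attr(out, "prior") <- attr(mod, "prior")
  attr(out, "study_id") <- study$study_id
  out
}

#' Venn summary of DEG sets by tissue
#'
#' Per-tissue DEG sets are the unions of DEG symbols over the studies of the
#' tissue; every non-empty region of the k-set Venn diagram is counted, and
#' tissue-specific (exactly one tissue) vs shared counts are reported.
#'
#' @param deg_tables named list of DEG tables (per study).
#' @param study_to_tissue named character vector mapping study id -> tissue.
#' @return list with `sets` (per-tissue DEG symbol sets), `regions` (named
#'   count vector, names like `"adipose&muscle"`), and `per_tissue` (data
#'   frame with columns `tissue`, `total`, `specific`, `shared`).
#' @export
tissue_venn <- function(deg_tables, study_to_tissue) {
  ids <- names(deg_tables)
  if (is.null(ids) || !all(ids %in% names(study_to_tissue)))
    stop("every DEG table must be named and mapped to a tissue")
  tissues <- unique(unname(study_to_tissue[ids]))
  sets <- lapply(tissues, function(tt) {
    tabs <- deg_tables[ids[study_to_tissue[ids] == tt]]
    unique(unlist(lapply(tabs, function(d) d$gene[d$status != "ns"])))
  })
  names(sets) <- tissues
  all_genes <- unique(unlist(sets))
  membership <- vapply(sets, function(s) all_genes %in% s,
                       logical(length(all_genes)))
  if (length(all_genes) == 1) membership <- matrix(membership, nrow = 1,
                                                   dimnames = list(NULL, tissues))
  key <- apply(membership, 1, function(m) paste(tissues[m], collapse = "&"))
  regions <- table(key[key != ""])
  n_in <- if (length(all_genes)) rowSums(membership) else integer(0)
  per_tissue <- data.frame(
    tissue = tissues,
    total = vapply(sets, length, 0L),
    specific = vapply(tissues, function(tt)
      sum(membership[, tt] & n_in == 1), 0L),
    shared = vapply(tissues, function(tt)
      sum(membership[, tt] & n_in > 1), 0L),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(sets = sets,
       regions = stats::setNames(as.integer(regions), names(regions)),
       per_tissue = per_tissue)
}
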