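# Three meta-analytic strategies over per-study DEG tables: random-effects
# fold-change synthesis (DerSimonian-Laird), vote counting with sign
# consistency, and Fisher p-value combining; plus top-percentile extraction
# and compilation of the highly perturbed gene set.

#' Meta-analysis configuration
#'
#' @param metathr proportion of the top-most perturbed genes extracted by
#'   [top_perturbed()] (default 0.01, the top 1%).
#' @param vc_p_threshold per-study p-value threshold used by vote counting
#'   (default 0.05).
#' @param vc_abs_fc_threshold per-study absolute fold-change threshold used
#'   by vote counting (default 0).
#' @param p_floor smallest p-value fed to Fisher's log (default 1e-300).
#' @param ca_center central tendency of the combining approach's summary
#'   fold-change, `"mean"` or `"median"`.
#' @return an object of class `meta_config`.
#' @export
meta_config <- function(metathr = 0.01, vc_p_threshold = 0.05,
                        vc_abs_fc_threshold = 0, p_floor = 1e-300,
                        ca_center = c("mean", "median")) {
  if (metathr <= 0 || metathr > 1) stop("metathr must lie in (0, 1]")
  cfg <- list(metathr = metathr, vc_p_threshold = vc_p_threshold,
              vc_abs_fc_threshold = vc_abs_fc_threshold, p_floor = p_floor,
              ca_center = match.arg(ca_center))
  class(cfg) <- "meta_config"
  cfg
}

# Stack per-study tables into one long frame (gene, study, log2FC, p, v).
# Within-study variances derive from the CI width: v = ((CI.R - CI.L)/3.92)^2.
stack_studies <- function(study_tables, need_ci = TRUE) {
  if (length(study_tables) == 0) stop("need at least one study table")
  if (is.null(names(study_tables)))
    names(study_tables) <- paste0("study", seq_along(study_tables))
  rows <- lapply(names(study_tables), function(id) {
    d <- study_tables[[id]]
    if (!all(c("gene", "log2FC", "P.Value") %in% colnames(d)))
      stop("study table '", id, "' lacks gene/log2FC/P.Value columns")
    v <- rep(NA_real_, nrow(d))
    if (all(c("CI.L", "CI.R") %in% colnames(d))) {
      if (any(d$CI.R < d$CI.L)) stop("CI.R < CI.L in study table '", id, "'")
      v <- ((d$CI.R - d$CI.L) / (2 * 1.96))^2
    } else if (need_ci) {
      stop("study table '", id, "' lacks CI.L/CI.R columns")
    }
    data.frame(gene = toupper(d$gene), study = id, log2FC = d$log2FC,
               p = d$P.Value, v = v, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Random-effects model (REM) meta-analysis of fold-changes
#'
#' Per gene, over the studies where it is present: within-study variances
#' are derived from the 95% CI width, between-study variance tau^2 by the
#' DerSimonian-Laird moment estimator, random-effects weights
#' `1/(v + tau^2)`, and a two-sided normal p-value for the summary
#' fold-change against zero.
#'
#' @param study_tables list of DEG tables with columns `gene`, `log2FC`,
#'   `CI.L`, `CI.R`, `P.Value`.
#' @param config a [meta_config()].
#' @return data frame with columns `gene`, `n_studies_present`, `rem_fc`,
#'   `rem_se`, `rem_p`, `tau_sq`, `mean_fc`.
#' @export
rem_meta <- function(study_tables, config = meta_config()) {
  long <- stack_studies(study_tables, need_ci = TRUE)
  idx <- split(seq_len(nrow(long)), long$gene)
  res <- lapply(idx, function(i) {
    fc <- long$log2FC[i]; v <- long$v[i]; k <- length(i)
    w <- 1 / v
    fixed <- sum(w * fc) / sum(w)
    tau2 <- 0
    if (k > 1) {
      Q <- sum(w * (fc - fixed)^2)
      denom <- sum(w) - sum(w^2) / sum(w)
      if (denom > 0) tau2 <- max(0, (Q - (k - 1)) / denom)
    }
    ws <- 1 / (v + tau2)
    est <- sum(ws * fc) / sum(ws)
    se <- sqrt(1 / sum(ws))
    c(k = k, est = est, se = se, tau2 = tau2, mean_fc = mean(fc))
  })
  m <- do.call(rbind, res)
  data.frame(gene = names(idx),
             n_studies_present = as.integer(m[, "k"]),
             rem_fc = m[, "est"], rem_se = m[, "se"],
             rem_p = 2 * stats::pnorm(-abs(m[, "est"] / m[, "se"])),
             tau_sq = m[, "tau2"], mean_fc = m[, "mean_fc"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Vote-counting (VC) meta-analysis
#'
#' Per gene: `n_up` counts studies with `p < vc_p_threshold` and
#' `log2FC > vc_abs_fc_threshold`, `n_down` those with `p < vc_p_threshold`
#' and `log2FC < -vc_abs_fc_threshold`; `ndiff = n_up + n_down` and
#' `sign_consistency = n_up - n_down`.
#'
#' @inheritParams rem_meta
#' @return data frame with columns `gene`, `n_studies_present`, `n_up`,
#'   `n_down`, `ndiff`, `sign_consistency`, `mean_fc`.
#' @export
vc_meta <- function(study_tables, config = meta_config()) {
  long <- stack_studies(study_tables, need_ci = FALSE)
  de <- long$p < config$vc_p_threshold
  up <- de & long$log2FC > config$vc_abs_fc_threshold
  dn <- de & long$log2FC < -config$vc_abs_fc_threshold
  genes <- sort(unique(long$gene))
  f <- factor(long$gene, levels = genes)
  n_up <- as.integer(tapply(up, f, sum, default = 0L))
  n_down <- as.integer(tapply(dn, f, sum, default = 0L))
  data.frame(gene = genes,
             n_studies_present = as.integer(tabulate(f, length(genes))),
             n_up = n_up, n_down = n_down,
             ndiff = n_up + n_down,
             sign_consistency = n_up - n_down,
             mean_fc = as.numeric(tapply(long$log2FC, f, mean)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' p-value combining (CA) meta-analysis by Fisher's method
#'
#' Per gene: summary fold-change at the mean (or median) level, Fisher
#' statistic `-2 * sum(log(p))` over the studies where the gene is present,
#' and the upper chi-square tail with `2 * n_studies_present` degrees of
#' freedom. p-values are floored at `config$p_floor` before the log.
#'
#' @inheritParams rem_meta
#' @return data frame with columns `gene`, `n_studies_present`, `ca_fc`,
#'   `fisher_stat`, `fisher_p`.
#' @export
ca_meta <- function(study_tables, config = meta_config()) {
  long <- stack_studies(study_tables, need_ci = FALSE)
  genes <- sort(unique(long$gene))
  f <- factor(long$gene, levels = genes)
  centerf <- if (config$ca_center == "mean") mean else stats::median
  k <- as.integer(tabulate(f, length(genes)))
  stat <- as.numeric(tapply(-2 * log(pmax(long$p, config$p_floor)), f, sum))
  data.frame(gene = genes, n_studies_present = k,
             ca_fc = as.numeric(tapply(long$log2FC, f, centerf)),
             fisher_stat = stat,
             fisher_p = stats::pchisq(stat, df = 2 * k, lower.tail = FALSE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Inverse cumulative distribution of vote counts
#'
#' For each k from 1 to `max(ndiff)`, the number of genes differentially
#' expressed in at least k studies.
#'
#' @param vc_summaries output of [vc_meta()].
#' @return data frame with columns `k` and `n_genes` (non-increasing in k);
#'   zero rows when no gene has `ndiff >= 1`.
#' @export
inverse_cumulative_distribution <- function(vc_summaries) {
  mx <- suppressWarnings(max(vc_summaries$ndiff))
  if (!is.finite(mx) || mx < 1)
    return(data.frame(k = integer(0), n_genes = integer(0)))
  k <- seq_len(mx)
  data.frame(k = k,
             n_genes = vapply(k, function(kk) sum(vc_summaries$ndiff >= kk), 0L))
}

#' Extract the top-most perturbed genes from one meta-analytic model
#'
#' Ranking: REM by summary p ascending (ties by |summary FC| descending);
#' VC by `ndiff` descending, then |sign consistency| descending, then
#' |mean FC| descending; CA by Fisher p ascending (ties by |summary FC|
#' descending). The top `ceiling(metathr * G)` genes are returned, where G
#' is the number of genes present in at least one study. Regulation is the
#' sign of the model's summary fold-change.
#'
#' @param summaries output of the matching `*_meta()` function.
#' @param model one of `"REM"`, `"VC"`, `"CA"`.
#' @param config a [meta_config()].
#' @return data frame with columns `gene`, `regulation` (`"up"`/`"down"`),
#'   `source`.
#' @export
top_perturbed <- function(summaries, model = c("REM", "VC", "CA"),
                          config = meta_config()) {
  model <- match.arg(model)
  ord <- switch(model,
    REM = order(summaries$rem_p, -abs(summaries$rem_fc)),
    VC = order(-summaries$ndiff, -abs(summaries$sign_consistency),
               -abs(summaries$mean_fc)),
    CA = order(summaries$fisher_p, -abs(summaries$ca_fc))
  )
  fc <- switch(model, REM = summaries$rem_fc, VC = summaries$mean_fc,
               CA = summaries$ca_fc)
  n_top <- ceiling(config$metathr * nrow(summaries))
  sel <- ord[seq_len(min(n_top, length(ord)))]
  data.frame(gene = summaries$gene[sel],
             regulation = ifelse(fc[sel] >= 0, "up", "down"),
             source = model, row.names = NULL, stringsAsFactors = FALSE)
}

#' Compile the union of perturbed gene sets
#'
#' Symbol-unique union of several `(gene, regulation, source)` sets.
#' Conflicting regulation labels for the same gene across sources are an
#' error listing the offending genes.
#'
#' @param sets list of data frames with columns `gene`, `regulation` and
#'   optionally `source`.
#' @return data frame with columns `gene`, `regulation`, `source`
#'   (semicolon-joined contributing sources).
#' @export
compile_union <- function(sets) {
  if (length(sets) == 0) stop("need at least one input set")
  all <- do.call(rbind, lapply(sets, function(s) {
    if (is.null(s$source)) s$source <- "set"
    s[, c("gene", "regulation", "source")]
  }))
  all$gene <- toupper(all$gene)
  reg <- tapply(all$regulation, all$gene, unique)
  bad <- names(reg)[vapply(reg, length, 0L) > 1]
  if (length(bad) > 0)
    stop("conflicting regulation across sources for: ",
         paste(sort(bad), collapse = ", "))
  genes <- unique(all$gene)
  data.frame(
    gene = genes,
    regulation = vapply(reg[genes], `[[`, "", 1),
    source = vapply(genes, function(g)
      paste(unique(all$source[all$gene == g]), collapse = ";"), ""),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
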