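# Summary statistics on count pairs, tabular result summaries, and the
# umbrella pipeline wiring all stages over a (synthetic or supplied)
# multi-study collection.

#' One-sided continuity-corrected proportion test on the larger count
#'
#' Tests whether the larger of two counts exceeds half of their total, with
#' a 0.5 continuity correction under the normal approximation:
#' `z = (larger - 0.5 - n/2) / sqrt(n/4)`, `p = P(Z >= z)`. An exact
#' binomial tail is available via `exact = TRUE`.
#'
#' @param count_a,count_b non-negative integer counts.
#' @param exact use the exact binomial upper tail `P(X >= larger)` under
#'   Binomial(n, 1/2) instead of the normal approximation.
#' @return list of class `proportion_comparison` with elements `count_a`,
#'   `count_b`, `n`, `larger`, `z`, `p_one_sided`.
#' @export
larger_proportion_test <- function(count_a, count_b, exact = FALSE) {
  if (count_a < 0 || count_b < 0) stop("counts must be non-negative")
  n <- count_a + count_b
  if (n < 1) stop("need count_a + count_b >= 1")
  larger <- max(count_a, count_b)
  z <- (larger - 0.5 - n / 2) / sqrt(n / 4)
  p <- if (exact) stats::pbinom(larger - 1, n, 0.5, lower.tail = FALSE)
       else stats::pnorm(z, lower.tail = FALSE)
  out <- list(count_a = count_a, count_b = count_b, n = n, larger = larger,
              z = z, p_one_sided = p)
  class(out) <- "proportion_comparison"
  out
}

#' @export
print.proportion_comparison <- function(x, ...) {
  cat(sprintf("larger-proportion test: %d vs %d (n = %d), z = %.4f, p = %.6f\n",
              x$count_a, x$count_b, x$n, x$z, x$p_one_sided))
  invisible(x)
}

#' Summary count tables with proportion tests
#'
#' Per-study up/down DEG counts, per-tissue totals with an up-vs-down test,
#' tissue-specific vs shared counts with a test, and up/down partitions of
#' the compiled perturbed set and the hub set with tests. Comparisons with
#' zero total are skipped (p reported as NA).
#'
#' @param deg_tables named list of per-study DEG tables.
#' @param study_to_tissue named character vector study id -> tissue.
#' @param compiled optional compiled perturbed set ([compile_union()]).
#' @param hub_records optional hub-selection records ([select_hubs()]) with a
#'   `regulation` column for non-predicted nodes.
#' @return list of data frames: `per_study`, `per_tissue`, `set_partitions`.
#' @export
summarize_counts <- function(deg_tables, study_to_tissue, compiled = NULL,
                             hub_records = NULL) {
  test_p <- function(a, b) {
    if (a + b < 1) return(NA_real_)
    larger_proportion_test(a, b)$p_one_sided
  }
  per_study <- data.frame(
    study = names(deg_tables),
    tissue = unname(study_to_tissue[names(deg_tables)]),
    n_up = vapply(deg_tables, function(d) sum(d$status == "up"), 0L),
    n_down = vapply(deg_tables, function(d) sum(d$status == "down"), 0L),
    row.names = NULL, stringsAsFactors = FALSE
  )
  per_study$n_deg <- per_study$n_up + per_study$n_down

  venn <- tissue_venn(deg_tables, study_to_tissue)
  agg_up <- tapply(per_study$n_up, per_study$tissue, sum)
  agg_dn <- tapply(per_study$n_down, per_study$tissue, sum)
  tt <- venn$per_tissue$tissue
  per_tissue <- data.frame(
    tissue = tt,
    n_up = as.integer(agg_up[tt]),
    n_down = as.integer(agg_dn[tt]),
    specific = venn$per_tissue$specific,
    shared = venn$per_tissue$shared,
    row.names = NULL, stringsAsFactors = FALSE
  )
  per_tissue$p_up_vs_down <- mapply(test_p, per_tissue$n_up, per_tissue$n_down)
  per_tissue$p_specific_vs_shared <-
    mapply(test_p, per_tissue$specific, per_tissue$shared)

  parts <- list()
  total <- c(up = sum(per_study$n_up), down = sum(per_study$n_down))
  parts[["all_degs"]] <- c(total, p = test_p(unname(total["up"]),
                                             unname(total["down"])))
  if (!is.null(compiled)) {
    u <- sum(compiled$regulation == "up"); d <- sum(compiled$regulation == "down")
    parts[["compiled"]] <- c(up = u, down = d, p = test_p(u, d))
  }
  if (!is.null(hub_records) && !is.null(hub_records$regulation)) {
    hr <- hub_records[hub_records$is_hub & !hub_records$predicted, ]
    u <- sum(hr$regulation == "up", na.rm = TRUE)
    d <- sum(hr$regulation == "down", na.rm = TRUE)
    parts[["hubs"]] <- c(up = u, down = d, p = test_p(u, d))
  }
  set_partitions <- data.frame(
    set = names(parts),
    n_up = vapply(parts, function(p) as.integer(p[["up"]]), 0L),
    n_down = vapply(parts, function(p) as.integer(p[["down"]]), 0L),
    p_one_sided = vapply(parts, function(p) as.numeric(p[["p"]]), 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(per_study = per_study, per_tissue = per_tissue,
       set_partitions = set_partitions, venn = venn)
}

#' Pipeline configuration
#'
#' @param synth a [simulation_config()] describing the synthetic collection.
#' @param meta a [meta_config()].
#' @param fc_up,fc_down,alpha DEG thresholds, see [call_degs()].
#' @param min_degree network pruning threshold.
#' @param interactome_m preferential-attachment edges per node for the
#'   synthetic interactome.
#' @param n_terms,term_size_range synthetic gene-set library shape.
#' @param background_size enrichment background N.
#' @param stages character vector of stages to run, a subset of
#'   `c("dex", "meta", "network", "enrich")`; later stages require earlier
#'   ones.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = simulation_config(),
                            meta = meta_config(),
                            fc_up = 1, fc_down = -0.5, alpha = 0.05,
                            min_degree = 2, interactome_m = 3,
                            n_terms = 50, term_size_range = c(10, 100),
                            background_size = 20000,
                            stages = c("dex", "meta", "network", "enrich")) {
  cfg <- list(synth = synth, meta = meta, fc_up = fc_up, fc_down = fc_down,
              alpha = alpha, min_degree = min_degree,
              interactome_m = interactome_m, n_terms = n_terms,
              term_size_range = term_size_range,
              background_size = background_size, stages = stages)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full evidence-synthesis pipeline
#'
#' Generates (or accepts) a multi-study collection, runs per-study
#' differential expression, the three meta-analytic models with
#' top-percentile extraction and compilation, interaction-network hub
#' selection on the compiled set, over-representation analysis of the
#' compiled and hub sets, and the summary count tables. Studies without any
#' DEG are excluded from the meta-analysis stage. Fully deterministic for a
#' fixed configuration.
#'
#' @param config a [pipeline_config()].
#' @param studies optional list of `expression_study` objects (generated
#'   from `config$synth` when omitted).
#' @param interactome optional edge-list data frame; a scale-free synthetic
#'   interactome over the gene universe is generated when omitted.
#' @param gene_set_lib optional [gene_set_library()]; a synthetic library is
#'   generated when omitted.
#' @return list with elements `config`, `deg_tables`, `summaries` (REM/VC/CA),
#'   `top_sets`, `compiled`, `inverse_cdf`, `centrality`, `hub_genes`,
#'   `enrichment` (compiled and hub), `counts`.
#' @export
run_pipeline <- function(config = pipeline_config(), studies = NULL,
                         interactome = NULL, gene_set_lib = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  res <- list(config = config)
  if (length(config$stages) == 0 || !"dex" %in% config$stages) return(res)

  if (is.null(studies)) studies <- generate_collection(config$synth)
  study_to_tissue <- vapply(studies, function(s)
    if (is.null(s$tissue)) NA_character_ else s$tissue, "")

  deg_tables <- lapply(studies, run_dex, fc_up = config$fc_up,
                       fc_down = config$fc_down, alpha = config$alpha)
  res$deg_tables <- deg_tables
  res$study_to_tissue <- study_to_tissue
  if (!"meta" %in% config$stages) return(res)

  with_degs <- vapply(deg_tables, function(d) any(d$status != "ns"), TRUE)
  if (!any(with_degs)) stop("meta stage: no study has any DEG")
  meta_in <- deg_tables[with_degs]
  summaries <- list(REM = rem_meta(meta_in, config$meta),
                    VC = vc_meta(meta_in, config$meta),
                    CA = ca_meta(meta_in, config$meta))
  top_sets <- list(REM = top_perturbed(summaries$REM, "REM", config$meta),
                   VC = top_perturbed(summaries$VC, "VC", config$meta),
                   CA = top_perturbed(summaries$CA, "CA", config$meta))
  res$summaries <- summaries
  res$top_sets <- top_sets
  res$compiled <- compile_union(top_sets)
  res$inverse_cdf <- inverse_cumulative_distribution(summaries$VC)
  if (!"network" %in% config$stages) return(res)

  universe <- sort(unique(unlist(lapply(studies, `[[`, "gene_ids"))))
  if (is.null(interactome))
    interactome <- generate_interactome(length(universe),
                                        config$interactome_m,
                                        seed = config$synth$seed,
                                        node_ids = universe)
  g <- load_network(interactome)
  seed_nodes <- intersect(igraph::V(g)$name, res$compiled$gene)
  # emulate the prediction service: the query plus its direct interactors,
  # added nodes flagged as predicted
  keep <- unique(unlist(lapply(igraph::ego(g, 1, nodes = seed_nodes),
                               igraph::as_ids)))
  sub <- igraph::induced_subgraph(g, keep)
  node_attrs <- data.frame(node = keep,
                           predicted = !(keep %in% res$compiled$gene))
  cent <- run_nethub(igraph::as_data_frame(sub, what = "edges"),
                     min_degree = config$min_degree, node_attrs = node_attrs)
  cent$regulation <-
    res$compiled$regulation[match(cent$node, res$compiled$gene)]
  res$centrality <- cent
  res$hub_genes <- cent$node[cent$is_hub]
  if (!"enrich" %in% config$stages) return(res)

  if (is.null(gene_set_lib))
    gene_set_lib <- generate_gene_set_library(
      universe, config$n_terms, config$term_size_range,
      seed = config$synth$seed, background_size = config$background_size)
  reg <- stats::setNames(res$compiled$regulation, res$compiled$gene)
  res$enrichment <- list(
    compiled = enrich(res$compiled$gene, gene_set_lib, regulation = reg),
    hubs = if (length(res$hub_genes) > 0)
      enrich(res$hub_genes, gene_set_lib, regulation = reg) else NULL
  )
  res$counts <- summarize_counts(deg_tables, study_to_tissue,
                                 compiled = res$compiled,
                                 hub_records = cent)
  res
}
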