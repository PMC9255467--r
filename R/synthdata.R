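#' Configuration for a synthetic multi-study expression collection
#'
#' Bundles and validates the parameters of the generative model used by
#' [generate_study()] and [generate_collection()]. The model emulates a
#' collection of small two-group (case/control) microarray studies on the
#' log2 scale: gene-wise true variances are drawn from a scaled
#' inverse-chi-square prior (the prior assumed by the moderated-t machinery
#' in [ebayes_moderate()]), a fixed fraction of genes carries a planted
#' group-mean shift whose identity and sign are shared across all studies,
#' and optional per-gene batch offsets create removable batch structure.
#'
#' @param n_studies number of studies in the collection.
#' @param genes_per_study number of genes per study.
#' @param samples_per_group samples in each of the case and control groups.
#' @param deg_fraction fraction of genes with a planted nonzero log2
#'   fold-change (shared identity and sign across studies).
#' @param effect_size_log2fc absolute planted log2 fold-change.
#' @param sign_mix fraction of planted genes that are upregulated.
#' @param prior_df_d0 prior degrees of freedom of the variance prior.
#' @param prior_scale_s0sq prior scale (variance) of the variance prior.
#' @param batch_count number of batches per study (0 or 1 disables batch
#'   structure); batches are assigned round-robin within each group so the
#'   design stays balanced.
#' @param batch_sd standard deviation of the per-gene, per-batch offsets.
#' @param tissue_labels character vector of length `n_studies` assigning each
#'   study to a tissue group; by default four tissue labels are recycled
#'   across the studies.
#' @param baseline_mean,baseline_sd mean and SD of the per-study gene
#'   baseline expression (log2 scale).
#' @param seed master seed; study `i` uses substream `seed + i`.
#' @return an object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_studies = 16,
                              genes_per_study = 2000,
                              samples_per_group = 10,
                              deg_fraction = 0.01,
                              effect_size_log2fc = 2,
                              sign_mix = 0.5,
                              prior_df_d0 = 4,
                              prior_scale_s0sq = 0.25,
                              batch_count = 2,
                              batch_sd = 0.5,
                              tissue_labels = NULL,
                              baseline_mean = 7,
                              baseline_sd = 1.5,
                              seed = 1) {
  if (n_studies < 1 || genes_per_study < 1 || samples_per_group < 2)
    stop("non-positive dimensions: need n_studies >= 1, genes_per_study >= 1, samples_per_group >= 2")
  if (deg_fraction < 0 || deg_fraction > 1)
    stop("deg_fraction must lie in [0, 1]")
  if (sign_mix < 0 || sign_mix > 1)
    stop("sign_mix must lie in [0, 1]")
  if (prior_df_d0 <= 0 || prior_scale_s0sq <= 0)
    stop("variance prior parameters must be positive")
  if (batch_count < 0 || batch_sd < 0)
    stop("batch parameters must be non-negative")
  if (is.null(tissue_labels)) {
    tissue_labels <- rep(c("circulatory", "adipose", "digestive", "muscle"),
                         length.out = n_studies)
  }
  if (length(tissue_labels) != n_studies)
    stop("tissue_labels must have length n_studies (",
         length(tissue_labels), " != ", n_studies, ")")
  cfg <- list(
    n_studies = as.integer(n_studies),
    genes_per_study = as.integer(genes_per_study),
    samples_per_group = as.integer(samples_per_group),
    deg_fraction = deg_fraction,
    effect_size_log2fc = effect_size_log2fc,
    sign_mix = sign_mix,
    prior_df_d0 = prior_df_d0,
    prior_scale_s0sq = prior_scale_s0sq,
    batch_count = as.integer(batch_count),
    batch_sd = batch_sd,
    tissue_labels = as.character(tissue_labels),
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  cfg
}

synthetic_gene_ids <- function(n) sprintf("G%06d", seq_len(n))

#' Planted differentially expressed genes of a configuration
#'
#' The planted identity list is a deterministic function of the
#' configuration (the first `round(deg_fraction * genes_per_study)` gene
#' ids), so it is shared by every study of a collection.
#'
#' @param config a [simulation_config()].
#' @return data frame with columns `gene` and `sign` (+1 up, -1 down);
#'   zero rows when no genes are planted.
#' @export
planted_genes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n_deg <- round(config$deg_fraction * config$genes_per_study)
  if (n_deg == 0)
    return(data.frame(gene = character(0), sign = numeric(0)))
  ids <- synthetic_gene_ids(config$genes_per_study)[seq_len(n_deg)]
  n_up <- round(config$sign_mix * n_deg)
  data.frame(gene = ids,
             sign = c(rep(1, n_up), rep(-1, n_deg - n_up)),
             stringsAsFactors = FALSE)
}

#' Generate one synthetic two-group expression study
#'
#' Draws a genes x samples log2-scale matrix. Per gene g the true variance is
#' `sigma_g^2 = s0_sq * d0 / rchisq(d0)` (scaled inverse-chi-square), the
#' baseline mean is Normal(`baseline_mean`, `baseline_sd^2`) (redrawn per
#' study), planted genes add `sign * effect_size_log2fc` to the case group
#' mean, and, when `batch_count >= 2`, per-gene batch offsets
#' Normal(0, `batch_sd^2`) are added to every sample of the batch.
#' Deterministic for a fixed `(seed, study_index)`.
#'
#' @param config a [simulation_config()].
#' @param study_index 1-based study index (`<= n_studies`).
#' @return an object of class `expression_study`: a list with elements
#'   `study_id`, `gene_ids`, `matrix` (rownames = genes, colnames = samples),
#'   `group` (`"case"`/`"control"` per sample), `batch` (or `NULL`) and
#'   `tissue`.
#' @export
generate_study <- function(config, study_index) {
  stopifnot(inherits(config, "simulation_config"))
  if (study_index < 1 || study_index > config$n_studies)
    stop("study_index must lie in 1..n_studies")
  set.seed(config$seed + as.integer(study_index))

  G <- config$genes_per_study
  npg <- config$samples_per_group
  n <- 2L * npg
  genes <- synthetic_gene_ids(G)
  group <- rep(c("control", "case"), each = npg)

  sigma2 <- config$prior_scale_s0sq * config$prior_df_d0 /
    stats::rchisq(G, df = config$prior_df_d0)
  mu <- stats::rnorm(G, config$baseline_mean, config$baseline_sd)

  delta <- numeric(G)
  pl <- planted_genes(config)
  if (nrow(pl) > 0)
    delta[match(pl$gene, genes)] <- pl$sign * config$effect_size_log2fc

  mean_mat <- matrix(mu, G, n) +
    outer(delta, as.numeric(group == "case"))
  noise <- matrix(stats::rnorm(G * n, 0, sqrt(sigma2)), G, n)
  x <- mean_mat + noise

  batch <- NULL
  if (config$batch_count >= 2) {
    batch <- paste0("B", ((seq_len(npg) - 1L) %% config$batch_count) + 1L)
    batch <- c(batch, batch)  # same round-robin within each group: balanced
    offs <- matrix(stats::rnorm(G * config$batch_count, 0, config$batch_sd),
                   G, config$batch_count)
    x <- x + offs[, match(batch, paste0("B", seq_len(config$batch_count)))]
  }

  rownames(x) <- genes
  colnames(x) <- sprintf("S%02d", seq_len(n))
  study <- list(
    study_id = sprintf("SYN%02d", as.integer(study_index)),
    gene_ids = genes,
    matrix = x,
    group = group,
    batch = batch,
    tissue = config$tissue_labels[[study_index]]
  )
  class(study) <- "expression_study"
  study
}

#' Generate a collection of synthetic studies
#'
#' All studies share the planted gene identity list and planted signs, so
#' the planted fold-changes are sign-consistent across the collection.
#'
#' @param config a [simulation_config()].
#' @return list of [generate_study()] results, named by study id.
#' @export
generate_collection <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  studies <- lapply(seq_len(config$n_studies),
                    function(i) generate_study(config, i))
  names(studies) <- vapply(studies, `[[`, "", "study_id")
  studies
}

#' Generate a scale-free synthetic interactome
#'
#' Preferential-attachment (Barabasi-Albert) undirected simple graph: each
#' new node attaches `edges_per_new_node` edges to existing nodes with
#' probability proportional to degree. The result is connected, with no
#' self-loops or duplicate edges, and a heavy-tailed degree distribution.
#'
#' @param n_nodes number of nodes.
#' @param edges_per_new_node edges added per incoming node (`m`).
#' @param seed integer seed.
#' @param node_ids optional character vector of `n_nodes` node labels;
#'   defaults to `N0001...`.
#' @return data frame edge list with columns `from` and `to`.
#' @export
generate_interactome <- function(n_nodes, edges_per_new_node = 2, seed = 1,
                                 node_ids = NULL) {
  if (edges_per_new_node < 1 || n_nodes <= edges_per_new_node)
    stop("need n_nodes > edges_per_new_node >= 1")
  if (is.null(node_ids)) node_ids <- sprintf("N%04d", seq_len(n_nodes))
  if (length(node_ids) != n_nodes)
    stop("node_ids must have length n_nodes")
  set.seed(as.integer(seed))
  g <- igraph::sample_pa(n_nodes, m = edges_per_new_node, directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  data.frame(from = node_ids[el[, 1]], to = node_ids[el[, 2]],
             stringsAsFactors = FALSE)
}

#' Generate a synthetic gene-set library
#'
#' Each term is a uniform sample (without replacement) from the universe,
#' with sizes uniform over `size_range`.
#'
#' @param universe character vector of gene symbols.
#' @param n_terms number of terms.
#' @param size_range integer pair `c(min, max)` of term sizes.
#' @param seed integer seed.
#' @param background_size background gene count `N` for enrichment
#'   (default 20000).
#' @return a [gene_set_library()].
#' @export
generate_gene_set_library <- function(universe, n_terms, size_range = c(5, 50),
                                      seed = 1, background_size = 20000) {
  if (length(universe) == 0) stop("universe must be non-empty")
  size_range <- as.integer(size_range)
  if (length(size_range) != 2 || size_range[1] < 1 ||
      size_range[2] > length(universe) || size_range[1] > size_range[2])
    stop("size_range must lie within [1, |universe|]")
  set.seed(as.integer(seed))
  sizes <- size_range[1] - 1L +
    sample.int(size_range[2] - size_range[1] + 1L, n_terms, replace = TRUE)
  terms <- lapply(sizes, function(s) sample(universe, s))
  names(terms) <- sprintf("TERM%03d", seq_len(n_terms))
  gene_set_library(terms, name = "synthetic", background_size = background_size)
}
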