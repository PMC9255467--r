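# Accessors for the bundled reference tables: the highly perturbed gene
# lists (with regulation labels) reported per meta-analytic model by a
# published 16-microarray meta-analysis of type 2 diabetes, and the hub-gene
# topology table from the same study's network stage. Used as worked-example
# inputs for the set-arithmetic and proportion-test stages.

#' Published highly perturbed gene lists (per meta-analytic model)
#'
#' Columns `model` (`REM`/`VC`/`CA`), `gene`, `regulation` (`up`/`down`).
#'
#' @return data frame.
#' @export
t2d_reported_gene_sets <- function() {
  utils::read.delim(system.file("extdata", "t2d_meta_gene_sets.tsv",
                                package = "metadeg"),
                    stringsAsFactors = FALSE)
}

#' Published hub-gene topology table
#'
#' Columns `gene`, `betweenness`, `closeness`, `degree`, `regulation`
#' (`NA` for nodes added by the prediction service), `predicted`.
#'
#' @return data frame.
#' @export
t2d_reported_hub_topology <- function() {
  utils::read.delim(system.file("extdata", "t2d_hub_topology.tsv",
                                package = "metadeg"),
                    stringsAsFactors = FALSE)
}
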