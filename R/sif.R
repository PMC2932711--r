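#' Export signed, scored edges as SIF plus a score table
#'
#' Writes Cytoscape-style SIF lines `geneA pos geneB` / `geneA neg geneB`
#' (relation from the sign of rho) and a companion TSV with columns
#' `gene_a`, `gene_b`, `dataset_id`, `rho`. An empty edge list produces an
#' empty SIF file (no header) and a header-only companion TSV.
#'
#' @param edges A `correlation_edges` data frame (columns `gene_a`,
#'   `gene_b`, `rho`, `dataset_id`), e.g. from [pairwise_correlations()].
#' @param sif_path Output path for the SIF file.
#' @param tsv_path Output path for the score TSV; defaults to the SIF
#'   path with extension replaced by `_edges.tsv`.
#' @return Invisibly, a list with the two paths written.
#' @export
write_network_sif <- function(edges, sif_path,
                              tsv_path = paste0(tools::file_path_sans_ext(sif_path),
                                                "_edges.tsv")) {
  stopifnot(is.data.frame(edges))
  need <- c("gene_a", "gene_b", "rho", "dataset_id")
  if (!all(need %in% names(edges))) {
    stop("`edges` needs columns gene_a, gene_b, rho, dataset_id", call. = FALSE)
  }
  rel <- ifelse(edges$rho >= 0, "pos", "neg")
  sif_lines <- if (nrow(edges)) {
    paste(edges$gene_a, rel, edges$gene_b)
  } else character(0)
  writeLines(sif_lines, sif_path)
  tsv_lines <- c(
    "gene_a\tgene_b\tdataset_id\trho",
    if (nrow(edges)) {
      paste(edges$gene_a, edges$gene_b, edges$dataset_id,
            sprintf("%.17g", edges$rho), sep = "\t")
    }
  )
  writeLines(tsv_lines, tsv_path)
  invisible(list(sif = sif_path, tsv = tsv_path))
}
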