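#' Build one miRNA-regulated protein interaction network
#'
#' The network has two gene layers: L0, the miRNA's consensus target
#' genes, and L1, every gene sharing a protein-protein interaction with an
#' L0 gene. Edges are the induced subgraph of the reference interaction
#' map on the network's nodes, so L1-L1 interactions are retained.
#' Isolated L0 genes are allowed: a network may consist of its L0 layer
#' only.
#'
#' @param mirna_id The regulating miRNA.
#' @param l0_genes Non-empty character vector of direct target genes.
#' @param ppi Canonical undirected edge `data.frame` (`gene_a`, `gene_b`),
#'   e.g. from [read_ppi_edges()].
#' @return A list of class `"pin"` with elements `mirna_id`, `nodes`
#'   (`data.frame` of `gene_id`, `layer`) and `edges`.
#' @examples
#' ppi <- data.frame(gene_a = c("g1", "g1", "g3"),
#'                   gene_b = c("g2", "g3", "g4"))
#' pin <- build_pin("mir-1", c("g1", "g2"), ppi)
#' pin$nodes  # g1, g2 in L0; g3 in L1; g4 excluded
#' @export
build_pin <- function(mirna_id, l0_genes, ppi) {
  l0_genes <- unique(as.character(l0_genes))
  if (!length(l0_genes)) stop("'l0_genes' must be non-empty")
  touches_a <- ppi$gene_a %in% l0_genes
  touches_b <- ppi$gene_b %in% l0_genes
  l1 <- setdiff(unique(c(ppi$gene_b[touches_a], ppi$gene_a[touches_b])),
                l0_genes)
  nodes <- data.frame(
    gene_id = c(sort(l0_genes), sort(l1)),
    layer = rep(c("L0", "L1"), c(length(l0_genes), length(l1))),
    stringsAsFactors = FALSE)
  keep <- ppi$gene_a %in% nodes$gene_id & ppi$gene_b %in% nodes$gene_id
  edges <- ppi[keep, c("gene_a", "gene_b"), drop = FALSE]
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(mirna_id = mirna_id, nodes = nodes, edges = edges),
            class = "pin")
}

#' @export
print.pin <- function(x, ...) {
  cat(sprintf("pin: %s regulates %d genes (%d L0 + %d L1), %d interactions\n",
              x$mirna_id, nrow(x$nodes), sum(x$nodes$layer == "L0"),
              sum(x$nodes$layer == "L1"), nrow(x$edges)))
  invisible(x)
}

#' Build the networks of every miRNA in a consensus pair table
#'
#' @param pairs Output of [consensus_pairs()].
#' @inheritParams build_pin
#' @return Named list of [build_pin()] objects, one per miRNA, ordered by
#'   miRNA id.
#' @export
build_pins <- function(pairs, ppi) {
  mirnas <- sort(unique(pairs$mirna_id))
  pins <- lapply(mirnas, function(m) {
    build_pin(m, pairs$gene_id[pairs$mirna_id == m], ppi)
  })
  names(pins) <- mirnas
  pins
}

#' Summarize network sizes
#'
#' @param pins List of [build_pin()] objects.
#' @return `data.frame` sorted by `mirna_id` with columns `mirna_id`,
#'   `total`, `l0_count`, `l1_count` (`total = l0_count + l1_count`).
#' @export
summarize_pins <- function(pins) {
  out <- data.frame(
    mirna_id = vapply(pins, function(p) p$mirna_id, character(1)),
    total = vapply(pins, function(p) nrow(p$nodes), integer(1)),
    l0_count = vapply(pins, function(p) sum(p$nodes$layer == "L0"),
                      integer(1)),
    l1_count = vapply(pins, function(p) sum(p$nodes$layer == "L1"),
                      integer(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
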