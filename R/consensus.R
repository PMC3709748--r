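#' Opposite-trend compatibility of a miRNA/gene pair
#'
#' A miRNA represses its targets, so an up-regulated miRNA is paired with a
#' down-regulated gene and vice versa. Only selected features (direction
#' `"up"` or `"down"`) may enter pairing.
#'
#' @param mirna_direction,gene_direction Character vectors in
#'   `c("up", "down")`; recycled to a common length.
#' @return Logical vector: `TRUE` iff the directions differ.
#' @export
direction_compatible <- function(mirna_direction, gene_direction) {
  ok <- c("up", "down")
  if (!all(mirna_direction %in% ok) || !all(gene_direction %in% ok))
    stop("directions must be 'up' or 'down' (not 'ns')")
  mirna_direction != gene_direction
}

#' Consensus miRNA-target pairs
#'
#' Pairs each differentially expressed miRNA with every oppositely
#' regulated differentially expressed gene that at least `min_support`
#' distinct target-prediction databases list as its target. Support counts
#' distinct source names, never record multiplicity, so a pair listed
#' twice within one database still has support 1.
#'
#' @param de_mirna,de_gene `data.frame`s with columns `feature_id` and
#'   `direction` (rows with direction `"ns"` are ignored).
#' @param targets Target records (`mirna_id`, `gene_id`, `source`), e.g.
#'   the row-bound output of [read_target_db()] over several databases.
#' @param min_support Minimum number of distinct supporting sources.
#' @return `data.frame` sorted by (`mirna_id`, `gene_id`) with columns
#'   `mirna_id`, `mirna_direction`, `gene_id`, `gene_direction`, `support`,
#'   `sources` (comma-joined, sorted).
#' @export
consensus_pairs <- function(de_mirna, de_gene, targets, min_support = 2) {
  if (min_support < 1) stop("'min_support' must be >= 1")
  empty <- data.frame(mirna_id = character(), mirna_direction = character(),
                      gene_id = character(), gene_direction = character(),
                      support = integer(), sources = character(),
                      stringsAsFactors = FALSE)
  mir <- de_mirna[de_mirna$direction %in% c("up", "down"), , drop = FALSE]
  gen <- de_gene[de_gene$direction %in% c("up", "down"), , drop = FALSE]
  if (!nrow(mir) || !nrow(gen) || !nrow(targets)) return(empty)

  rec <- unique(targets[, c("mirna_id", "gene_id", "source")])
  rec <- rec[rec$mirna_id %in% mir$feature_id &
               rec$gene_id %in% gen$feature_id, , drop = FALSE]
  if (!nrow(rec)) return(empty)
  rec$mirna_direction <- mir$direction[match(rec$mirna_id, mir$feature_id)]
  rec$gene_direction <- gen$direction[match(rec$gene_id, gen$feature_id)]
  rec <- rec[direction_compatible(rec$mirna_direction, rec$gene_direction), ,
             drop = FALSE]
  if (!nrow(rec)) return(empty)

  key <- paste(rec$mirna_id, rec$gene_id, sep = "\r")
  support <- tapply(rec$source, key, function(s) length(unique(s)))
  sources <- tapply(rec$source, key,
                    function(s) paste(sort(unique(s)), collapse = ","))
  first <- rec[!duplicated(key), , drop = FALSE]
  k <- paste(first$mirna_id, first$gene_id, sep = "\r")
  out <- data.frame(mirna_id = first$mirna_id,
                    mirna_direction = first$mirna_direction,
                    gene_id = first$gene_id,
                    gene_direction = first$gene_direction,
                    support = as.integer(support[k]),
                    sources = as.character(sources[k]),
                    stringsAsFactors = FALSE)
  out <- out[out$support >= min_support, , drop = FALSE]
  out <- out[order(out$mirna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
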