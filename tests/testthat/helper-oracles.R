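# Independent oracles and small fixture builders shared across the suite.
# Every oracle is deliberately naive (enumeration, brute force) and never
# calls the implementation it checks.

# upper-tail hypergeometric by exhaustive enumeration of all C(N, n) draws
enum_hypergeom_tail <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # items 1..K are the category
  mean(hits >= k)
}

# Benjamini-Yekutieli by the step-down/step-up hand formula
hand_by <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  ord <- order(p)
  adj <- m * cm * p[ord] / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# AUC by explicit pairwise comparison
pairwise_auc <- function(pos, neg) {
  s <- 0
  for (x in pos) for (y in neg) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(pos) * length(neg))
}

# consensus pairing by brute-force triple loop over (miRNA, gene, source)
brute_consensus <- function(de_mirna, de_gene, targets, min_support = 2) {
  mir <- de_mirna[de_mirna$direction %in% c("up", "down"), ]
  gen <- de_gene[de_gene$direction %in% c("up", "down"), ]
  out <- NULL
  for (i in seq_len(nrow(mir))) for (j in seq_len(nrow(gen))) {
    if (mir$direction[i] == gen$direction[j]) next
    srcs <- character()
    for (r in seq_len(nrow(targets))) {
      if (targets$mirna_id[r] == mir$feature_id[i] &&
          targets$gene_id[r] == gen$feature_id[j])
        srcs <- union(srcs, targets$source[r])
    }
    if (length(srcs) >= min_support)
      out <- rbind(out, data.frame(mirna_id = mir$feature_id[i],
                                   gene_id = gen$feature_id[j],
                                   support = length(srcs),
                                   stringsAsFactors = FALSE))
  }
  if (is.null(out)) return(out)
  out <- out[order(out$mirna_id, out$gene_id), ]
  rownames(out) <- NULL
  out
}

# PIN node set by depth-1 BFS with igraph
ego_pin_nodes <- function(l0, ppi) {
  if (!nrow(ppi)) return(sort(unique(l0)))
  g <- igraph::graph_from_data_frame(ppi, directed = FALSE,
                                     vertices = unique(c(l0, ppi$gene_a,
                                                         ppi$gene_b)))
  reach <- igraph::ego(g, order = 1, nodes = l0)
  sort(unique(c(l0, unlist(lapply(reach, names)))))
}

# two-feature expression set used by several IO and DE tests
toy_expression_set <- function() {
  values <- rbind(fA = c(2, 4, 8, 16, 12),
                  fB = c(10, 12, 5, 6, 7))
  colnames(values) <- paste0("s", 1:5)
  labels <- c(s1 = "normal", s2 = "normal", s3 = "tumor", s4 = "tumor",
              s5 = "tumor")
  expression_set(values, labels, "linear")
}

# diamond ontology: root <- a, root <- b, {a,b} <- c, a <- d
toy_ontology <- function() {
  ontology(
    data.frame(term_id = c("root", "a", "b", "c", "d"),
               name = c("root term", "branch a", "branch b",
                        "diamond child", "leaf d"),
               stringsAsFactors = FALSE),
    list(root = character(), a = "root", b = "root",
         c = c("a", "b"), d = "a"))
}

random_de_table <- function(ids, directions) {
  data.frame(feature_id = ids, direction = directions,
             stringsAsFactors = FALSE)
}
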