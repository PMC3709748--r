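#' GO term levels
#'
#' The level of a term is the number of `is_a` edges on the shortest path
#' to a root of the ontology (roots have level 0). Terms unreachable from
#' any root get `NA` with a warning.
#'
#' @param onto An [ontology()].
#' @return Named integer vector of levels, one per term.
#' @export
compute_term_levels <- function(onto) {
  stopifnot(inherits(onto, "ontology"))
  ids <- onto$terms$term_id
  edges <- ontology_edges(onto$parents)
  if (!nrow(edges)) {
    lev <- stats::setNames(rep(NA_integer_, length(ids)), ids)
    lev[onto$roots] <- 0L
    return(lev)
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("parent", "child")], directed = TRUE, vertices = ids)
  d <- igraph::distances(g, v = onto$roots, mode = "out")
  lev <- apply(d, 2, min)
  lev <- stats::setNames(as.integer(ifelse(is.finite(lev), lev, NA)),
                         colnames(d))[ids]
  names(lev) <- ids
  if (anyNA(lev))
    warning(sum(is.na(lev)), " terms unreachable from any root")
  lev
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability that a
#' size-`n` draw from an `N`-gene universe containing `K` category genes
#' includes at least `k` of them. This is the classic over-representation
#' p-value; the observed count is included in the tail, so `k = 0` gives 1.
#'
#' @param k Observed category genes in the draw.
#' @param K Category genes in the universe.
#' @param n Draw (network) size.
#' @param N Universe size.
#' @return The tail probability, in (0, 1]. All arguments recycle.
#' @examples
#' hypergeometric_upper_tail(3, 4, 5, 10)  # 66/252
#' @export
hypergeometric_upper_tail <- function(k, K, n, N) {
  bad <- k < 0 | n > N | K > N | k > n | k > K | n < 0 | K < 0
  if (any(bad))
    stop("invalid hypergeometric parameters: need 0 <= k <= min(K, n), ",
         "K <= N, n <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up adjustment valid under arbitrary dependence:
#' `adj_i = min(1, min over j with p_j >= p_i of m * c(m) * p_j / rank_j)`
#' with `c(m) = sum(1/i)`. Order-preserving; ties share a value; always at
#' least the raw p and at least the Benjamini-Hochberg adjustment.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' adjust_benjamini_yekutieli(c(0.01, 0.02, 0.03))  # all 0.055
#' @export
adjust_benjamini_yekutieli <- function(p) {
  if (!length(p)) return(numeric())
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BY")
}

#' Default cancer-keyword rule
#'
#' The lowercase substrings that flag a GO term as cancer-related in the
#' original study.
#'
#' @return Character vector of keywords.
#' @export
cancer_keywords <- function() {
  c("cell proliferation", "cell death", "apoptosis", "signaling",
    "microtubule", "actin")
}

#' Classify a GO term name as cancer-related
#'
#' @param term_name Character vector of term names.
#' @param keywords Lowercase substrings; a term matches if its lowercased
#'   name contains any of them.
#' @return Logical vector.
#' @export
classify_cancer_related <- function(term_name, keywords = cancer_keywords()) {
  if (!length(keywords) || any(!nzchar(keywords)))
    stop("'keywords' must be non-empty")
  if (any(keywords != tolower(keywords)))
    stop("'keywords' must be lowercase")
  lowered <- tolower(term_name)
  hit <- logical(length(term_name))
  for (kw in keywords) hit <- hit | grepl(kw, lowered, fixed = TRUE)
  hit
}

#' GO enrichment of one miRNA-regulated network
#'
#' Tests every annotated term at ontology level `min_level` or deeper
#' against the network's genes with the upper-tail hypergeometric test,
#' adjusts across all tested terms of this network with
#' Benjamini-Yekutieli and reports terms with adjusted p below `alpha`.
#' Networks smaller than `min_pin_size` genes are not tested at all (the
#' study discarded networks with five or fewer genes). The universe is the
#' set of all annotated genes; the network enters the test through its
#' annotated genes only.
#'
#' @param pin A [build_pin()] object.
#' @param annotations Named list mapping term ids to gene sets.
#' @param onto An [ontology()] supplying term names and levels.
#' @param min_pin_size Minimum network size (gene count) to test.
#' @param min_level Minimum term level kept (see [compute_term_levels()]).
#' @param alpha Threshold on the adjusted p-value.
#' @param keywords Cancer-keyword rule for [classify_cancer_related()].
#' @param term_levels Optional precomputed [compute_term_levels()] result,
#'   to avoid recomputation across networks.
#' @return `data.frame` with one row per significant term: `mirna_id`,
#'   `term_id`, `term_name`, `level`, `k`, `K`, `n`, `N`, `p`, `p_adj`,
#'   `cancer_related`, `member_genes` (comma-joined sorted intersection of
#'   network and term genes). Sorted by `p_adj`, then `term_id`.
#' @export
enrich_pin <- function(pin, annotations, onto, min_pin_size = 6,
                       min_level = 5, alpha = 1e-4,
                       keywords = cancer_keywords(),
                       term_levels = NULL) {
  stopifnot(inherits(pin, "pin"))
  empty <- empty_enrichment()
  if (nrow(pin$nodes) < min_pin_size) return(empty)
  universe <- annotation_universe(annotations)
  if (!length(universe)) stop("empty annotation universe")
  if (is.null(term_levels)) term_levels <- compute_term_levels(onto)

  tested <- names(annotations)[
    !is.na(term_levels[names(annotations)]) &
      term_levels[names(annotations)] >= min_level &
      lengths(annotations) >= 1]
  if (!length(tested)) return(empty)

  pin_genes <- intersect(pin$nodes$gene_id, universe)
  n <- length(pin_genes)
  N <- length(universe)
  members <- lapply(annotations[tested],
                    function(g) sort(intersect(pin_genes, g)))
  k <- lengths(members)
  K <- lengths(annotations[tested])
  p <- hypergeometric_upper_tail(k, K, n, N)
  p_adj <- adjust_benjamini_yekutieli(p)

  name <- onto$terms$name[match(tested, onto$terms$term_id)]
  out <- data.frame(
    mirna_id = pin$mirna_id, term_id = tested, term_name = name,
    level = as.integer(term_levels[tested]),
    k = as.integer(k), K = as.integer(K), n = n, N = N,
    p = p, p_adj = p_adj,
    cancer_related = classify_cancer_related(name, keywords),
    member_genes = vapply(members, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  out <- out[out$p_adj < alpha, , drop = FALSE]
  out <- out[order(out$p_adj, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname enrich_pin
#' @param pins List of [build_pin()] objects.
#' @export
enrich_pins <- function(pins, annotations, onto, min_pin_size = 6,
                        min_level = 5, alpha = 1e-4,
                        keywords = cancer_keywords()) {
  if (!length(pins)) return(empty_enrichment())
  term_levels <- compute_term_levels(onto)
  res <- lapply(pins, enrich_pin, annotations = annotations, onto = onto,
                min_pin_size = min_pin_size, min_level = min_level,
                alpha = alpha, keywords = keywords,
                term_levels = term_levels)
  out <- do.call(rbind, res)
  if (is.null(out)) out <- empty_enrichment()
  rownames(out) <- NULL
  out
}

empty_enrichment <- function() {
  data.frame(mirna_id = character(), term_id = character(),
             term_name = character(), level = integer(),
             k = integer(), K = integer(), n = integer(),
             N = integer(), p = numeric(), p_adj = numeric(),
             cancer_related = logical(), member_genes = character(),
             stringsAsFactors = FALSE)
}
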