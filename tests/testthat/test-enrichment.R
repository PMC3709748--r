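test_that("term levels are shortest is_a paths from the root", {
  lev <- compute_term_levels(toy_ontology())
  expect_identical(lev[["root"]], 0L)
  expect_identical(lev[["a"]], 1L)
  expect_identical(lev[["c"]], 2L)  # diamond: two paths, both length 2

  # a longer alternative path never raises a level
  deep <- ontology(
    data.frame(term_id = c("root", "a", "b", "c", "d"),
               name = letters[1:5], stringsAsFactors = FALSE),
    list(root = character(), a = "root", b = "root",
         d = "a", c = c("a", "b", "d")))
  expect_identical(compute_term_levels(deep)[["c"]], 2L)

  # unreachable terms are flagged, not silently levelled
  orphanish <- ontology(
    data.frame(term_id = c("root", "x", "y"), name = c("r", "x", "y"),
               stringsAsFactors = FALSE),
    list(root = character(), x = character(), y = "x"))
  expect_identical(sort(orphanish$roots), c("root", "x"))
})

test_that("hypergeometric upper tail agrees with exhaustive enumeration", {
  expect_equal(hypergeometric_upper_tail(3, 4, 5, 10), 66 / 252)
  expect_equal(hypergeometric_upper_tail(0, 4, 5, 10), 1)
  expect_equal(hypergeometric_upper_tail(5, 5, 5, 5), 1)
  for (N in c(5, 8, 12)) {
    for (K in 0:N) for (n in 0:N) for (k in max(0, n + K - N):min(K, n)) {
      expect_equal(hypergeometric_upper_tail(k, K, n, N),
                   enum_hypergeom_tail(k, K, n, N), tolerance = 1e-12)
    }
  }
  expect_error(hypergeometric_upper_tail(6, 4, 5, 10), "invalid")
  expect_error(hypergeometric_upper_tail(1, 4, 11, 10), "invalid")
})

test_that("BY adjustment matches the step-down hand formula", {
  expect_equal(adjust_benjamini_yekutieli(0.03), 0.03)
  expect_equal(adjust_benjamini_yekutieli(c(0.01, 0.02, 0.03)),
               c(0.055, 0.055, 0.055))
  for (seed in 1:5) {
    set.seed(seed)
    p <- runif(40)^2
    adj <- adjust_benjamini_yekutieli(p)
    expect_equal(adj, hand_by(p))
    expect_true(all(adj >= p))
    expect_true(all(adj >= p.adjust(p, "BH")))
    expect_identical(order(adj[order(p)]), seq_along(p))  # order-preserving
  }
  expect_error(adjust_benjamini_yekutieli(c(0.5, 1.2)), "0, 1")
})

test_that("cancer-keyword classifier matches the study's rule", {
  expect_true(classify_cancer_related(
    "Negative regulation of programmed cell death"))
  expect_true(classify_cancer_related("Microtubule cytoskeleton"))
  expect_false(classify_cancer_related("nucleotide binding"))
  expect_identical(
    classify_cancer_related(c("Induction of apoptosis", "ATP binding"),
                            c("apoptosis")),
    c(TRUE, FALSE))
  expect_error(classify_cancer_related("x", character()), "non-empty")
  expect_error(classify_cancer_related("x", "Apoptosis"), "lowercase")
})

test_that("keyword rule on the printed enrichment fixture yields 7 miRNAs", {
  s6 <- load_fixture("S6")
  flagged <- classify_cancer_related(s6$term_name)
  # every printed term containing a keyword is marked
  expect_true(all(flagged[grepl("apoptosis|cell death|signaling",
                                tolower(s6$term_name))]))
  survival <- unique(s6$mirna_name[classify_cancer_related(
    s6$term_name, c("apoptosis", "cell death", "cell proliferation"))])
  expect_identical(length(survival), 7L)
  expect_setequal(survival,
                  c("hsa-miR-520d-3p", "hsa-miR-497-5p", "hsa-miR-125b-5p",
                    "hsa-miR-21-5p", "hsa-miR-31-5p", "hsa-let-7c",
                    "hsa-miR-125a-5p"))
})

make_enrichment_world <- function(seed, n_universe = 300, pin_size = 20,
                                  overlap = 15, planted_K = 30) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_universe))
  pin_genes <- sample(genes, pin_size)
  onto <- simulate_ontology(genes, pin_genes, depth = 6, branching = 2,
                            planted_term_level = 5,
                            planted_overlap = overlap,
                            planted_term_size = planted_K, seed = seed)
  pin <- structure(list(
    mirna_id = "mir-test",
    nodes = data.frame(gene_id = pin_genes, layer = "L0",
                       stringsAsFactors = FALSE),
    edges = data.frame(gene_a = character(), gene_b = character(),
                       stringsAsFactors = FALSE)), class = "pin")
  list(onto = onto, pin = pin, pin_genes = pin_genes)
}

test_that("a planted overlapping term is the top enrichment hit", {
  top_hits <- 0
  for (seed in 1:10) {
    w <- make_enrichment_world(seed)
    res <- enrich_pin(w$pin, w$onto$annotations, w$onto$ontology)
    if (nrow(res) && res$term_id[1] == w$onto$truth$planted_term)
      top_hits <- top_hits + 1
    # member genes are exactly the PIN/term intersection
    planted_row <- res[res$term_id == w$onto$truth$planted_term, ]
    expect_identical(
      strsplit(planted_row$member_genes, ",")[[1]],
      sort(intersect(w$pin_genes,
                     w$onto$annotations[[w$onto$truth$planted_term]])))
    # only terms at the configured level or deeper are reported
    expect_true(all(res$level >= 5))
  }
  expect_gte(top_hits, 9)
})

test_that("networks at or below five genes are never tested", {
  w <- make_enrichment_world(1)
  small <- w$pin
  small$nodes <- small$nodes[1:5, ]
  expect_identical(nrow(enrich_pin(small, w$onto$annotations,
                                   w$onto$ontology)), 0L)
  expect_gt(nrow(enrich_pin(w$pin, w$onto$annotations, w$onto$ontology)), 0L)
})

test_that("enrichment under a uniform null controls the false-hit rate", {
  set.seed(2024)
  genes <- sprintf("g%03d", 1:300)
  w <- make_enrichment_world(99)
  lev <- compute_term_levels(w$onto$ontology)
  deep_terms <- names(lev)[!is.na(lev) & lev >= 5]
  n_pins <- 200
  false_hit <- logical(n_pins)
  # random annotations, random PINs: no term is truly enriched
  ann <- lapply(setNames(deep_terms, deep_terms),
                function(t) sample(genes, sample(10:40, 1)))
  for (i in seq_len(n_pins)) {
    pin <- structure(list(
      mirna_id = "null",
      nodes = data.frame(gene_id = sample(genes, 20), layer = "L0",
                         stringsAsFactors = FALSE),
      edges = data.frame(gene_a = character(), gene_b = character())),
      class = "pin")
    res <- enrich_pin(pin, ann, w$onto$ontology, alpha = 0.05,
                      term_levels = lev)
    false_hit[i] <- nrow(res) > 0
  }
  rate <- mean(false_hit)
  bound <- 0.05 + 3 * sqrt(0.05 * 0.95 / n_pins)
  expect_lte(rate, bound)
})
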