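test_that("expression simulation is seeded, scaled and truthful", {
  a <- simulate_expression(50, 4, 5, seed = 7)
  b <- simulate_expression(50, 4, 5, seed = 7)
  expect_identical(a$es$values, b$es$values)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_expression(50, 4, 5, seed = 8)
  expect_false(identical(a$es$values, c2$es$values))

  none <- simulate_expression(50, 4, 4, de_fraction = 0, seed = 1)
  expect_identical(none$truth$planted_up, character(0))
  expect_identical(none$truth$planted_down, character(0))
  d <- sam_d_statistics(log2(none$es$values + 1), none$es$labels, s0 = 0.1)
  expect_lt(max(abs(d$d)), 6)

  expect_error(simulate_expression(10, 1, 5), ">= 2")
  expect_error(simulate_expression(10, 3, 5, noise_sd = 0), "positive")
})

test_that("planted target databases drive consensus exactly", {
  mirs <- sprintf("m%02d", 1:10)
  genes <- sprintf("g%02d", 1:40)
  planted <- data.frame(mirna_id = c("m01", "m01", "m02"),
                        gene_id = c("g01", "g02", "g03"),
                        stringsAsFactors = FALSE)
  # directions chosen so every planted pair is opposite-trend:
  # m01 down / g01, g02 up; m02 up / g03 down
  de_mir <- random_de_table(mirs, rep(c("down", "up"), 5))
  de_gene <- random_de_table(genes, c("up", "up", "down",
                                      rep(c("up", "down"), 20)[-(1:3)]))

  rec <- simulate_target_databases(mirs, genes, planted,
                                   support_per_planted = 2,
                                   decoy_rate = 2, seed = 3)
  # planted pairs appear in exactly 2 sources; decoys in exactly 1
  key <- paste(rec$mirna_id, rec$gene_id)
  support <- tapply(rec$source, key, function(s) length(unique(s)))
  planted_key <- paste(planted$mirna_id, planted$gene_id)
  expect_true(all(support[planted_key] == 2))
  expect_true(all(support[setdiff(names(support), planted_key)] == 1))

  got <- consensus_pairs(de_mir, de_gene, rec)
  expect_setequal(paste(got$mirna_id, got$gene_id), planted_key)

  # support below the threshold: none of the planted pairs survive
  low <- simulate_target_databases(mirs, genes, planted,
                                   support_per_planted = 1,
                                   decoy_rate = 0, seed = 3)
  expect_identical(nrow(consensus_pairs(de_mir, de_gene, low)), 0L)
  expect_setequal(paste(low$mirna_id, low$gene_id), planted_key)

  expect_error(simulate_target_databases(mirs, genes,
                                         data.frame(mirna_id = "nope",
                                                    gene_id = "g01"),
                                         seed = 1),
               "unknown feature")
})

test_that("simulated PPI wires dedicated neighborhoods", {
  genes <- sprintf("g%03d", 1:100)
  targets <- c("g001", "g002")
  sim <- simulate_ppi(genes, targets, neighbors_per_target = 4,
                      background_edge_prob = 0, seed = 5)
  expect_identical(nrow(sim$edges), 8L)
  pin <- build_pin("m", "g001", sim$edges)
  expect_identical(nrow(pin$nodes), 5L)  # 1 target + 4 dedicated partners
  # canonical, self-loop-free
  expect_true(all(sim$edges$gene_a < sim$edges$gene_b))

  none <- simulate_ppi(genes, targets, neighbors_per_target = 0,
                       background_edge_prob = 0, seed = 5)
  expect_identical(nrow(none$edges), 0L)
  expect_identical(nrow(build_pin("m", "g001", none$edges)$nodes), 1L)
})

test_that("simulated ontology plants a term at the requested level", {
  genes <- sprintf("g%03d", 1:300)
  set.seed(1)
  pin_genes <- sample(genes, 20)
  sim <- simulate_ontology(genes, pin_genes, depth = 6,
                           planted_term_level = 5, seed = 11)
  lev <- compute_term_levels(sim$ontology)
  expect_identical(lev[[sim$truth$planted_term]], 5L)
  expect_identical(
    length(intersect(sim$annotations[[sim$truth$planted_term]], pin_genes)),
    15L)
  expect_error(simulate_ontology(genes, pin_genes, depth = 3,
                                 planted_term_level = 5, seed = 1),
               "exceed")
  expect_error(simulate_ontology(genes, pin_genes[1:5],
                                 planted_overlap = 15, seed = 1),
               "overlap")

  # serialized ontology parses back identically
  dir <- withr::local_tempdir()
  write_obo(sim$ontology, file.path(dir, "o.obo"))
  back <- read_obo(file.path(dir, "o.obo"))
  expect_identical(back$terms, sim$ontology$terms)
  expect_identical(back$parents, sim$ontology$parents)
})

test_that("a full simulated study is reproducible and reader-clean", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  s1 <- simulate_study(study_config(), seed = 13, out_dir = dir1)
  s2 <- simulate_study(study_config(), seed = 13, out_dir = dir2)
  for (nm in names(s1$paths))
    expect_identical(readLines(s1$paths[[nm]]), readLines(s2$paths[[nm]]),
                     info = nm)
  # generated files pass every reader without warnings
  expect_no_warning({
    read_expression_matrix(s1$paths[["mirna_expr"]],
                           s1$paths[["mirna_labels"]])
    read_expression_matrix(s1$paths[["gene_expr"]],
                           s1$paths[["gene_labels"]])
    read_ppi_edges(s1$paths[["ppi"]])
    read_ontology_and_annotations(s1$paths[["ontology"]],
                                  s1$paths[["annotations"]])
    for (db in grep("^db", names(s1$paths), value = TRUE))
      read_target_db(s1$paths[[db]], db)
  })
  s3 <- simulate_study(study_config(), seed = 14,
                       out_dir = withr::local_tempdir())
  expect_false(identical(readLines(s1$paths[["mirna_expr"]]),
                         readLines(s3$paths[["mirna_expr"]])))
})
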