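#' Simulate a two-group expression matrix with planted effects
#'
#' Log2-space values are `baseline + group shift + noise`: per-feature
#' baselines are Uniform(4, 10), planted features receive a tumor-group
#' shift of `+log2_effect` (up) or `-log2_effect` (down), split evenly
#' between directions, and noise is Gaussian with standard deviation
#' `noise_sd`. Values are exported on the linear scale (`2^x`), matching
#' array-like lognormal data. All randomness comes from a single stream
#' seeded by `seed`; the same seed reproduces the matrix exactly.
#'
#' @param n_features Number of features.
#' @param n_normal,n_tumor Group sizes (>= 2 each).
#' @param de_fraction Fraction of features planted as differential.
#' @param log2_effect Planted shift in log2 units (`1.33` corresponds
#'   roughly to the study's miRNA fold-change threshold of 2.5).
#' @param noise_sd Gaussian noise standard deviation in log2 units (> 0).
#' @param seed Integer seed.
#' @param prefix Feature-id prefix.
#' @return List with `es` (an [expression_set()], linear scale) and
#'   `truth` (`planted_up`, `planted_down` feature ids).
#' @export
simulate_expression <- function(n_features, n_normal, n_tumor,
                                de_fraction = 0.1, log2_effect = 3,
                                noise_sd = 0.5, seed = 1, prefix = "f") {
  if (n_normal < 2 || n_tumor < 2) stop("need >= 2 samples per group")
  if (de_fraction < 0 || de_fraction > 1)
    stop("'de_fraction' must lie in [0, 1]")
  if (noise_sd <= 0) stop("'noise_sd' must be positive")
  n <- n_normal + n_tumor
  feature_ids <- sprintf("%s%03d", prefix, seq_len(n_features))
  sample_ids <- c(sprintf("N%02d", seq_len(n_normal)),
                  sprintf("T%03d", seq_len(n_tumor)))
  labels <- stats::setNames(rep(c("normal", "tumor"), c(n_normal, n_tumor)),
                            sample_ids)
  n_de <- round(de_fraction * n_features)
  n_up <- floor(n_de / 2)
  withr::with_seed(seed, {
    planted <- sample(feature_ids, n_de)
    up <- planted[seq_len(n_up)]
    down <- setdiff(planted, up)
    baseline <- stats::runif(n_features, 4, 10)
    log2_vals <- matrix(baseline, n_features, n) +
      matrix(stats::rnorm(n_features * n, 0, noise_sd), n_features, n)
    shift <- numeric(n_features)
    shift[feature_ids %in% up] <- log2_effect
    shift[feature_ids %in% down] <- -log2_effect
    log2_vals[, labels == "tumor"] <-
      log2_vals[, labels == "tumor"] + shift
  })
  values <- 2^log2_vals
  dimnames(values) <- list(feature_ids, sample_ids)
  list(es = expression_set(values, labels, "linear"),
       truth = list(planted_up = sort(up), planted_down = sort(down)))
}

#' Simulate target-prediction databases with planted consensus
#'
#' Every planted pair is written into exactly `support_per_planted`
#' randomly chosen sources; decoy pairs (random miRNA-gene combinations
#' distinct from the planted ones) each appear in exactly one source, i.e.
#' below any consensus threshold of 2 or more.
#'
#' @param mirnas,genes Identifier universes.
#' @param planted_pairs `data.frame` with columns `mirna_id`, `gene_id`;
#'   all ids must come from the universes.
#' @param n_sources Number of databases (named `dbA`, `dbB`, ...).
#' @param support_per_planted Sources per planted pair
#'   (<= `n_sources`).
#' @param decoy_rate Decoy pairs per source, as a multiple of the planted
#'   pair count.
#' @param seed Integer seed.
#' @return `data.frame` of target records (`mirna_id`, `gene_id`,
#'   `source`).
#' @export
simulate_target_databases <- function(mirnas, genes, planted_pairs,
                                      n_sources = 3, support_per_planted = 2,
                                      decoy_rate = 1, seed = 1) {
  if (support_per_planted > n_sources)
    stop("'support_per_planted' cannot exceed 'n_sources'")
  if (nrow(planted_pairs)) {
    bad <- !(planted_pairs$mirna_id %in% mirnas) |
      !(planted_pairs$gene_id %in% genes)
    if (any(bad))
      stop("planted pair references unknown feature: ",
           paste(planted_pairs$mirna_id[bad], planted_pairs$gene_id[bad],
                 sep = "-", collapse = ", "))
  }
  sources <- paste0("db", LETTERS[seq_len(n_sources)])
  planted_key <- paste(planted_pairs$mirna_id, planted_pairs$gene_id)
  withr::with_seed(seed, {
    rec <- list()
    for (i in seq_len(nrow(planted_pairs))) {
      chosen <- sample(sources, support_per_planted)
      rec[[length(rec) + 1L]] <- data.frame(
        mirna_id = planted_pairs$mirna_id[i],
        gene_id = planted_pairs$gene_id[i],
        source = chosen, stringsAsFactors = FALSE)
    }
    n_decoys <- round(decoy_rate * max(nrow(planted_pairs), 1)) *
      n_sources
    if (n_decoys > 0) {
      pool_m <- sample(mirnas, n_decoys * 3, replace = TRUE)
      pool_g <- sample(genes, n_decoys * 3, replace = TRUE)
      key <- paste(pool_m, pool_g)
      keep <- !duplicated(key) & !(key %in% planted_key)
      idx <- which(keep)[seq_len(min(n_decoys, sum(keep)))]
      rec[[length(rec) + 1L]] <- data.frame(
        mirna_id = pool_m[idx], gene_id = pool_g[idx],
        source = sample(sources, length(idx), replace = TRUE),
        stringsAsFactors = FALSE)
    }
  })
  out <- unique(do.call(rbind, rec))
  rownames(out) <- NULL
  out
}

#' Simulate a protein-protein interaction map with a planted neighborhood
#'
#' Each planted target gene is wired to `neighbors_per_target` dedicated
#' partner genes (each partner attaches to exactly one target and receives
#' no other edges), so a network built from the planted targets has a
#' known size. The remaining genes form an Erdos-Renyi background with
#' edge probability `background_edge_prob`.
#'
#' @param genes Gene universe.
#' @param planted_targets Genes to wire (subset of `genes`).
#' @param neighbors_per_target Dedicated partners per target.
#' @param background_edge_prob Edge probability among the untouched genes.
#' @param seed Integer seed.
#' @return List with `edges` (canonical edge `data.frame`) and `truth`
#'   (named list target -> its dedicated partners).
#' @export
simulate_ppi <- function(genes, planted_targets, neighbors_per_target = 3,
                         background_edge_prob = 0.01, seed = 1) {
  if (background_edge_prob < 0 || background_edge_prob > 1)
    stop("'background_edge_prob' must lie in [0, 1]")
  stopifnot(all(planted_targets %in% genes))
  free <- setdiff(genes, planted_targets)
  need <- length(planted_targets) * neighbors_per_target
  if (length(free) < need)
    stop("not enough genes for dedicated neighbors")
  withr::with_seed(seed, {
    partners <- if (need) sample(free, need) else character()
    module <- stats::setNames(
      split(partners, rep(seq_along(planted_targets),
                          each = neighbors_per_target))[
                            seq_along(planted_targets)],
      planted_targets)
    module <- lapply(module, function(x) if (is.null(x)) character() else x)
    edges_a <- rep(planted_targets, each = neighbors_per_target)
    edges_b <- partners
    rest <- setdiff(free, partners)
    if (length(rest) >= 2 && background_edge_prob > 0) {
      cmb <- utils::combn(sort(rest), 2)
      pick <- stats::runif(ncol(cmb)) < background_edge_prob
      edges_a <- c(edges_a, cmb[1, pick])
      edges_b <- c(edges_b, cmb[2, pick])
    }
  })
  list(edges = canonical_ppi(edges_a, edges_b), truth = module)
}

#' Simulate a layered ontology with one planted enriched term
#'
#' Builds a rooted `is_a` tree of the given depth and branching factor,
#' plus optional extra edges that link a term to a second parent one level
#' above it (such edges can never shorten any term's level). One term at
#' `planted_term_level` is annotated with `planted_overlap` genes from
#' `pin_genes` plus random fill to `planted_term_size`; every other
#' non-root term receives a uniform random gene set.
#'
#' @param genes Gene universe to annotate from.
#' @param pin_genes Genes of the network the planted term must overlap.
#' @param depth Tree depth (root = level 0).
#' @param branching Children per internal node.
#' @param planted_term_level Level of the planted term (<= depth).
#' @param planted_overlap Planted genes shared with `pin_genes`.
#' @param planted_term_size Total annotation size of the planted term.
#' @param decoy_size_range Uniform range of decoy annotation sizes.
#' @param extra_edge_prob Probability of a second same-level-parent edge.
#' @param seed Integer seed.
#' @return List with `ontology`, `annotations` and `truth`
#'   (`planted_term`, `level`).
#' @export
simulate_ontology <- function(genes, pin_genes, depth = 6, branching = 2,
                              planted_term_level = 5, planted_overlap = 15,
                              planted_term_size = 30,
                              decoy_size_range = c(5, 40),
                              extra_edge_prob = 0.05, seed = 1) {
  if (planted_term_level > depth)
    stop("'planted_term_level' cannot exceed 'depth'")
  if (planted_overlap > length(pin_genes))
    stop("planted overlap exceeds network size")
  if (planted_overlap > planted_term_size)
    stop("planted overlap exceeds planted term size")
  ids <- "T000001"
  level <- c(T000001 = 0L)
  parents <- list(T000001 = character())
  nxt <- 2L
  frontier <- "T000001"
  for (lev in seq_len(depth)) {
    children <- character()
    for (node in frontier) {
      kid_ids <- sprintf("T%06d", seq(nxt, length.out = branching))
      nxt <- nxt + branching
      for (k in kid_ids) parents[[k]] <- node
      level[kid_ids] <- lev
      children <- c(children, kid_ids)
    }
    ids <- c(ids, children)
    frontier <- children
  }
  terms <- data.frame(term_id = ids,
                      name = paste("synthetic term", ids),
                      namespace = "synthetic_process",
                      stringsAsFactors = FALSE)
  withr::with_seed(seed, {
    # extra is_a edges from a same-level alternative parent: the new parent
    # sits one level above the child, so no shortest path changes
    for (id in ids[level[ids] >= 2]) {
      if (stats::runif(1) < extra_edge_prob) {
        cand <- setdiff(ids[level == level[id] - 1L], parents[[id]])
        if (length(cand))
          parents[[id]] <- c(parents[[id]], sample(cand, 1))
      }
    }
    planted_term <- sample(ids[level == planted_term_level], 1)
    ann <- list()
    for (id in ids[level[ids] >= 1]) {
      size <- sample(seq(decoy_size_range[1], decoy_size_range[2]), 1)
      ann[[id]] <- sort(sample(genes, min(size, length(genes))))
    }
    ann[[planted_term]] <- sort(c(
      sample(pin_genes, planted_overlap),
      sample(setdiff(genes, pin_genes),
             planted_term_size - planted_overlap)))
  })
  list(ontology = ontology(terms, parents),
       annotations = ann,
       truth = list(planted_term = planted_term,
                    level = as.integer(planted_term_level)))
}

#' Default configuration of the simulated study
#'
#' The defaults emulate a scaled-down version of the original design: 11
#' normal samples per profile (as in the study), a reduced tumor arm of
#' 20 samples, 60 miRNAs and 400 genes with 10% planted differential
#' features at a log2 effect of 3 and noise sd 0.5, three target
#' databases with 2-of-3 planted support, dedicated interaction
#' neighborhoods of 3 partners per target, and a depth-6 binary ontology
#' with the planted term at level 5 overlapping the first planted
#' network in 15 of its 20 genes.
#'
#' @param ... Overrides for individual fields.
#' @return Named list of generator settings.
#' @export
study_config <- function(...) {
  cfg <- list(
    n_mirnas = 60, n_genes = 400,
    n_normal = 11, n_tumor = 20,
    de_fraction = 0.1, log2_effect = 3, noise_sd = 0.5,
    n_planted_mirnas = 3, targets_per_mirna = 5,
    n_sources = 3, support_per_planted = 2, decoy_rate = 3,
    neighbors_per_target = 3, background_edge_prob = 0.02,
    depth = 6, branching = 2, planted_term_level = 5,
    planted_overlap = 15, planted_term_size = 30,
    mirna_fc_threshold = 2.5, gene_fc_threshold = 1.9,
    q_threshold = 1e-6, n_permutations = 1000,
    min_support = 2, min_pin_size = 6, min_level = 5, alpha = 1e-4)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop("unknown study_config fields: ", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  cfg
}

#' Simulate a full study and write every pipeline input
#'
#' One call produces the miRNA and gene expression profiles with labels,
#' the target-prediction databases, the interaction map, the ontology and
#' its annotations, and a plain-text truth manifest recording everything
#' planted. The planted design pairs each planted-down miRNA with planted-up
#' target genes (and the planted-up miRNAs with planted-down genes),
#' supports every pair in 2 of 3 databases, and wires the first planted
#' miRNA's targets into a dedicated interaction neighborhood that the
#' planted ontology term overlaps. Byte-reproducible for a fixed seed.
#'
#' @param config A [study_config()].
#' @param seed Integer master seed (sub-seeds for the individual
#'   generators are derived from it).
#' @param out_dir Directory for the generated files (created if needed).
#' @return Invisibly, a list with `paths` (named file paths), `truth` and
#'   `config`.
#' @export
simulate_study <- function(config = study_config(), seed = 1,
                           out_dir = tempfile("simstudy")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sub_seed <- function(k) as.integer((as.numeric(seed) * 7 + k) %% 2147483647)

  sim_mir <- simulate_expression(
    config$n_mirnas, config$n_normal, config$n_tumor,
    de_fraction = config$de_fraction, log2_effect = config$log2_effect,
    noise_sd = config$noise_sd, seed = sub_seed(1L), prefix = "mir")
  sim_gene <- simulate_expression(
    config$n_genes, config$n_normal, config$n_tumor,
    de_fraction = config$de_fraction, log2_effect = config$log2_effect,
    noise_sd = config$noise_sd, seed = sub_seed(2L), prefix = "gene")

  # planted consensus pairs: down miRNAs target up genes and vice versa
  down_mirs <- sim_mir$truth$planted_down
  up_mirs <- sim_mir$truth$planted_up
  up_genes <- sim_gene$truth$planted_up
  down_genes <- sim_gene$truth$planted_down
  tpm <- config$targets_per_mirna
  pairs <- list()
  gi <- 0L
  for (m in utils::head(down_mirs, config$n_planted_mirnas)) {
    take <- up_genes[gi + seq_len(tpm)]
    gi <- gi + tpm
    pairs[[length(pairs) + 1L]] <- data.frame(
      mirna_id = m, gene_id = take, stringsAsFactors = FALSE)
  }
  if (length(up_mirs) && tpm > 0) {
    pairs[[length(pairs) + 1L]] <- data.frame(
      mirna_id = up_mirs[1], gene_id = utils::head(down_genes, tpm),
      stringsAsFactors = FALSE)
  }
  planted_pairs <- do.call(rbind, pairs)
  if (is.null(planted_pairs))
    planted_pairs <- data.frame(mirna_id = character(),
                                gene_id = character(),
                                stringsAsFactors = FALSE)
  if (anyNA(planted_pairs$gene_id))
    stop("not enough planted genes for the requested pairs; ",
         "raise de_fraction or n_genes")

  all_genes <- rownames(sim_gene$es$values)
  targets <- simulate_target_databases(
    rownames(sim_mir$es$values), all_genes, planted_pairs,
    n_sources = config$n_sources,
    support_per_planted = config$support_per_planted,
    decoy_rate = config$decoy_rate, seed = sub_seed(3L))

  ppi <- simulate_ppi(all_genes, unique(planted_pairs$gene_id),
                      neighbors_per_target = config$neighbors_per_target,
                      background_edge_prob = config$background_edge_prob,
                      seed = sub_seed(4L))

  # network of the first planted miRNA: its targets plus their partners
  if (nrow(planted_pairs)) {
    focal_mirna <- planted_pairs$mirna_id[1]
    focal_targets <- planted_pairs$gene_id[planted_pairs$mirna_id ==
                                             focal_mirna]
    focal_pin_genes <- c(focal_targets,
                         unlist(ppi$truth[focal_targets],
                                use.names = FALSE))
    overlap <- config$planted_overlap
  } else {
    focal_mirna <- NA_character_
    focal_pin_genes <- character()
    overlap <- 0
  }
  onto <- simulate_ontology(
    all_genes, focal_pin_genes, depth = config$depth,
    branching = config$branching,
    planted_term_level = config$planted_term_level,
    planted_overlap = overlap,
    planted_term_size = config$planted_term_size, seed = sub_seed(5L))

  paths <- c(
    mirna_expr = file.path(out_dir, "mirna_expr.tsv"),
    mirna_labels = file.path(out_dir, "mirna_labels.tsv"),
    gene_expr = file.path(out_dir, "gene_expr.tsv"),
    gene_labels = file.path(out_dir, "gene_labels.tsv"),
    ppi = file.path(out_dir, "ppi.tsv"),
    ontology = file.path(out_dir, "ontology.obo"),
    annotations = file.path(out_dir, "annotations.gmt"),
    truth = file.path(out_dir, "truth.json"))
  write_expression_matrix(sim_mir$es, paths["mirna_expr"],
                          paths["mirna_labels"])
  write_expression_matrix(sim_gene$es, paths["gene_expr"],
                          paths["gene_labels"])
  src_names <- sort(unique(targets$source))
  target_paths <- stats::setNames(
    file.path(out_dir, paste0("targets_", src_names, ".tsv")), src_names)
  for (s in src_names)
    write_target_db(targets[targets$source == s, , drop = FALSE],
                    target_paths[[s]])
  write_ppi_edges(ppi$edges, paths["ppi"])
  write_obo(onto$ontology, paths["ontology"])
  write_gmt(onto$annotations, paths["annotations"])

  truth <- list(
    schema = "mirpin-truth/1",
    seed = seed,
    planted_up_mirnas = sim_mir$truth$planted_up,
    planted_down_mirnas = sim_mir$truth$planted_down,
    planted_up_genes = sim_gene$truth$planted_up,
    planted_down_genes = sim_gene$truth$planted_down,
    planted_pairs = planted_pairs,
    focal_mirna = focal_mirna,
    focal_pin_genes = sort(focal_pin_genes),
    planted_term = onto$truth$planted_term,
    planted_term_level = onto$truth$level)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(paths = c(paths, target_paths), truth = truth,
                 config = config))
}
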