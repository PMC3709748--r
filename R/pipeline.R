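#' Validate a pipeline configuration
#'
#' A configuration is a flat named list (or a YAML file holding one) with
#' input paths and stage thresholds. Required fields: `mirna_expr`,
#' `mirna_labels`, `gene_expr`, `gene_labels`, `target_dbs` (named list or
#' vector of source -> path), `ppi`, `ontology`, `annotations`, `out_dir`.
#' Optional: `roc_expr`/`roc_labels` (an independent profile for marker
#' evaluation; the network-construction matrix is deliberately not
#' reused), thresholds (`q_threshold`, `mirna_fc_threshold`,
#' `gene_fc_threshold`, `min_support`, `min_pin_size`, `min_level`,
#' `alpha`, `se_mode`), `n_permutations` and `seed`.
#'
#' @param config Named list or path to a YAML file.
#' @return The completed configuration with defaults filled in.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("'config' must be a list or a YAML path")
  defaults <- list(q_threshold = 1e-6, mirna_fc_threshold = 2.5,
                   gene_fc_threshold = 1.9, min_support = 2,
                   min_pin_size = 6, min_level = 5, alpha = 1e-4,
                   se_mode = "observed", n_permutations = 1000, seed = 1,
                   s0_strategy = "median_s")
  missing_f <- setdiff(names(defaults), names(config))
  config[missing_f] <- defaults[missing_f]
  required <- c("mirna_expr", "mirna_labels", "gene_expr", "gene_labels",
                "target_dbs", "ppi", "ontology", "annotations", "out_dir")
  absent <- setdiff(required, names(config))
  if (length(absent))
    stop("missing configuration fields: ", paste(absent, collapse = ", "))
  if (config$q_threshold < 0 || config$q_threshold > 1)
    stop("q_threshold must lie in [0, 1]")
  if (config$mirna_fc_threshold < 1 || config$gene_fc_threshold < 1)
    stop("fold-change thresholds must be >= 1")
  if (config$min_support < 1) stop("min_support must be >= 1")
  if (config$min_pin_size < 1) stop("min_pin_size must be >= 1")
  if (config$alpha <= 0 || config$alpha > 1)
    stop("alpha must lie in (0, 1]")
  if (!config$se_mode %in% c("observed", "null"))
    stop("se_mode must be 'observed' or 'null'")
  if (is.null(names(config$target_dbs)))
    names(config$target_dbs) <-
      paste0("db", LETTERS[seq_along(config$target_dbs)])
  paths <- c(config$mirna_expr, config$mirna_labels, config$gene_expr,
             config$gene_labels, unlist(config$target_dbs), config$ppi,
             config$ontology, config$annotations,
             config$roc_expr, config$roc_labels)
  gone <- paths[!file.exists(paths)]
  if (length(gone))
    stop("configured input files do not exist: ",
         paste(gone, collapse = ", "))
  config
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full discovery pipeline
#'
#' Executes, in order: differential expression of miRNAs and genes,
#' opposite-trend consensus pairing, per-miRNA network construction,
#' level-filtered GO enrichment, and (when an independent profile is
#' configured) ROC marker evaluation. Stage outputs are written to
#' `out_dir` via [write_outputs()] together with a machine-readable run
#' manifest (`run_manifest.json`) echoing every threshold, the seed, the
#' package version and a hash of the configuration; re-running with the
#' same configuration and seed reproduces identical outputs.
#'
#' @param config See [pipeline_config()].
#' @return Invisibly, a list with elements `de_mirna`, `de_gene`, `pairs`,
#'   `pins`, `pin_summary`, `enrichment`, `roc` (`NULL` when not
#'   configured) and `manifest`.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  t0 <- Sys.time()

  stage <- "de-mirna"
  mir_es <- read_expression_matrix(config$mirna_expr, config$mirna_labels)
  cfg_mir <- sam_config(s0_strategy = config$s0_strategy,
                        n_permutations = config$n_permutations,
                        q_threshold = config$q_threshold,
                        fc_threshold = config$mirna_fc_threshold,
                        seed = config$seed)
  de_mirna <- tryCatch(sam_analysis(mir_es, cfg_mir),
                       error = function(e)
                         stop("stage ", stage, " failed on ",
                              config$mirna_expr, ": ", conditionMessage(e)))
  stage_log(stage, "%d features, %d selected (%d up, %d down)",
            nrow(de_mirna), sum(de_mirna$direction != "ns"),
            sum(de_mirna$direction == "up"),
            sum(de_mirna$direction == "down"))

  stage <- "de-gene"
  gene_es <- read_expression_matrix(config$gene_expr, config$gene_labels)
  cfg_gene <- sam_config(s0_strategy = config$s0_strategy,
                         n_permutations = config$n_permutations,
                         q_threshold = config$q_threshold,
                         fc_threshold = config$gene_fc_threshold,
                         seed = config$seed)
  de_gene <- tryCatch(sam_analysis(gene_es, cfg_gene),
                      error = function(e)
                        stop("stage ", stage, " failed on ",
                             config$gene_expr, ": ", conditionMessage(e)))
  stage_log(stage, "%d features, %d selected (%d up, %d down)",
            nrow(de_gene), sum(de_gene$direction != "ns"),
            sum(de_gene$direction == "up"),
            sum(de_gene$direction == "down"))

  stage <- "consensus"
  targets <- do.call(rbind, lapply(names(config$target_dbs), function(s) {
    read_target_db(config$target_dbs[[s]], s)
  }))
  pairs <- consensus_pairs(de_mirna, de_gene, targets,
                           min_support = config$min_support)
  stage_log(stage, "%d target records -> %d consensus pairs (%d miRNAs)",
            nrow(targets), nrow(pairs), length(unique(pairs$mirna_id)))

  stage <- "network"
  ppi <- read_ppi_edges(config$ppi)
  pins <- build_pins(pairs, ppi)
  pin_summary <- summarize_pins(pins)
  stage_log(stage, "%d PPI edges -> %d networks", nrow(ppi), length(pins))

  stage <- "enrichment"
  oa <- read_ontology_and_annotations(config$ontology, config$annotations)
  enrichment <- enrich_pins(pins, oa$annotations, oa$ontology,
                            min_pin_size = config$min_pin_size,
                            min_level = config$min_level,
                            alpha = config$alpha)
  stage_log(stage, "%d significant term hits across %d networks",
            nrow(enrichment), length(unique(enrichment$mirna_id)))

  roc <- NULL
  if (!is.null(config$roc_expr)) {
    stage <- "roc"
    roc_es <- read_expression_matrix(config$roc_expr, config$roc_labels)
    feats <- intersect(unique(pairs$mirna_id), rownames(roc_es$values))
    roc <- if (length(feats))
      roc_markers(roc_es, feats, se_mode = config$se_mode)
    stage_log(stage, "%d markers evaluated", length(feats))
  }

  results <- list(de_mirna = de_mirna, de_gene = de_gene, pairs = pairs,
                  pin_summary = pin_summary, enrichment = enrichment,
                  roc = roc, pins = pins)
  files <- write_outputs(results, config$out_dir)

  cfg_json <- jsonlite::toJSON(config[order(names(config))],
                               auto_unbox = TRUE, digits = NA)
  hash_file <- tempfile()
  writeLines(as.character(cfg_json), hash_file)
  manifest <- list(
    package = "mirpin",
    version = as.character(utils::packageVersion("mirpin")),
    r_version = R.version.string,
    seed = config$seed,
    config = config,
    config_hash = unname(tools::md5sum(hash_file)),
    counts = list(
      mirna_features = nrow(de_mirna),
      mirna_selected_pre_fc = sum(!is.na(de_mirna$q) &
                                    de_mirna$q <= config$q_threshold),
      mirna_selected = sum(de_mirna$direction != "ns"),
      gene_features = nrow(de_gene),
      gene_selected_pre_fc = sum(!is.na(de_gene$q) &
                                   de_gene$q <= config$q_threshold),
      gene_selected = sum(de_gene$direction != "ns"),
      consensus_pairs = nrow(pairs),
      networks = length(pins),
      enriched_terms = nrow(enrichment)),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = files)
  unlink(hash_file)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(results, list(manifest = manifest)))
}

#' Recompute the study's count-based claims from the packaged fixtures
#'
#' From the fixtures alone: the down/up split of the miRNA table, the
#' down- and up-regulated gene counts, the number of constructed networks
#' and their size consistency (`total = L0 + L1`), and the number of
#' distinct miRNAs whose networks carry an enriched term matching the
#' apoptosis / cell death / cell proliferation keywords.
#'
#' @return `data.frame` with columns `quantity`, `computed`, `printed`,
#'   `match`.
#' @export
reproduce_paper_counts <- function() {
  s1 <- load_fixture("S1")
  s2 <- load_fixture("S2")
  s3 <- load_fixture("S3")
  s4 <- load_fixture("S4")
  s5 <- load_fixture("S5")
  s6 <- load_fixture("S6")
  survival_kw <- c("apoptosis", "cell death", "cell proliferation")
  kw_mirnas <- unique(s6$mirna_name[
    classify_cancer_related(s6$term_name, survival_kw)])
  computed <- c(
    down_mirnas = sum(s1$fold_change < 1),
    up_mirnas = sum(s1$fold_change > 1),
    down_genes = nrow(s2),
    up_genes = nrow(s3),
    roc_mirnas = nrow(s4),
    networks = nrow(s5),
    networks_size_consistent = sum(s5$total == s5$l0_count + s5$l1_count),
    keyword_mirnas = length(kw_mirnas))
  printed <- c(down_mirnas = 89, up_mirnas = 1, down_genes = 726,
               up_genes = 437, roc_mirnas = 18, networks = 18,
               networks_size_consistent = 18, keyword_mirnas = 7)
  data.frame(quantity = names(computed),
             computed = unname(computed),
             printed = unname(printed[names(computed)]),
             match = unname(computed == printed[names(computed)]),
             stringsAsFactors = FALSE)
}
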