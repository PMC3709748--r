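#' Construct a two-group expression set
#'
#' Bundles a features-by-samples numeric matrix with normal/tumor sample
#' labels and a scale hint. All pipeline stages consume this container.
#'
#' @param values Numeric matrix; rownames are feature identifiers, colnames
#'   sample identifiers. `NA` marks missing measurements; all other values
#'   must be finite.
#' @param labels Named character vector mapping sample ids to `"normal"` or
#'   `"tumor"`. Every name must be a column of `values`.
#' @param scale_hint Either `"linear"` (normalized abundance) or `"log2"`.
#' @return A list of class `"expression_set"` with elements `values`,
#'   `labels` (aligned to the columns they label) and `scale_hint`.
#' @export
expression_set <- function(values, labels, scale_hint = c("linear", "log2")) {
  scale_hint <- match.arg(scale_hint)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature identifiers in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers in expression matrix")
  if (any(is.infinite(values)))
    stop("expression values must be finite or NA")
  if (is.null(names(labels)) || anyDuplicated(names(labels)))
    stop("'labels' must be uniquely named by sample id")
  if (!all(labels %in% c("normal", "tumor")))
    stop("labels must be 'normal' or 'tumor'")
  missing_samples <- setdiff(names(labels), colnames(values))
  if (length(missing_samples))
    stop("labeled samples absent from matrix: ",
         paste(missing_samples, collapse = ", "))
  structure(
    list(values = values, labels = labels, scale_hint = scale_hint),
    class = "expression_set"
  )
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("expression_set: %d features x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale_hint))
  cat(sprintf("  groups: %d normal, %d tumor; %d unlabeled\n",
              sum(x$labels == "normal"), sum(x$labels == "tumor"),
              ncol(x$values) - length(x$labels)))
  invisible(x)
}

read_tsv_raw <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = "NA")
}

#' Read an expression matrix and its group labels
#'
#' The matrix is a TSV whose header row holds sample ids and whose first
#' column holds feature ids; `NA` encodes missing values and lines starting
#' with `#` are comments. The label file is a two-column TSV
#' (`sample_id`, `group`) with `group` in normal/tumor.
#'
#' @param path Path to the expression TSV.
#' @param labels_path Path to the label TSV.
#' @param scale_hint Scale of the stored values, `"linear"` or `"log2"`.
#' @param drop_unlabeled Drop matrix columns without a label instead of
#'   raising an error.
#' @return An [expression_set()].
#' @export
read_expression_matrix <- function(path, labels_path,
                                   scale_hint = c("linear", "log2"),
                                   drop_unlabeled = FALSE) {
  scale_hint <- match.arg(scale_hint)
  header <- utils::head(grep("^[^#]", readLines(path, warn = FALSE),
                             value = TRUE), 1)
  if (anyDuplicated(strsplit(header, "\t", fixed = TRUE)[[1]][-1]))
    stop("duplicate sample id in header of ", path)
  tab <- read_tsv_raw(path)
  if (ncol(tab) < 2)
    stop("expression file needs a feature-id column and >=1 sample: ", path)
  feature_ids <- as.character(tab[[1]])
  if (anyDuplicated(feature_ids))
    stop("duplicate feature id in ", path, ": ",
         feature_ids[duplicated(feature_ids)][1])
  numeric_col <- vapply(tab[, -1, drop = FALSE],
                        function(x) is.numeric(x) || all(is.na(x)),
                        logical(1))
  if (!all(numeric_col))
    stop("non-numeric expression values in ", path,
         " (samples: ", paste(names(numeric_col)[!numeric_col],
                              collapse = ", "), ")")
  values <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- feature_ids

  lab <- read_tsv_raw(labels_path)
  if (ncol(lab) < 2)
    stop("label file needs columns sample_id and group: ", labels_path)
  labels <- as.character(lab[[2]])
  names(labels) <- as.character(lab[[1]])
  if (!all(labels %in% c("normal", "tumor")))
    stop("unknown group label in ", labels_path, ": ",
         paste(setdiff(labels, c("normal", "tumor")), collapse = ", "))
  unlabeled <- setdiff(colnames(values), names(labels))
  if (length(unlabeled)) {
    if (!drop_unlabeled)
      stop("unlabeled samples in ", path, ": ",
           paste(unlabeled, collapse = ", "),
           " (set drop_unlabeled = TRUE to discard them)")
    values <- values[, setdiff(colnames(values), unlabeled), drop = FALSE]
  }
  expression_set(values, labels, scale_hint)
}

#' Write an expression set to TSV files
#'
#' Inverse of [read_expression_matrix()]; round-trips byte-identically for
#' matrices whose values print exactly (ids sorted as stored).
#'
#' @param es An [expression_set()].
#' @param path,labels_path Output paths for the matrix and label TSVs.
#' @return Invisibly, `c(path, labels_path)`.
#' @export
write_expression_matrix <- function(es, path, labels_path) {
  stopifnot(inherits(es, "expression_set"))
  tab <- data.frame(feature_id = rownames(es$values), es$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  lab <- data.frame(sample_id = names(es$labels), group = unname(es$labels),
                    stringsAsFactors = FALSE)
  utils::write.table(lab, labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, labels_path))
}

#' Read one miRNA target-prediction database
#'
#' Accepts a two-column TSV (`mirna_id`, `gene_id`), tags every record with
#' the database name and collapses duplicates.
#'
#' @param path Path to the TSV.
#' @param source_name Non-empty database name attached to every record.
#' @return `data.frame` with columns `mirna_id`, `gene_id`, `source`.
#' @export
read_target_db <- function(path, source_name) {
  if (!is.character(source_name) || length(source_name) != 1 ||
      !nzchar(source_name))
    stop("'source_name' must be a non-empty string")
  tab <- read_tsv_raw(path)
  if (nrow(tab) == 0)
    return(data.frame(mirna_id = character(), gene_id = character(),
                      source = character(), stringsAsFactors = FALSE))
  if (ncol(tab) < 2)
    stop("target file needs columns mirna_id and gene_id: ", path)
  rec <- data.frame(mirna_id = as.character(tab[[1]]),
                    gene_id = as.character(tab[[2]]),
                    source = source_name, stringsAsFactors = FALSE)
  if (any(is.na(rec$mirna_id) | !nzchar(rec$mirna_id)) ||
      any(is.na(rec$gene_id) | !nzchar(rec$gene_id)))
    stop("empty miRNA or gene identifier in ", path)
  unique(rec)
}

#' @rdname read_target_db
#' @param records Target records (`mirna_id`, `gene_id`; extra columns are
#'   dropped).
#' @export
write_target_db <- function(records, path) {
  utils::write.table(records[, c("mirna_id", "gene_id")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

canonical_ppi <- function(gene_a, gene_b) {
  keep <- gene_a != gene_b
  gene_a <- gene_a[keep]
  gene_b <- gene_b[keep]
  swap <- gene_a > gene_b
  tmp <- gene_a[swap]
  gene_a[swap] <- gene_b[swap]
  gene_b[swap] <- tmp
  edges <- unique(data.frame(gene_a = gene_a, gene_b = gene_b,
                             stringsAsFactors = FALSE))
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Read protein-protein interaction edges
#'
#' Accepts a headered two-column TSV or a SIF file
#' (`node <TAB> relation <TAB> node`). Edges are undirected: self-loops are
#' dropped and each unordered pair is stored once, lexicographically
#' ordered within the row and sorted.
#'
#' @param path Path to the edge file.
#' @return `data.frame` with columns `gene_a`, `gene_b`.
#' @export
read_ppi_edges <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  sif <- all(nf == 3)
  if (!sif && !all(nf == 2)) {
    bad <- which(!(nf %in% c(2L, 3L)) | nf != nf[1])[1]
    stop("malformed PPI row at line ", bad, " of ", path, ": ", lines[bad])
  }
  first <- vapply(fields, `[[`, character(1), 1L)
  last <- vapply(fields, function(f) f[[length(f)]], character(1))
  if (identical(tolower(first[1]), "gene_a") ||
      identical(tolower(first[1]), "node_a")) {
    first <- first[-1]
    last <- last[-1]
  }
  if (any(!nzchar(first)) || any(!nzchar(last)))
    stop("empty node name in ", path)
  canonical_ppi(first, last)
}

#' @rdname read_ppi_edges
#' @param edges Canonical edge `data.frame` (`gene_a`, `gene_b`).
#' @export
write_ppi_edges <- function(edges, path) {
  utils::write.table(edges[, c("gene_a", "gene_b")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an ontology DAG
#'
#' @param terms `data.frame` with columns `term_id`, `name` and optionally
#'   `namespace`.
#' @param parents Named list mapping each `term_id` to a character vector of
#'   parent `term_id`s (empty for roots), following `is_a` relations only.
#' @return List of class `"ontology"` with `terms`, `parents` and the
#'   derived `roots`.
#' @export
ontology <- function(terms, parents) {
  stopifnot(is.data.frame(terms), all(c("term_id", "name") %in% names(terms)))
  if (anyDuplicated(terms$term_id))
    stop("duplicate term_id in ontology")
  if (is.null(terms$namespace)) terms$namespace <- NA_character_
  parents <- parents[terms$term_id]
  names(parents) <- terms$term_id
  parents <- lapply(parents, function(p) if (is.null(p)) character() else p)
  unresolved <- setdiff(unlist(parents), terms$term_id)
  if (length(unresolved))
    stop("parent references unresolved terms: ",
         paste(unresolved, collapse = ", "))
  edges <- ontology_edges(parents)
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = terms$term_id)
    if (!igraph::is_dag(g))
      stop("ontology contains a cycle")
  }
  roots <- terms$term_id[lengths(parents) == 0]
  if (!length(roots))
    stop("ontology has no root term")
  structure(list(terms = terms, parents = parents, roots = roots),
            class = "ontology")
}

# child -> parent edge list as a data.frame
ontology_edges <- function(parents) {
  child <- rep(names(parents), lengths(parents))
  data.frame(child = child, parent = unlist(parents, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Read an OBO-subset ontology file
#'
#' Honors only `[Term]` stanzas with `id:`, `name:`, `namespace:` and
#' `is_a:` lines; every other tag (including `part_of` relationships) is
#' ignored. Obsolete terms are skipped.
#'
#' @param path Path to the OBO file.
#' @return An [ontology()].
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  breaks <- c(which(grepl("^\\[", lines)), length(lines) + 1L)
  ids <- character()
  nms <- character()
  nss <- character()
  parents <- list()
  for (i in seq_len(length(breaks) - 1L)) {
    if (lines[breaks[i]] != "[Term]") next
    stanza <- lines[(breaks[i] + 1L):(breaks[i + 1L] - 1L)]
    tag <- sub(":.*", "", stanza)
    val <- trimws(sub("^[a-z_]+:", "", stanza))
    if (any(tag == "is_obsolete" & val == "true")) next
    id <- val[tag == "id"][1]
    if (is.na(id)) stop("[Term] stanza without id in ", path)
    ids <- c(ids, id)
    nms <- c(nms, if (any(tag == "name")) val[tag == "name"][1] else id)
    nss <- c(nss, if (any(tag == "namespace")) val[tag == "namespace"][1]
             else NA_character_)
    isa <- val[tag == "is_a"]
    parents[[id]] <- trimws(sub("!.*", "", isa))
  }
  ontology(data.frame(term_id = ids, name = nms, namespace = nss,
                      stringsAsFactors = FALSE), parents)
}

#' @rdname read_obo
#' @param onto An [ontology()] to serialize.
#' @export
write_obo <- function(onto, path) {
  stopifnot(inherits(onto, "ontology"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(onto$terms))) {
    writeLines(c("", "[Term]",
                 paste0("id: ", onto$terms$term_id[i]),
                 paste0("name: ", onto$terms$name[i])), con)
    if (!is.na(onto$terms$namespace[i]))
      writeLines(paste0("namespace: ", onto$terms$namespace[i]), con)
    for (p in onto$parents[[onto$terms$term_id[i]]])
      writeLines(paste0("is_a: ", p), con)
  }
  invisible(path)
}

#' Read term and edge TSVs as an ontology
#'
#' Alternative to OBO input: a term table (`term_id`, `name`, optional
#' `namespace`) plus a child-to-parent edge table.
#'
#' @param terms_path,edges_path Paths to the two TSVs.
#' @return An [ontology()].
#' @export
read_term_edges <- function(terms_path, edges_path) {
  terms <- read_tsv_raw(terms_path)
  edges <- read_tsv_raw(edges_path)
  parents <- split(as.character(edges[[2]]), as.character(edges[[1]]))
  ontology(data.frame(term_id = as.character(terms$term_id),
                      name = as.character(terms$name),
                      namespace = if ("namespace" %in% names(terms))
                        as.character(terms$namespace) else NA_character_,
                      stringsAsFactors = FALSE),
           parents)
}

#' Read or write gene-set annotations in GMT format
#'
#' Each GMT row is `term_id <TAB> description <TAB> gene...`. Reading is
#' delegated to [fgsea::gmtPathways()].
#'
#' @param path Path to the GMT file.
#' @return A named list mapping `term_id` to a character vector of genes.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lapply(sets, unique)
}

#' @rdname read_gmt
#' @param annotations Named list of gene sets.
#' @export
write_gmt <- function(annotations, path) {
  rows <- vapply(names(annotations), function(id) {
    paste(c(id, id, annotations[[id]]), collapse = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Read an ontology together with its annotations
#'
#' @param onto_path OBO file (see [read_obo()]).
#' @param gmt_path GMT annotation file.
#' @param lenient Downgrade "annotation references unknown term" from an
#'   error to a warning, dropping the offending sets.
#' @return List with elements `ontology` and `annotations`.
#' @export
read_ontology_and_annotations <- function(onto_path, gmt_path,
                                          lenient = FALSE) {
  onto <- read_obo(onto_path)
  ann <- read_gmt(gmt_path)
  unknown <- setdiff(names(ann), onto$terms$term_id)
  if (length(unknown)) {
    msg <- paste("annotations reference unknown terms:",
                 paste(unknown, collapse = ", "))
    if (!lenient) stop(msg)
    warning(msg)
    ann <- ann[setdiff(names(ann), unknown)]
  }
  list(ontology = onto, annotations = ann)
}

#' Annotation universe
#'
#' @param annotations Named list of gene sets.
#' @return Sorted character vector of all annotated genes.
#' @export
annotation_universe <- function(annotations) {
  sort(unique(unlist(annotations, use.names = FALSE)))
}

#' Write pipeline stage results to deterministic files
#'
#' Every table is written as a TSV with fixed column order and rows sorted
#' by primary key; every PIN is additionally written as a SIF file with
#' `targets` edges from the miRNA to its L0 genes and `pp` edges for
#' protein interactions. Writing the same results twice yields
#' byte-identical files.
#'
#' @param results Named list; recognised elements are data.frames
#'   (`de_mirna`, `de_gene`, `pairs`, `pin_summary`, `enrichment`, `roc`)
#'   and `pins`, a list of [build_pin()] objects.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written paths (the manifest).
#' @export
write_outputs <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  manifest <- character()
  keys <- list(de_mirna = "feature_id", de_gene = "feature_id",
               pairs = c("mirna_id", "gene_id"),
               pin_summary = "mirna_id",
               enrichment = c("mirna_id", "p_adj", "term_id"),
               roc = "feature_id")
  for (nm in names(keys)) {
    if (is.null(results[[nm]])) next
    tab <- results[[nm]]
    ord <- do.call(order, unname(as.list(tab[, keys[[nm]], drop = FALSE])))
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tab[ord, , drop = FALSE], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest <- c(manifest, path)
  }
  for (pin in results$pins) {
    path <- file.path(out_dir, paste0(gsub("[^A-Za-z0-9._-]", "_",
                                           pin$mirna_id), ".sif"))
    write_pin_sif(pin, path)
    manifest <- c(manifest, path)
  }
  manifest
}

#' @rdname write_outputs
#' @param pin A [build_pin()] object.
#' @param path Output SIF path.
#' @export
write_pin_sif <- function(pin, path) {
  stopifnot(inherits(pin, "pin"))
  l0 <- sort(pin$nodes$gene_id[pin$nodes$layer == "L0"])
  rows <- paste(pin$mirna_id, "targets", l0, sep = "\t")
  if (nrow(pin$edges)) {
    e <- pin$edges[order(pin$edges$gene_a, pin$edges$gene_b), , drop = FALSE]
    rows <- c(rows, paste(e$gene_a, "pp", e$gene_b, sep = "\t"))
  }
  writeLines(rows, path)
  invisible(path)
}
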