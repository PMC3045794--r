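#' Default interaction-record exclusion patterns
#'
#' Case-insensitive substrings matched against the detection-method and
#' interaction-type fields. Mass-spectrometry detection methods are
#' excluded because they do not discriminate direct from indirect physical
#' association; genetic/functional interaction types are excluded because
#' they are not physical contacts.
#' @return A list with `methods` and `types` character vectors.
#' @export
default_exclusions <- function() {
  list(methods = c("mass spectrometry", "ms/ms", "tandem ms",
                   "MI:0069", "MI:0427", "MI:0943"),
       types = c("genetic interaction", "synthetic lethal",
                 "colocalization", "association by phenotype",
                 "MI:0208", "MI:0794", "MI:0403"))
}

#' Network filter configuration
#'
#' @param excluded_method_patterns,excluded_type_patterns Character vectors
#'   of case-insensitive substrings; a record matching any pattern in its
#'   detection-method / interaction-type field is removed.
#' @param id_map Optional data.frame (`raw_id`, `gene_id`) mapping raw
#'   interactor identifiers to gene ids; a raw id may map to several genes
#'   (every mapped combination becomes an edge candidate). `NULL` means
#'   identifiers are already gene ids.
#' @return A list with class `network_filter_config`.
#' @export
network_filter_config <- function(
    excluded_method_patterns = default_exclusions()$methods,
    excluded_type_patterns = default_exclusions()$types,
    id_map = NULL) {
  if (!is.null(id_map))
    stopifnot(all(c("raw_id", "gene_id") %in% names(id_map)))
  structure(list(excluded_method_patterns = excluded_method_patterns,
                 excluded_type_patterns = excluded_type_patterns,
                 id_map = id_map),
            class = "network_filter_config")
}

#' Read interaction records
#'
#' Two dialects: `edge_tsv` is a headerless TSV with columns
#' `id_a, id_b, method, type, db` (trailing columns optional, blanks kept
#' as empty strings); `mitab_min` reads columns 1, 2, 7, 12 and 13 of a
#' MITAB 2.5 file (interactor A/B, detection method, interaction type,
#' source database). Short lines are skipped with a diagnostic.
#'
#' @param path Input path.
#' @param dialect `"edge_tsv"` or `"mitab_min"`.
#' @return A data.frame with columns `id_a, id_b, detection_method,
#'   interaction_type, source_db`.
#' @export
read_interactions <- function(path, dialect = c("edge_tsv", "mitab_min")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  need <- if (dialect == "edge_tsv") 2L else 13L
  short <- lengths(parts) < need
  if (any(short))
    warning(sum(short), " short line(s) skipped in ", path)
  parts <- parts[!short]
  grab <- function(p, i) if (length(p) >= i) p[[i]] else ""
  if (dialect == "edge_tsv") {
    data.frame(
      id_a = vapply(parts, grab, "", 1L),
      id_b = vapply(parts, grab, "", 2L),
      detection_method = vapply(parts, grab, "", 3L),
      interaction_type = vapply(parts, grab, "", 4L),
      source_db = vapply(parts, grab, "", 5L),
      stringsAsFactors = FALSE)
  } else {
    strip <- function(x) sub("^[^:]*:", "", x)  # drop db prefixes like uniprotkb:
    data.frame(
      id_a = strip(vapply(parts, grab, "", 1L)),
      id_b = strip(vapply(parts, grab, "", 2L)),
      detection_method = vapply(parts, grab, "", 7L),
      interaction_type = vapply(parts, grab, "", 12L),
      source_db = vapply(parts, grab, "", 13L),
      stringsAsFactors = FALSE)
  }
}

matches_any <- function(x, patterns) {
  if (!length(patterns)) return(rep(FALSE, length(x)))
  hit <- rep(FALSE, length(x))
  xl <- tolower(x)
  for (p in patterns) hit <- hit | grepl(tolower(p), xl, fixed = TRUE)
  hit
}

#' Build a gene-level PPI network from interaction records
#'
#' Records matching an excluded detection-method or interaction-type
#' pattern are removed; raw identifiers are mapped to gene ids (unmapped
#' identifiers are dropped, with a count diagnostic); all proteins of a
#' gene collapse into one vertex. Pairs with both endpoints on the same
#' gene become self-interaction flags rather than edges; distinct-gene
#' pairs are deduplicated into unordered edges. Vertex degree counts
#' distinct partners (self-interactions excluded). Vertices with no edge
#' and no self-interaction record are discarded; a vertex kept only by a
#' self-interaction record is retained with degree 0.
#'
#' @param records Records data.frame from [read_interactions()].
#' @param filter_config A [network_filter_config()].
#' @param protein_lengths Optional named vector of protein lengths attached
#'   to vertices.
#' @return An object of class `ppi_network`: a list with `vertices`
#'   (data.frame `gene_id, degree, protein_length, self_interacting,
#'   category`) and `edges` (data.frame `gene_a, gene_b`, unordered,
#'   deduplicated).
#' @export
build_network <- function(records, filter_config = network_filter_config(),
                          protein_lengths = NULL) {
  stopifnot(inherits(filter_config, "network_filter_config"))
  drop <- matches_any(records$detection_method,
                      filter_config$excluded_method_patterns) |
    matches_any(records$interaction_type,
                filter_config$excluded_type_patterns)
  rec <- records[!drop, , drop = FALSE]
  map <- filter_config$id_map
  if (!is.null(map)) {
    expand <- function(ids) split(map$gene_id, map$raw_id)[ids]
    ga <- expand(rec$id_a); gb <- expand(rec$id_b)
    n_unmapped <- sum(vapply(ga, is.null, TRUE) | vapply(gb, is.null, TRUE))
    if (n_unmapped)
      message(n_unmapped, " record(s) dropped: unmapped identifier")
    pairs <- do.call(rbind, lapply(seq_len(nrow(rec)), function(i) {
      if (is.null(ga[[i]]) || is.null(gb[[i]])) return(NULL)
      expand.grid(a = ga[[i]], b = gb[[i]], stringsAsFactors = FALSE)
    }))
  } else {
    pairs <- data.frame(a = rec$id_a, b = rec$id_b, stringsAsFactors = FALSE)
  }
  if (is.null(pairs)) pairs <- data.frame(a = character(0), b = character(0))
  self_set <- unique(pairs$a[pairs$a == pairs$b])
  pp <- pairs[pairs$a != pairs$b, , drop = FALSE]
  lo <- pmin(pp$a, pp$b); hi <- pmax(pp$a, pp$b)
  edges <- unique(data.frame(gene_a = lo, gene_b = hi,
                             stringsAsFactors = FALSE))
  rownames(edges) <- NULL
  new_ppi_network(edges, self_set, protein_lengths)
}

new_ppi_network <- function(edges, self_set, protein_lengths = NULL,
                            category = NULL) {
  ids <- sort(unique(c(edges$gene_a, edges$gene_b, self_set)))
  deg <- stats::setNames(numeric(length(ids)), ids)
  if (nrow(edges)) {
    t1 <- table(c(edges$gene_a, edges$gene_b))
    deg[names(t1)] <- as.numeric(t1)
  }
  plen <- if (is.null(protein_lengths)) rep(NA_real_, length(ids)) else
    unname(protein_lengths[ids])
  cat_v <- if (is.null(category)) rep(NA_character_, length(ids)) else
    unname(as.character(category[ids]))
  vertices <- data.frame(gene_id = ids, degree = unname(deg),
                         protein_length = as.numeric(plen),
                         self_interacting = ids %in% self_set,
                         category = cat_v, stringsAsFactors = FALSE)
  structure(list(vertices = vertices, edges = edges), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf(
    "<ppi_network> %d vertices, %d edges, %d self-interacting, mean degree %.2f\n",
    nrow(x$vertices), nrow(x$edges), sum(x$vertices$self_interacting),
    if (nrow(x$vertices)) mean(x$vertices$degree) else 0))
  invisible(x)
}

#' Attach shuffling categories to network vertices
#' @param network A `ppi_network`.
#' @param calls Calls data.frame from [classify_genes()].
#' @return The network with the `category` vertex column filled where known.
#' @export
annotate_network <- function(network, calls) {
  idx <- match(network$vertices$gene_id, calls$gene_id)
  network$vertices$category <- as.character(calls$category)[idx]
  network
}

#' Project a PPI network into another species by orthology
#'
#' A target-species gene pair is connected if and only if both genes have
#' orthologs in the source species and those orthologs are connected in
#' the source network. Self-interactions are inherited the same way.
#' Rows of the ortholog table participating in many-to-many relationships
#' are rejected with a diagnostic; target genes without an ortholog are
#' simply absent from the projection.
#'
#' @param source_network A `ppi_network`.
#' @param ortholog_table Data.frame with columns `target_gene`,
#'   `source_gene` (one-to-one pairs).
#' @param protein_lengths Optional named lengths for target genes.
#' @return A `ppi_network` over target-species genes.
#' @export
project_by_orthology <- function(source_network, ortholog_table,
                                 protein_lengths = NULL) {
  ot <- ortholog_table
  stopifnot(all(c("target_gene", "source_gene") %in% names(ot)))
  dup <- duplicated(ot$target_gene) | duplicated(ot$target_gene, fromLast = TRUE) |
    duplicated(ot$source_gene) | duplicated(ot$source_gene, fromLast = TRUE)
  if (any(dup)) {
    warning(sum(dup), " many-to-many ortholog row(s) rejected")
    ot <- ot[!dup, , drop = FALSE]
  }
  back <- stats::setNames(ot$target_gene, ot$source_gene)
  e <- source_network$edges
  keep <- e$gene_a %in% names(back) & e$gene_b %in% names(back)
  ta <- unname(back[e$gene_a[keep]]); tb <- unname(back[e$gene_b[keep]])
  edges <- unique(data.frame(gene_a = pmin(ta, tb), gene_b = pmax(ta, tb),
                             stringsAsFactors = FALSE))
  rownames(edges) <- NULL
  src_self <- source_network$vertices$gene_id[
    source_network$vertices$self_interacting]
  self_set <- unname(back[intersect(src_self, names(back))])
  new_ppi_network(edges, self_set, protein_lengths)
}

#' Contingency table of network presence for two gene categories
#'
#' Cross-tabulates genes of two shuffling categories by membership in the
#' PPI network: rows are the categories, columns are (in network, not in
#' network).
#'
#' @param calls Calls data.frame covering the full protein-coding gene set.
#' @param network A `ppi_network`.
#' @param category_pair Character vector of two categories, e.g.
#'   `c("ES", "SS")`.
#' @return A 2x2 integer matrix.
#' @export
presence_contingency <- function(calls, network, category_pair) {
  stopifnot(length(category_pair) == 2L)
  in_net <- calls$gene_id %in% network$vertices$gene_id
  m <- t(vapply(category_pair, function(cc) {
    sel <- as.character(calls$category) == cc
    c(in_network = sum(sel & in_net), not_in_network = sum(sel & !in_net))
  }, c(in_network = 0, not_in_network = 0)))
  storage.mode(m) <- "integer"
  m
}

#' Write a network's vertex and edge tables
#' @param network A `ppi_network`.
#' @param vertices_path,edges_path Output paths.
#' @export
write_network <- function(network, vertices_path, edges_path) {
  utils::write.table(network$vertices, vertices_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(network$edges, edges_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(vertices_path, edges_path))
}
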