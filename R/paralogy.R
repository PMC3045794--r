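#' Detect paralog families from all-vs-all alignments
#'
#' Two genes are paralogous when the summed query-side span of
#' non-overlapping high-scoring pairs between them reaches at least
#' `min_fraction` (default 0.7) of the length of the *longer* protein.
#' Non-overlapping HSPs are chosen greedily in decreasing bitscore order
#' on the query coordinates; either orientation of a pair may qualify it.
#' Paralogy is transitive, so families are the connected components of the
#' paralog-pair graph; every gene in `protein_lengths` is assigned to a
#' family (singletons included).
#'
#' @param hits Hits data.frame (see [read_blast_tab()]).
#' @param protein_lengths Named integer vector over the full gene set.
#' @param min_fraction Added-HSP coverage threshold (default 0.7).
#' @return A `paralog_families` object: list with `membership` (named
#'   integer vector gene -> family id) and `sizes` (family id -> size).
#' @export
detect_paralogs <- function(hits, protein_lengths, min_fraction = 0.7) {
  missing <- setdiff(unique(c(hits$query_id, hits$subject_id)),
                     names(protein_lengths))
  if (length(missing))
    stop("protein_lengths missing gene(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  pair_edges <- list()
  if (nrow(hits)) {
    key <- paste(hits$query_id, hits$subject_id, sep = "\r")
    for (k in unique(key)) {
      h <- hits[key == k, , drop = FALSE]
      q <- h$query_id[1L]; s <- h$subject_id[1L]
      added <- added_hsp_span(h$q_start, h$q_end, h$bitscore)
      if (added >= min_fraction * max(protein_lengths[q], protein_lengths[s]))
        pair_edges[[length(pair_edges) + 1L]] <- c(q, s)
    }
  }
  families_from_pairs(pair_edges, names(protein_lengths))
}

# greedy non-overlap selection by decreasing bitscore; returns summed span
added_hsp_span <- function(q_start, q_end, bitscore) {
  ord <- order(-bitscore, q_start)
  taken_s <- integer(0); taken_e <- integer(0); total <- 0L
  for (i in ord) {
    if (!length(taken_s) ||
        all(q_end[i] < taken_s | q_start[i] > taken_e)) {
      taken_s <- c(taken_s, q_start[i]); taken_e <- c(taken_e, q_end[i])
      total <- total + (q_end[i] - q_start[i] + 1L)
    }
  }
  total
}

families_from_pairs <- function(pair_edges, all_genes) {
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(all_genes)
  if (length(pair_edges)) {
    em <- do.call(rbind, pair_edges)
    g <- igraph::add_edges(g, t(em))
  }
  comp <- igraph::components(g)
  membership <- comp$membership
  structure(list(membership = membership,
                 sizes = as.integer(comp$csize)),
            class = "paralog_families")
}

#' Read paralog pairs from a TSV list
#'
#' Curated paralog lists (one `gene_a <TAB> gene_b` pair per line), when
#' available, take precedence over alignment-based detection. Transitivity
#' is applied the same way.
#'
#' @param path Path to the pair list.
#' @param all_genes Character vector of the full gene set (singletons are
#'   included in the partition).
#' @return A `paralog_families` object.
#' @export
read_paralog_list <- function(path, all_genes) {
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character")
  all_genes <- union(all_genes, unique(c(tab[[1L]], tab[[2L]])))
  families_from_pairs(
    lapply(seq_len(nrow(tab)), function(i) c(tab[i, 1L], tab[i, 2L])),
    all_genes)
}

#' @export
print.paralog_families <- function(x, ...) {
  cat(sprintf("<paralog_families> %d genes in %d families (largest %d)\n",
              length(x$membership), length(x$sizes),
              if (length(x$sizes)) max(x$sizes) else 0L))
  invisible(x)
}

#' Family size of each gene
#' @param families A `paralog_families` object.
#' @param genes Gene ids (default: all genes in the partition).
#' @return Named integer vector of family sizes k (including the gene).
#' @export
family_size <- function(families, genes = names(families$membership)) {
  unknown <- setdiff(genes, names(families$membership))
  if (length(unknown))
    stop("gene(s) not in the paralog partition: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  stats::setNames(families$sizes[families$membership[genes]], genes)
}

#' 1/k paralog weight of a gene
#'
#' A gene in a paralog family of size `k` contributes `1/k` of a count,
#' damping duplication-driven inflation; weights in each family sum to 1.
#'
#' @inheritParams family_size
#' @return Named numeric vector of weights.
#' @export
family_weight <- function(families, genes = names(families$membership))
  1 / family_size(families, genes)

#' Paralog confluence of a PPI network
#'
#' Within each paralog family, network vertices sharing the same shuffling
#' category are replaced by a single vertex whose degree and protein
#' length are the arithmetic means of the members' (fractional degrees
#' allowed) and whose self-interaction flag is the disjunction of the
#' members'. Vertices of distinct categories are never merged. Edges are
#' left untouched: the merged vertex is a statistical unit carrying
#' degree/length/flags for the downstream comparisons.
#'
#' @param network A `ppi_network` (category-annotated or not).
#' @param families A `paralog_families` covering the network's vertices.
#' @param calls Optional calls data.frame supplying categories for
#'   vertices whose `category` column is unset.
#' @return A `ppi_network` whose `vertices` table holds the merged units;
#'   `edges` are unchanged.
#' @export
confluence <- function(network, families, calls = NULL) {
  v <- network$vertices
  if (!is.null(calls)) {
    idx <- match(v$gene_id, calls$gene_id)
    fill <- is.na(v$category) & !is.na(idx)
    v$category[fill] <- as.character(calls$category)[idx[fill]]
  }
  if (anyNA(v$category))
    stop("vertex without a shuffling call: ",
         paste(utils::head(v$gene_id[is.na(v$category)], 5L), collapse = ", "))
  fam <- families$membership[v$gene_id]
  if (anyNA(fam))
    stop("vertex missing from the paralog partition")
  grp <- paste(fam, v$category, sep = "\r")
  merged <- do.call(rbind, lapply(split(seq_len(nrow(v)), grp), function(ix) {
    data.frame(
      gene_id = if (length(ix) == 1L) v$gene_id[ix] else
        paste0(v$gene_id[ix][1L], "+", length(ix) - 1L, "paralogs"),
      degree = mean(v$degree[ix]),
      protein_length = mean(v$protein_length[ix]),
      self_interacting = any(v$self_interacting[ix]),
      category = v$category[ix][1L],
      n_members = length(ix),
      stringsAsFactors = FALSE)
  }))
  rownames(merged) <- NULL
  structure(list(vertices = merged, edges = network$edges),
            class = "ppi_network")
}

#' Write the paralog partition as TSV
#' @param families A `paralog_families`.
#' @param path Output path.
#' @export
write_families <- function(families, path) {
  utils::write.table(
    data.frame(gene_id = names(families$membership),
               family_id = unname(families$membership)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
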