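#' Flanking windows of an aligned region's borders
#'
#' Each homologous region has two borders on each of the two genes. A
#' border at CDS nucleotide position is surrounded by a window over intron
#' *junction offsets* extending 20 nucleotides toward the region exterior
#' and 3 nucleotides toward the region interior. With the aligned residue
#' span projected to nucleotides `[n5, n3]` (see [residue_span_to_nt()]):
#' the 5' border junction is `n5 - 1` and its window is
#' `[n5 - 1 - exterior, n5 - 1 + interior]`; the 3' border junction is `n3`
#' and its window is `[n3 - interior, n3 + exterior]`. Windows are clipped
#' to `[0, cds_length]` rather than discarded when they overrun a sequence
#' end (bilateral flanking is not required).
#'
#' @param region One-row regions data.frame (see
#'   [find_homologous_regions()]).
#' @param gene_a_model,gene_b_model `gene_model`s for the two genes.
#' @param exterior,interior Window extents in nucleotides (defaults 20, 3).
#' @return A data.frame with four rows (2 genes x 2 borders) and columns
#'   `gene_id, side, lo, hi`.
#' @export
border_windows <- function(region, gene_a_model, gene_b_model,
                           exterior = 20L, interior = 3L) {
  one_gene <- function(model, start_res, end_res) {
    if (end_res > nchar(model$protein_seq) || start_res < 1L)
      stop("region coordinates outside protein ", model$gene_id)
    nt <- residue_span_to_nt(start_res, end_res)
    n5 <- nt[1L, "nt_start"]; n3 <- nt[1L, "nt_end"]
    clip <- function(x) pmin(pmax(x, 0L), model$cds_length)
    data.frame(
      gene_id = model$gene_id,
      side = c("five_prime", "three_prime"),
      lo = clip(c(n5 - 1L - exterior, n3 - interior)),
      hi = clip(c(n5 - 1L + interior, n3 + exterior)),
      stringsAsFactors = FALSE)
  }
  rbind(one_gene(gene_a_model, region$a_start, region$a_end),
        one_gene(gene_b_model, region$b_start, region$b_end))
}

#' Count flanking windows that contain at least one intron
#'
#' @param windows Window data.frame from [border_windows()].
#' @param models Named list of `gene_model`s covering the windows' genes.
#' @return Integer in 0..4.
#' @export
count_intron_windows <- function(windows, models) {
  sum(vapply(seq_len(nrow(windows)), function(i) {
    j <- models[[windows$gene_id[i]]]$intron_junctions
    any(j >= windows$lo[i] & j <= windows$hi[i])
  }, logical(1)))
}

#' Classify genes into exon-shuffling categories
#'
#' Genes with at least one qualifying homologous region whose four border
#' windows contain introns in at least `species_config$min_intron_windows`
#' windows are exon-shuffling (ES) genes; the call applies to both genes
#' of the region regardless of which gene carries the flanking introns.
#' Genes with regions but never enough intron-bearing windows are
#' sequence-shuffling (SS); genes with no region at all are
#' without-shuffling (WS). Every gene in `models` receives exactly one
#' call.
#'
#' @param regions Regions data.frame from [find_homologous_regions()].
#' @param models Named list of `gene_model`s (the full gene set).
#' @param config A [species_config()].
#' @param exterior,interior Window extents passed to [border_windows()].
#' @return A data.frame with columns `gene_id, category, best_window_count,
#'   n_regions`; `category` is a factor with levels ES, SS, WS.
#' @export
classify_genes <- function(regions, models, config = species_config(),
                           exterior = 20L, interior = 3L) {
  ids <- names(models)
  unknown <- setdiff(unique(c(regions$gene_a, regions$gene_b)), ids)
  if (length(unknown))
    stop("region references unknown gene(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  best <- stats::setNames(integer(length(ids)), ids)
  nreg <- stats::setNames(integer(length(ids)), ids)
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    w <- border_windows(r, models[[r$gene_a]], models[[r$gene_b]],
                        exterior = exterior, interior = interior)
    cnt <- count_intron_windows(w, models)
    for (g in c(r$gene_a, r$gene_b)) {
      best[g] <- max(best[g], cnt)
      nreg[g] <- nreg[g] + 1L
    }
  }
  category <- ifelse(nreg == 0L, "WS",
                     ifelse(best >= config$min_intron_windows, "ES", "SS"))
  data.frame(gene_id = ids,
             category = factor(category, levels = c("ES", "SS", "WS")),
             best_window_count = unname(best),
             n_regions = unname(nreg),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write shuffling calls as TSV
#' @param calls Calls data.frame from [classify_genes()].
#' @param path Output path.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
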