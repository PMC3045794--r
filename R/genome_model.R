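#' Gene model constructor
#'
#' A `gene_model` holds one gene's maximal-length protein product, its CDS
#' length (stop codon excluded, so always 3x the protein length) and the
#' positions of introns along the CDS. Intron positions are stored as
#' *junction offsets*: offset `j` means an intron interrupts the coding
#' sequence between CDS nucleotide `j` and `j + 1` (1-based nucleotides),
#' so valid offsets are strictly between 0 and `cds_length`.
#'
#' @param gene_id Character scalar identifier.
#' @param protein_seq Amino-acid sequence as a character scalar.
#' @param intron_junctions Integer vector of junction offsets (may be empty).
#' @param species Optional species tag used to select thresholds downstream.
#' @return An object of class `gene_model`.
#' @examples
#' g <- gene_model("g1", strrep("M", 100), c(150L, 299L))
#' g$cds_length  # 300
#' @export
gene_model <- function(gene_id, protein_seq, intron_junctions = integer(0),
                       species = NA_character_) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id),
            is.character(protein_seq), length(protein_seq) == 1L,
            nchar(protein_seq) >= 1L)
  cds_length <- 3L * nchar(protein_seq)
  j <- as.integer(sort(unique(intron_junctions)))
  if (length(j) && (any(j <= 0L) || any(j >= cds_length)))
    stop("gene ", gene_id, ": intron junction offsets must lie strictly ",
         "between 0 and cds_length (", cds_length, ")")
  structure(
    list(gene_id = gene_id, protein_seq = protein_seq,
         cds_length = cds_length, intron_junctions = j, species = species),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s: %d aa, cds %d nt, %d intron junction(s)\n",
              x$gene_id, nchar(x$protein_seq), x$cds_length,
              length(x$intron_junctions)))
  invisible(x)
}

#' Species-level classification thresholds
#'
#' Intron-rich lineages (human, mouse) require at least three of the four
#' alignment-flanking windows to contain introns before a homologous region
#' counts as exon-shuffling evidence; lineages with more extensive intron
#' loss (fly, worm, fungus, plant) require only two.
#'
#' @param species Species label; recognised labels pick the conventional
#'   threshold, anything else defaults to `min_intron_windows`.
#' @param min_intron_windows Integer, 2 or 3; overrides the label lookup.
#' @return A list with elements `species` and `min_intron_windows`.
#' @export
species_config <- function(species = "human", min_intron_windows = NULL) {
  three <- c("human", "homo_sapiens", "mouse", "mus_musculus")
  if (is.null(min_intron_windows))
    min_intron_windows <- if (tolower(species) %in% three) 3L else 2L
  min_intron_windows <- as.integer(min_intron_windows)
  stopifnot(min_intron_windows %in% c(2L, 3L))
  list(species = species, min_intron_windows = min_intron_windows)
}

#' Project a protein residue span onto CDS nucleotide coordinates
#'
#' Residue `r` occupies CDS nucleotides `3r - 2 .. 3r` (1-based, inclusive,
#' stop codon excluded), so a span of residues maps to the nucleotide
#' interval `(3*start_res - 2, 3*end_res)`.
#'
#' @param start_res,end_res 1-based inclusive residue coordinates,
#'   `start_res <= end_res`. Vectorised.
#' @return A two-column integer matrix with columns `nt_start`, `nt_end`.
#' @examples
#' residue_span_to_nt(1, 1)     # 1 3
#' residue_span_to_nt(100, 120) # 298 360
#' @export
residue_span_to_nt <- function(start_res, end_res) {
  start_res <- as.integer(start_res); end_res <- as.integer(end_res)
  if (any(start_res < 1L) || any(end_res < 1L))
    stop("residue coordinates must be positive")
  if (any(start_res > end_res))
    stop("start_res must not exceed end_res")
  cbind(nt_start = 3L * start_res - 2L, nt_end = 3L * end_res)
}

#' Read gene models from protein FASTA plus an intron table
#'
#' The intron table is a headerless three-column TSV:
#' `gene_id <TAB> cds_length <TAB> j1,j2,...` with the third field optionally
#' empty. Genes present in the FASTA but absent from the table are treated
#' as intron-less. Records whose stated `cds_length` disagrees with 3x the
#' protein length, or whose junctions fall outside the CDS interior, are
#' rejected with a per-record diagnostic (a warning naming the gene).
#'
#' @param fasta_path Path to a protein FASTA whose record names are gene ids.
#' @param intron_tsv_path Path to the intron table TSV, or `NULL` for an
#'   all-intron-less gene set.
#' @param species Species tag stored on every model.
#' @return A named list of `gene_model` objects, keyed by gene id.
#' @export
read_genes <- function(fasta_path, intron_tsv_path = NULL, species = NA_character_) {
  aa <- Biostrings::readAAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(aa))
  seqs <- unname(as.character(aa))
  jmap <- list(); lmap <- list()
  if (!is.null(intron_tsv_path)) {
    tab <- utils::read.delim(intron_tsv_path, header = FALSE,
                             colClasses = "character", blank.lines.skip = TRUE)
    if (ncol(tab) < 2L) stop("intron table needs >= 2 columns")
    if (ncol(tab) == 2L) tab$V3 <- ""
    for (i in seq_len(nrow(tab))) {
      gid <- tab[i, 1L]
      jmap[[gid]] <- if (nzchar(trimws(tab[i, 3L])))
        as.integer(strsplit(trimws(tab[i, 3L]), ",")[[1]]) else integer(0)
      lmap[[gid]] <- as.integer(tab[i, 2L])
    }
  }
  out <- list()
  for (k in seq_along(ids)) {
    gid <- ids[k]
    expected_cds <- 3L * nchar(seqs[k])
    if (!is.null(lmap[[gid]]) && lmap[[gid]] != expected_cds) {
      warning("gene ", gid, ": stated cds_length ", lmap[[gid]],
              " != 3 x protein length (", expected_cds, "); record rejected")
      next
    }
    g <- tryCatch(
      gene_model(gid, seqs[k],
                 if (is.null(jmap[[gid]])) integer(0) else jmap[[gid]],
                 species = species),
      error = function(e) { warning(conditionMessage(e)); NULL })
    if (!is.null(g)) out[[gid]] <- g
  }
  out
}

#' Write the intron table and FASTA for a gene-model collection
#'
#' Inverse of [read_genes()]; used by the synthetic-data generator to emit
#' the exact on-disk formats the readers consume.
#'
#' @param genes Named list of `gene_model` objects.
#' @param fasta_path,intron_tsv_path Output paths.
#' @return Invisibly, the paths written.
#' @export
write_genes <- function(genes, fasta_path, intron_tsv_path) {
  aa <- Biostrings::AAStringSet(vapply(genes, `[[`, "", "protein_seq"))
  names(aa) <- vapply(genes, `[[`, "", "gene_id")
  Biostrings::writeXStringSet(aa, fasta_path)
  lines <- vapply(genes, function(g)
    paste(g$gene_id, g$cds_length,
          paste(g$intron_junctions, collapse = ","), sep = "\t"), "")
  writeLines(lines, intron_tsv_path)
  invisible(c(fasta_path, intron_tsv_path))
}

#' Read Pfam-style domain hits
#'
#' Headerless TSV with columns `gene_id, domain_type, start_res, end_res,
#' evalue`. Rows at or above `evalue_max` are dropped (the filter is strict:
#' a hit at exactly the threshold is excluded). When `genes` is supplied,
#' rows whose coordinates exceed the gene's protein length are rejected with
#' a diagnostic.
#'
#' @param tsv_path Path to the hits TSV.
#' @param evalue_max Strict e-value cutoff; default `1e-2`.
#' @param genes Optional named list of `gene_model`s for coordinate checks.
#' @return A data.frame of occurrences sorted by gene then `start_res`.
#' @export
read_domain_hits <- function(tsv_path, evalue_max = 1e-2, genes = NULL) {
  tab <- utils::read.delim(tsv_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("gene_id", "domain_type",
                                         "start_res", "end_res", "evalue"))
  tab$start_res <- as.integer(tab$start_res)
  tab$end_res <- as.integer(tab$end_res)
  tab$evalue <- as.numeric(tab$evalue)
  bad <- tab$start_res < 1L | tab$start_res > tab$end_res
  if (!is.null(genes)) {
    plen <- vapply(genes, function(g) nchar(g$protein_seq), 0L)
    over <- !is.na(match(tab$gene_id, names(plen))) &
      tab$end_res > plen[tab$gene_id]
    over[is.na(over)] <- FALSE
    if (any(over))
      warning(sum(over), " domain hit(s) exceed the protein length; rejected: ",
              paste(utils::head(tab$gene_id[over], 5L), collapse = ", "))
    bad <- bad | over
  }
  tab <- tab[!bad & tab$evalue < evalue_max, , drop = FALSE]
  tab <- tab[order(tab$gene_id, tab$start_res), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Derive an intron table from a GFF3 file
#'
#' Standalone convenience converter: for each gene the transcript with the
#' longest total CDS is selected (ties broken by transcript id order), its
#' CDS segments are chained in translation order, and intron junction
#' offsets are the cumulative CDS-segment lengths at each internal segment
#' boundary. Requires the `rtracklayer` package.
#'
#' @param gff_path Path to a GFF3 file with `CDS` features carrying `Parent`
#'   transcript ids and transcripts carrying gene `Parent`s (or `gene_id`
#'   attributes).
#' @return A data.frame with columns `gene_id`, `cds_length`,
#'   `intron_junctions` (comma-separated string), suitable for writing as
#'   the intron-table TSV.
#' @export
gff_to_intron_table <- function(gff_path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("gff_to_intron_table() requires the rtracklayer package")
  gr <- rtracklayer::import(gff_path)
  cds <- gr[tolower(as.character(gr$type)) == "cds"]
  if (!length(cds)) stop("no CDS features in ", gff_path)
  parents <- vapply(as.list(cds$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, "")
  tx <- gr[tolower(as.character(gr$type)) %in% c("mrna", "transcript")]
  tx_gene <- vapply(as.list(tx$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, "")
  names(tx_gene) <- tx$ID
  out <- list()
  for (t_id in unique(parents)) {
    seg <- cds[parents == t_id]
    seg <- seg[order(GenomicRanges::start(seg))]
    if (as.character(GenomicRanges::strand(seg))[1] == "-")
      seg <- rev(seg)
    w <- GenomicRanges::width(seg)
    total <- sum(w)
    junc <- if (length(w) > 1L) cumsum(w)[-length(w)] else integer(0)
    gid <- if (!is.na(tx_gene[t_id])) unname(tx_gene[t_id]) else t_id
    # stop codon is inside the terminal CDS segment in GFF3; drop it
    out[[t_id]] <- data.frame(gene_id = gid, transcript_id = t_id,
                              cds_length = total - 3L,
                              intron_junctions = paste(junc, collapse = ","),
                              stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  keep <- unlist(lapply(split(seq_len(nrow(tab)), tab$gene_id), function(ix) {
    ix[order(-tab$cds_length[ix], tab$transcript_id[ix])][1]
  }), use.names = FALSE)
  tab <- tab[sort(keep), c("gene_id", "cds_length", "intron_junctions")]
  rownames(tab) <- NULL
  tab
}

protein_lengths_of <- function(genes)
  vapply(genes, function(g) nchar(g$protein_seq), 0L)
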