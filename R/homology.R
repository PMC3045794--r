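#' Homology filter configuration
#'
#' Filters applied to local alignments before they count as homologous
#' regions between non-homologous genes: the alignment e-value must be
#' strictly below `evalue_max` and the aligned span must cover strictly
#' less than `coverage_max` of the shorter of the two proteins. The
#' coverage cap is what keeps paralogous gene pairs out of the
#' shuffling-region set.
#'
#' @param evalue_max Strict e-value cutoff, default `1e-3`.
#' @param coverage_max Strict coverage cap as a fraction of the shorter
#'   protein, default `0.5`.
#' @return A list with class `homology_config`.
#' @export
homology_config <- function(evalue_max = 1e-3, coverage_max = 0.5) {
  stopifnot(evalue_max > 0, coverage_max > 0, coverage_max <= 1)
  structure(list(evalue_max = evalue_max, coverage_max = coverage_max),
            class = "homology_config")
}

#' Read BLAST tabular (outfmt 6) alignments
#'
#' Parses the standard 12-column tab-separated dialect
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`). Self-hits (query equal to subject) are dropped; both
#' orientations of a gene pair are retained. Lines with a wrong column
#' count are skipped with a diagnostic.
#'
#' @param path Path to the tabular file.
#' @return A data.frame of hits with columns `query_id, subject_id, q_start,
#'   q_end, s_start, s_end, evalue, bitscore`.
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != 12L)) {
    warning(sum(nc != 12L), " malformed line(s) skipped (expected 12 columns)")
    parts <- parts[nc == 12L]
  }
  if (!length(parts))
    return(empty_hits())
  m <- do.call(rbind, parts)
  hits <- data.frame(
    query_id = m[, 1L], subject_id = m[, 2L],
    q_start = as.integer(m[, 7L]), q_end = as.integer(m[, 8L]),
    s_start = as.integer(m[, 9L]), s_end = as.integer(m[, 10L]),
    evalue = as.numeric(m[, 11L]), bitscore = as.numeric(m[, 12L]),
    stringsAsFactors = FALSE)
  hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

empty_hits <- function()
  data.frame(query_id = character(0), subject_id = character(0),
             q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             evalue = numeric(0), bitscore = numeric(0),
             stringsAsFactors = FALSE)

#' Write alignment hits in BLAST tabular format
#'
#' Emits the same 12-column dialect [read_blast_tab()] consumes; percent
#' identity, mismatch and gap-open columns are filled with placeholders
#' when unknown.
#' @param hits Hits data.frame as returned by [read_blast_tab()] or
#'   [local_align()].
#' @param path Output path.
#' @export
write_blast_tab <- function(hits, path) {
  alen <- hits$q_end - hits$q_start + 1L
  lines <- sprintf("%s\t%s\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.3g\t%.1f",
                   hits$query_id, hits$subject_id, 100, alen, 0L, 0L,
                   hits$q_start, hits$q_end, hits$s_start, hits$s_end,
                   hits$evalue, hits$bitscore)
  writeLines(lines, path)
  invisible(path)
}

# Karlin-Altschul ungapped-style parameters conventionally used with
# BLOSUM62 + gap open 11 / extend 1 (BLASTP defaults of the 2.2.x era).
ka_params <- list(lambda = 0.267, K = 0.041)

#' Smith-Waterman local alignment of two protein sequences
#'
#' Optimal local alignment under an affine gap model (a gap of length L
#' costs `gap_open + L * gap_extend`), scored with a substitution matrix
#' (BLOSUM62 by default). The e-value is the Karlin-Altschul estimate
#' `E = K * m * n * exp(-lambda * S)` with the constants conventionally
#' paired with BLOSUM62/11/1; the bitscore is
#' `(lambda * S - ln K) / ln 2`. The dynamic programming is delegated to
#' `Biostrings::pairwiseAlignment()`.
#'
#' If no residue pair scores positively the alignment is empty; a
#' zero-score sentinel hit (coordinates 0, evalue `Inf`) is returned.
#'
#' @param seq_a,seq_b Amino-acid sequences (character scalars).
#' @param id_a,id_b Identifiers placed in the hit record.
#' @param substitution_matrix Matrix name understood by Biostrings
#'   (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap parameters (defaults 11, 1).
#' @return A one-row hits data.frame (see [read_blast_tab()]) with an
#'   additional `score` column.
#' @export
local_align <- function(seq_a, seq_b, id_a = "A", id_b = "B",
                        substitution_matrix = "BLOSUM62",
                        gap_open = 11, gap_extend = 1) {
  stopifnot(nzchar(seq_a), nzchar(seq_b))
  alphabet <- rownames(get(data(list = substitution_matrix,
                                package = "Biostrings",
                                envir = environment())))
  for (s in c(seq_a, seq_b)) {
    bad <- setdiff(strsplit(s, "")[[1]], alphabet)
    if (length(bad))
      stop("sequence contains symbol(s) outside the substitution matrix ",
           "alphabet: ", paste(unique(bad), collapse = ", "))
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "local", substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  s <- Biostrings::score(al)
  m <- nchar(seq_a); n <- nchar(seq_b)
  if (s <= 0) {
    out <- empty_hits()
    out[1L, ] <- list(id_a, id_b, 0L, 0L, 0L, 0L, Inf, 0)
    out$score <- 0
    return(out)
  }
  pr <- al@pattern@range; sr <- al@subject@range
  ev <- ka_params$K * m * n * exp(-ka_params$lambda * s)
  bit <- (ka_params$lambda * s - log(ka_params$K)) / log(2)
  data.frame(query_id = id_a, subject_id = id_b,
             q_start = as.integer(pr@start),
             q_end = as.integer(pr@start + pr@width - 1L),
             s_start = as.integer(sr@start),
             s_end = as.integer(sr@start + sr@width - 1L),
             evalue = ev, bitscore = bit, score = s,
             stringsAsFactors = FALSE)
}

#' Filter alignment hits into homologous regions
#'
#' Keeps every hit with e-value strictly below `config$evalue_max` whose
#' query-side aligned span is strictly less than `config$coverage_max`
#' times the length of the shorter protein of the pair. All qualifying
#' regions of a gene pair are retained (each is tested independently for
#' intron flanking downstream); duplicates on (unordered pair, coordinates)
#' are collapsed.
#'
#' @param hits Hits data.frame (see [read_blast_tab()]).
#' @param protein_lengths Named integer vector covering every gene in
#'   `hits`.
#' @param config A [homology_config()].
#' @return A data.frame of regions with columns `gene_a, gene_b, a_start,
#'   a_end, b_start, b_end, evalue` (`gene_a`/`gene_b` keep the hit's
#'   query/subject orientation).
#' @export
find_homologous_regions <- function(hits, protein_lengths,
                                    config = homology_config()) {
  stopifnot(inherits(config, "homology_config"))
  genes <- unique(c(hits$query_id, hits$subject_id))
  missing <- setdiff(genes, names(protein_lengths))
  if (length(missing))
    stop("protein_lengths missing gene(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  if (!nrow(hits)) return(empty_regions())
  shorter <- pmin(protein_lengths[hits$query_id],
                  protein_lengths[hits$subject_id])
  span <- hits$q_end - hits$q_start + 1L
  keep <- hits$evalue < config$evalue_max &
    span < config$coverage_max * shorter
  reg <- hits[keep, , drop = FALSE]
  if (!nrow(reg)) return(empty_regions())
  out <- data.frame(gene_a = reg$query_id, gene_b = reg$subject_id,
                    a_start = reg$q_start, a_end = reg$q_end,
                    b_start = reg$s_start, b_end = reg$s_end,
                    evalue = reg$evalue, stringsAsFactors = FALSE)
  # dedupe on unordered pair + coordinates (canonical orientation key)
  flip <- out$gene_b < out$gene_a
  key <- ifelse(flip,
                paste(out$gene_b, out$gene_a,
                      out$b_start, out$b_end, out$a_start, out$a_end),
                paste(out$gene_a, out$gene_b,
                      out$a_start, out$a_end, out$b_start, out$b_end))
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_regions <- function()
  data.frame(gene_a = character(0), gene_b = character(0),
             a_start = integer(0), a_end = integer(0),
             b_start = integer(0), b_end = integer(0),
             evalue = numeric(0), stringsAsFactors = FALSE)

#' Write homologous regions as TSV
#' @param regions Regions data.frame from [find_homologous_regions()].
#' @param path Output path.
#' @export
write_regions <- function(regions, path) {
  utils::write.table(regions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
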