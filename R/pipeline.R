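#' Bundled reference contingency counts
#'
#' Reference 2x2 contingency inputs from a published comparative analysis
#' of exon shuffling and PPI network topology in six eukaryotes, shipped
#' so the chi-square pipeline can be validated against the statistics
#' printed alongside them. Each row carries the four cell counts
#' (`a`, `b` on row one; `c`, `d` on row two), the statistic printed in
#' the original report (`reported_chi2`), and the Bonferroni multiplier
#' used there (`m`). Counts of the 1/k-weighted domain tables are
#' fractional and were printed rounded to 0.1, so their recomputed
#' statistics carry a correspondingly larger rounding tolerance.
#'
#' Two rows are flagged `reproducible = FALSE` and excluded from
#' pass/fail summaries because their printed statistics cannot be derived
#' from their own printed cells (verified against independent
#' continuity-corrected implementations): the `promiscuity_vs_abundance`
#' association (printed 83.9; the cells give 100.2, suggesting a
#' different denominator set was used) and the plant `II_vs_III`
#' self-interaction flanking comparison (printed 10.7 with the same
#' p-value as the human row of the same table, suggesting a transcription
#' duplicate; the cells give 5.8).
#'
#' @return A data.frame of reference comparisons.
#' @export
reference_tables <- function() {
  rows <- list(
    # self-interaction fractions among ES/SS/WS network vertices
    list("self_interaction", "human", "ES_vs_SS", 328, 705, 927, 2855, 21.7, 1, TRUE, FALSE),
    list("self_interaction", "human", "ES_vs_WS", 328, 705, 940, 3179, 35.0, 1, TRUE, FALSE),
    list("self_interaction", "human", "SS_vs_WS", 927, 2855, 940, 3179, 3.0, 1, TRUE, FALSE),
    # 1/k-weighted intron flanking of domains, by self-interaction class
    list("domain_self", "human", "I_vs_II", 3168.2, 17189.1, 180.5, 1702.4, 47.6, 3, TRUE, TRUE),
    list("domain_self", "human", "I_vs_III", 3168.2, 17189.1, 548.8, 3838.0, 26.1, 3, TRUE, TRUE),
    list("domain_self", "human", "II_vs_III", 180.5, 1702.4, 548.8, 3838.0, 10.7, 3, TRUE, TRUE),
    list("domain_self", "sea_anemone", "I_vs_II", 1078.2, 9276.5, 110.5, 1480.9, 18.1, 3, TRUE, TRUE),
    list("domain_self", "sea_anemone", "I_vs_III", 1078.2, 9276.5, 187.8, 3344.2, 81.9, 3, TRUE, TRUE),
    list("domain_self", "sea_anemone", "II_vs_III", 110.5, 1480.9, 187.8, 3344.2, 5.0, 3, TRUE, TRUE),
    list("domain_self", "choanoflagellate", "I_vs_II", 272.7, 6525.3, 29.8, 922.0, 1.5, 3, TRUE, TRUE),
    list("domain_self", "choanoflagellate", "I_vs_III", 272.7, 6525.3, 55.6, 1890.8, 5.3, 3, TRUE, TRUE),
    list("domain_self", "choanoflagellate", "II_vs_III", 29.8, 922.0, 55.6, 1890.8, 0.1, 3, TRUE, TRUE),
    list("domain_self", "fungus", "I_vs_II", 98.5, 3690.1, 21.8, 668.2, 0.5, 3, TRUE, TRUE),
    list("domain_self", "fungus", "I_vs_III", 98.5, 3690.1, 34.8, 1502.7, 0.4, 3, TRUE, TRUE),
    list("domain_self", "fungus", "II_vs_III", 21.8, 668.2, 34.8, 1502.7, 1.2, 3, TRUE, TRUE),
    list("domain_self", "plant", "I_vs_II", 232.7, 5342.3, 29.9, 783.6, 0.3, 3, TRUE, TRUE),
    list("domain_self", "plant", "I_vs_III", 232.7, 5342.3, 81.6, 3678.9, 27.1, 3, TRUE, TRUE),
    list("domain_self", "plant", "II_vs_III", 29.9, 783.6, 81.6, 3678.9, 10.7, 3, FALSE, TRUE),
    # 1/k-weighted intron flanking, by promiscuity class
    list("domain_promiscuity", "human", "I_vs_II", 2723.4, 13357.3, 625.3, 5534.1, 159.8, 3, TRUE, TRUE),
    list("domain_promiscuity", "human", "I_vs_III", 2723.4, 13357.3, 548.8, 3838.0, 49.9, 3, TRUE, TRUE),
    list("domain_promiscuity", "human", "II_vs_III", 625.3, 5534.1, 548.8, 3838.0, 14.2, 3, TRUE, TRUE),
    list("domain_promiscuity", "sea_anemone", "I_vs_II", 904.5, 5730.4, 284.2, 5027.0, 224.9, 3, TRUE, TRUE),
    list("domain_promiscuity", "sea_anemone", "I_vs_III", 904.5, 5730.4, 187.8, 3344.2, 165.3, 3, TRUE, TRUE),
    list("domain_promiscuity", "sea_anemone", "II_vs_III", 284.2, 5027.0, 187.8, 3344.2, 0.0, 3, TRUE, TRUE),
    list("domain_promiscuity", "choanoflagellate", "I_vs_II", 197.2, 4097.5, 105.2, 3349.9, 11.8, 3, TRUE, TRUE),
    list("domain_promiscuity", "choanoflagellate", "I_vs_III", 197.2, 4097.5, 55.6, 1890.8, 9.9, 3, TRUE, TRUE),
    list("domain_promiscuity", "choanoflagellate", "II_vs_III", 105.2, 3349.9, 55.6, 1890.8, 0.1, 3, TRUE, TRUE),
    list("domain_promiscuity", "fungus", "I_vs_II", 68.7, 2196.2, 51.7, 2162.0, 1.8, 3, TRUE, TRUE),
    list("domain_promiscuity", "fungus", "I_vs_III", 68.7, 2196.2, 34.8, 1502.7, 1.8, 3, TRUE, TRUE),
    list("domain_promiscuity", "fungus", "II_vs_III", 51.7, 2162.0, 34.8, 1502.7, 0.0, 3, TRUE, TRUE),
    list("domain_promiscuity", "plant", "I_vs_II", 152.3, 3113.8, 110.4, 3012.0, 4.9, 3, TRUE, TRUE),
    list("domain_promiscuity", "plant", "I_vs_III", 152.3, 3113.8, 81.6, 3678.9, 33.0, 3, TRUE, TRUE),
    list("domain_promiscuity", "plant", "II_vs_III", 110.4, 3012.0, 81.6, 3678.9, 11.2, 3, TRUE, TRUE),
    # 1/k-weighted intron flanking, by abundance class
    list("domain_abundance", "human", "high_vs_low", 3729.5, 19111.6, 168.0, 3617.9, 366.5, 1, TRUE, TRUE),
    list("domain_abundance", "sea_anemone", "high_vs_low", 1259.4, 10640.1, 117.0, 3461.6, 180.8, 1, TRUE, TRUE),
    list("domain_abundance", "choanoflagellate", "high_vs_low", 278.4, 6800.3, 79.6, 2537.9, 4.0, 1, TRUE, TRUE),
    list("domain_abundance", "fungus", "high_vs_low", 98.6, 3365.0, 56.5, 2496.0, 2.1, 1, TRUE, TRUE),
    list("domain_abundance", "plant", "high_vs_low", 243.6, 6867.4, 100.6, 2937.4, 0.1, 1, TRUE, TRUE),
    # associations between domain-type properties (type counts)
    list("property_association", "human", "self_vs_promiscuity", 303, 936, 34, 453, 66.8, 1, TRUE, FALSE),
    list("property_association", "human", "self_vs_abundance", 385, 854, 79, 408, 38.5, 1, TRUE, FALSE),
    list("property_association", "human", "promiscuity_vs_abundance", 160, 287, 177, 1102, 83.9, 1, FALSE, FALSE))
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(analysis = r[[1]], species = r[[2]], comparison = r[[3]],
               a = r[[4]], b = r[[5]], c = r[[6]], d = r[[7]],
               reported_chi2 = r[[8]], m = r[[9]], reproducible = r[[10]],
               fractional = r[[11]], stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Recompute the reference chi-square statistics from their counts
#'
#' Runs [chi2_yates()] on every bundled reference contingency table (see
#' [reference_tables()]) and reports the recomputed statistic, the
#' Bonferroni-corrected p-value and the absolute difference from the
#' statistic printed in the original report.
#'
#' @return The [reference_tables()] data.frame with added columns
#'   `computed_chi2`, `p_value`, `p_corrected`, `abs_diff`.
#' @export
replicate_printed_tables <- function() {
  tab <- reference_tables()
  res <- lapply(seq_len(nrow(tab)), function(i)
    chi2_yates(tab$a[i], tab$b[i], tab$c[i], tab$d[i]))
  tab$computed_chi2 <- vapply(res, `[[`, 0, "statistic")
  tab$p_value <- vapply(res, `[[`, 0, "p_value")
  tab$p_corrected <- mapply(bonferroni, tab$p_value, tab$m)
  tab$abs_diff <- abs(tab$computed_chi2 - tab$reported_chi2)
  tab
}

#' Run the full analysis pipeline on in-memory inputs
#'
#' Orchestrates every stage over one species' data: homologous-region
#' filtering, ES/SS/WS classification, network annotation,
#' presence-in-network contingencies, pairwise degree comparisons (U
#' test and resampling, Bonferroni m = 3) before and after paralog
#' confluence, self-interaction contingencies, and the three
#' paralog-weighted domain flanking tables with their pairwise
#' chi-squares plus the domain property association tables.
#'
#' @param genes Named list of `gene_model`s (the full gene set).
#' @param hits Alignment hits data.frame (see [read_blast_tab()]).
#' @param network A `ppi_network`.
#' @param occurrences Domain occurrences (see [read_domain_hits()]).
#' @param ddi DDI table (see [read_ddi()]).
#' @param families Optional `paralog_families`; detected from `hits` when
#'   `NULL`.
#' @param species Species config from [species_config()].
#' @param homology A [homology_config()].
#' @param resample A [resample_config()] (drives every resampling test).
#' @param out_dir Optional directory; when set, every result table is
#'   also written as TSV.
#' @return A named list of result tables (`calls`, `network`,
#'   `confluenced`, `presence`, `degree_tests`, `self_interaction`,
#'   `flank_tables`, `flank_tests`, `association`, `counts_log`).
#' @export
run_full_analysis <- function(genes, hits, network, occurrences, ddi,
                              families = NULL,
                              species = species_config("synthetic", 2L),
                              homology = homology_config(),
                              resample = resample_config(n_iter = 10000L,
                                                         seed = 1L),
                              out_dir = NULL) {
  plen <- protein_lengths_of(genes)
  regions <- find_homologous_regions(hits, plen, homology)
  calls <- classify_genes(regions, genes, species)
  network <- annotate_network(network, calls)
  if (is.null(families)) families <- detect_paralogs(hits, plen)

  pairs <- list(c("ES", "SS"), c("ES", "WS"), c("SS", "WS"))
  # a zero margin (e.g. every gene in the network) carries no contrast;
  # record NA rather than abort the run
  chi2_or_na <- function(...) tryCatch(chi2_yates(...), error = function(e)
    list(statistic = NA_real_, p_value = NA_real_, df = 1L))
  presence <- lapply(pairs, function(p) {
    ct <- presence_contingency(calls, network, p)
    cs <- chi2_or_na(ct)
    list(pair = paste(p, collapse = "_vs_"), table = ct,
         chi2 = cs$statistic, p = cs$p_value,
         p_corrected = bonferroni(cs$p_value, 3))
  })

  degree_of <- function(net, cat)
    net$vertices$degree[net$vertices$category == cat &
                          !is.na(net$vertices$category)]
  conf <- confluence(network, families, calls)
  degree_tests <- do.call(rbind, lapply(pairs, function(p) {
    out <- lapply(c(before = "before", after = "after"), function(stage) {
      net <- if (stage == "before") network else conf
      dx <- degree_of(net, p[1L]); dy <- degree_of(net, p[2L])
      if (length(dx) < 2L || length(dy) < 2L) return(NULL)
      rs <- resample_mean_diff(dx, dy, resample)
      u <- mann_whitney_u(dx, dy)
      data.frame(pair = paste(p, collapse = "_vs_"), stage = stage,
                 mean_1 = mean(dx), mean_2 = mean(dy),
                 resample_p = bonferroni(rs$p_value, 3),
                 resample_p_is_bound = rs$p_is_bound,
                 z = rs$z_score, u_p = bonferroni(u$p_value, 3),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }))
  rownames(degree_tests) <- NULL

  self_tab <- do.call(rbind, lapply(pairs, function(p) {
    v <- network$vertices
    cells <- t(vapply(p, function(cc) {
      sel <- v$category == cc & !is.na(v$category)
      c(sum(v$self_interacting[sel]), sum(sel) - sum(v$self_interacting[sel]))
    }, numeric(2)))
    cs <- chi2_or_na(cells[1, 1], cells[1, 2], cells[2, 1], cells[2, 2])
    data.frame(pair = paste(p, collapse = "_vs_"),
               self_1 = cells[1, 1], non_self_1 = cells[1, 2],
               self_2 = cells[2, 1], non_self_2 = cells[2, 2],
               chi2 = cs$statistic, p = cs$p_value,
               stringsAsFactors = FALSE)
  }))

  classification <- classify_domain_types(ddi, occurrences)
  groupings <- c("self_interaction", "promiscuity", "abundance")
  flank_tables <- lapply(groupings, function(g)
    weighted_flank_table(occurrences, genes, families, classification, g))
  names(flank_tables) <- groupings
  flank_tests <- do.call(rbind, lapply(groupings, function(g) {
    ft <- flank_tables[[g]]
    combs <- utils::combn(nrow(ft), 2L)
    m <- ncol(combs)
    do.call(rbind, lapply(seq_len(m), function(k) {
      i <- combs[1L, k]; j <- combs[2L, k]
      cs <- chi2_or_na(ft$flanked_weighted[i],
                       ft$total_weighted[i] - ft$flanked_weighted[i],
                       ft$flanked_weighted[j],
                       ft$total_weighted[j] - ft$flanked_weighted[j])
      data.frame(grouping = g,
                 comparison = paste(ft$group[i], "vs", ft$group[j]),
                 chi2 = cs$statistic, p = cs$p_value,
                 p_corrected = bonferroni(cs$p_value, m),
                 stringsAsFactors = FALSE)
    }))
  }))

  assoc <- property_association_tables(classification)
  association <- do.call(rbind, lapply(names(assoc), function(nm) {
    cs <- chi2_or_na(assoc[[nm]])
    data.frame(association = nm, chi2 = cs$statistic, p = cs$p_value,
               stringsAsFactors = FALSE)
  }))

  counts_log <- data.frame(
    stage = c("genes", "hits", "regions", "ES", "SS", "WS",
              "network_vertices", "network_edges", "confluenced_vertices",
              "paralog_families", "domain_occurrences", "ddi_pairs"),
    n = c(length(genes), nrow(hits), nrow(regions),
          sum(calls$category == "ES"), sum(calls$category == "SS"),
          sum(calls$category == "WS"), nrow(network$vertices),
          nrow(network$edges), nrow(conf$vertices),
          length(families$sizes), nrow(occurrences), nrow(ddi)))

  out <- list(calls = calls, regions = regions, network = network,
              confluenced = conf, families = families,
              presence = presence, degree_tests = degree_tests,
              self_interaction = self_tab,
              classification = classification,
              flank_tables = flank_tables, flank_tests = flank_tests,
              association = association, counts_log = counts_log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    w(calls, "calls.tsv"); w(degree_tests, "degree_tests.tsv")
    w(self_tab, "self_interaction.tsv"); w(flank_tests, "flank_tests.tsv")
    w(association, "association.tsv"); w(counts_log, "counts_log.tsv")
    for (g in groupings) w(flank_tables[[g]],
                           paste0("flank_table_", g, ".tsv"))
  }
  out
}
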