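#' Read a domain-domain interaction (DDI) table
#'
#' Headerless two-column TSV of interacting domain-type pairs (self-pairs
#' allowed). Pairs are deduplicated as unordered pairs. Confidence-tier
#' filtering (e.g. keeping only structural and high-confidence predicted
#' interactions) is expected to have been applied to the input file.
#'
#' @param path Path to the DDI TSV.
#' @return A data.frame with columns `domain_a`, `domain_b` (unordered,
#'   deduplicated).
#' @export
read_ddi <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character")
  ddi_table(tab[[1L]], tab[[2L]])
}

#' Construct a DDI table from two vectors of domain types
#' @param domain_a,domain_b Character vectors of equal length.
#' @return Deduplicated unordered pair data.frame.
#' @export
ddi_table <- function(domain_a, domain_b) {
  lo <- pmin(domain_a, domain_b); hi <- pmax(domain_a, domain_b)
  out <- unique(data.frame(domain_a = lo, domain_b = hi,
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Classify domain types by interaction properties and abundance
#'
#' For every domain type seen in `occurrences` (and any type in the DDI
#' table), computes: `self_interacting` — the DDI table contains the
#' type's self-pair; `promiscuity` — `promiscuous` for six or more
#' distinct partner types (the self-pair counts as one partner),
#' `non_promiscuous_DI` for one to five, `non_DI` for none; `abundance` —
#' `high` for four or more occurrences proteome-wide, `low` for up to
#' three.
#'
#' @param ddi DDI data.frame (see [read_ddi()]).
#' @param occurrences Domain-occurrence data.frame (see
#'   [read_domain_hits()]).
#' @param promiscuity_min Partner count defining promiscuity (default 6).
#' @param abundance_min Occurrence count defining high abundance
#'   (default 4).
#' @return A data.frame with one row per domain type: `domain_type,
#'   self_interacting, n_partners, promiscuity, n_occurrences, abundance`.
#' @export
classify_domain_types <- function(ddi, occurrences,
                                  promiscuity_min = 6L, abundance_min = 4L) {
  types <- sort(unique(c(occurrences$domain_type, ddi$domain_a, ddi$domain_b)))
  partners <- stats::setNames(vector("list", length(types)), types)
  for (i in seq_len(nrow(ddi))) {
    a <- ddi$domain_a[i]; b <- ddi$domain_b[i]
    partners[[a]] <- union(partners[[a]], b)
    partners[[b]] <- union(partners[[b]], a)
  }
  n_partners <- vapply(types, function(t) length(partners[[t]]), 0L)
  self_int <- vapply(types, function(t) t %in% partners[[t]], TRUE)
  occ_tab <- table(occurrences$domain_type)
  n_occ <- stats::setNames(integer(length(types)), types)
  n_occ[names(occ_tab)] <- as.integer(occ_tab)
  promiscuity <- ifelse(n_partners == 0L, "non_DI",
                        ifelse(n_partners >= promiscuity_min,
                               "promiscuous", "non_promiscuous_DI"))
  data.frame(
    domain_type = types,
    self_interacting = unname(self_int),
    n_partners = unname(n_partners),
    promiscuity = factor(promiscuity,
                         levels = c("promiscuous", "non_promiscuous_DI",
                                    "non_DI")),
    n_occurrences = unname(n_occ),
    abundance = factor(ifelse(n_occ >= abundance_min, "high", "low"),
                       levels = c("high", "low")),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Is a domain occurrence bilaterally flanked by introns?
#'
#' Projects the occurrence's residue span to CDS nucleotides `[n5, n3]`
#' and tests the two flanking windows over intron junction offsets:
#' N-terminal window `[n5 - 1 - exterior, n5 - 1 + interior]`, C-terminal
#' window `[n3 - interior, n3 + exterior]`, both clipped to
#' `[0, cds_length]`. Returns `TRUE` only when *both* windows contain at
#' least one intron junction. Domain windows reach 32 nt toward the
#' exterior (versus 20 for alignment borders) and 3 nt toward the
#' interior.
#'
#' @param occurrence One-row occurrence data.frame (`start_res`,
#'   `end_res`).
#' @param gene_model The gene's `gene_model`.
#' @param interior,exterior Window extents in nucleotides (defaults 3,
#'   32).
#' @return Logical flag.
#' @export
domain_flanked <- function(occurrence, gene_model,
                           interior = 3L, exterior = 32L) {
  if (occurrence$start_res < 1L ||
      occurrence$end_res > nchar(gene_model$protein_seq))
    stop("domain occurrence outside protein ", gene_model$gene_id)
  nt <- residue_span_to_nt(occurrence$start_res, occurrence$end_res)
  n5 <- nt[1L, "nt_start"]; n3 <- nt[1L, "nt_end"]
  clip <- function(x) pmin(pmax(x, 0L), gene_model$cds_length)
  j <- gene_model$intron_junctions
  win <- function(lo, hi) any(j >= clip(lo) & j <= clip(hi))
  win(n5 - 1L - exterior, n5 - 1L + interior) &&
    win(n3 - interior, n3 + exterior)
}

#' Paralog-weighted flanked/total domain counts by group
#'
#' Every domain occurrence contributes `1/k` (its gene's paralog-family
#' weight) to its group's total and, when bilaterally intron-flanked, to
#' the group's flanked count. Grouping is by the occurrence's domain
#' type's class under one of three schemes: `self_interaction` (group I
#' self-interacting, II non-self-interacting DI, III non-DI),
#' `promiscuity` (I promiscuous, II non-promiscuous DI, III non-DI) or
#' `abundance` (I high, II low).
#'
#' @param occurrences Occurrence data.frame (see [read_domain_hits()]).
#' @param models Named list of `gene_model`s.
#' @param families A `paralog_families` covering the occurrences' genes.
#' @param classification Data.frame from [classify_domain_types()].
#' @param grouping One of `"self_interaction"`, `"promiscuity"`,
#'   `"abundance"`.
#' @param interior,exterior Window extents passed to [domain_flanked()].
#' @return A data.frame with columns `group, flanked_weighted,
#'   total_weighted, flanking_percentage`.
#' @export
weighted_flank_table <- function(occurrences, models, families,
                                 classification,
                                 grouping = c("self_interaction",
                                              "promiscuity", "abundance"),
                                 interior = 3L, exterior = 32L) {
  grouping <- match.arg(grouping)
  w <- family_weight(families, occurrences$gene_id)
  cls <- classification[match(occurrences$domain_type,
                              classification$domain_type), ]
  group <- switch(grouping,
    self_interaction = ifelse(cls$promiscuity == "non_DI", "III",
                              ifelse(cls$self_interacting, "I", "II")),
    promiscuity = c(promiscuous = "I", non_promiscuous_DI = "II",
                    non_DI = "III")[as.character(cls$promiscuity)],
    abundance = c(high = "I", low = "II")[as.character(cls$abundance)])
  flanked <- vapply(seq_len(nrow(occurrences)), function(i)
    domain_flanked(occurrences[i, ], models[[occurrences$gene_id[i]]],
                   interior = interior, exterior = exterior), TRUE)
  levels <- if (grouping == "abundance") c("I", "II") else c("I", "II", "III")
  out <- do.call(rbind, lapply(levels, function(g) {
    sel <- group == g
    data.frame(group = g,
               flanked_weighted = sum(w[sel & flanked]),
               total_weighted = sum(w[sel]),
               stringsAsFactors = FALSE)
  }))
  out$flanking_percentage <- ifelse(out$total_weighted > 0,
                                    100 * out$flanked_weighted / out$total_weighted,
                                    NA_real_)
  rownames(out) <- NULL
  out
}

#' Pairwise association tables between domain-type properties
#'
#' Cross-tabulates domain TYPES (not occurrences) on three dichotomies:
#' self-interacting vs non-self-interacting (among DI types),
#' promiscuous vs non-promiscuous (among DI types), abundant vs rare.
#' Three 2x2 tables are returned: self-interaction x promiscuity,
#' self-interaction x abundance, promiscuity x abundance. The first two
#' are restricted to domain-interacting types (self-interaction is
#' undefined for non-DI types); the third uses DI types as well, so all
#' three tables share one denominator set.
#'
#' @param classification Data.frame from [classify_domain_types()].
#' @return A named list of three 2x2 integer matrices:
#'   `self_vs_promiscuity`, `self_vs_abundance`,
#'   `promiscuity_vs_abundance`.
#' @export
property_association_tables <- function(classification) {
  di <- classification[classification$promiscuity != "non_DI", ]
  self_f <- factor(ifelse(di$self_interacting, "self_interacting",
                          "non_self_interacting"),
                   levels = c("self_interacting", "non_self_interacting"))
  prom_f <- factor(ifelse(di$promiscuity == "promiscuous", "promiscuous",
                          "non_promiscuous"),
                   levels = c("promiscuous", "non_promiscuous"))
  abund_f <- factor(ifelse(di$abundance == "high", "abundant", "rare"),
                    levels = c("abundant", "rare"))
  as_m <- function(f1, f2) {
    m <- table(f1, f2)
    m <- matrix(as.integer(m), 2L, 2L, dimnames = dimnames(m))
    names(dimnames(m)) <- NULL
    m
  }
  list(self_vs_promiscuity = as_m(self_f, prom_f),
       self_vs_abundance = as_m(self_f, abund_f),
       promiscuity_vs_abundance = as_m(prom_f, abund_f))
}

#' Write a weighted flank table as TSV
#' @param tab Data.frame from [weighted_flank_table()].
#' @param path Output path.
#' @export
write_flank_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
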