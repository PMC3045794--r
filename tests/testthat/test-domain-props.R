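make_occ <- function(gene_id, domain_type, start_res, end_res, evalue = 1e-5)
  data.frame(gene_id = gene_id, domain_type = domain_type,
             start_res = start_res, end_res = end_res, evalue = evalue,
             stringsAsFactors = FALSE)

test_that("domain types classify by partners, self-pairs and abundance", {
  ddi <- ddi_table(c("P1", "P1", "P1", "P1", "P1", "P1", "P2", "P3"),
                   c("A", "B", "C", "D", "E", "P1", "P2", "A"))
  occ <- rbind(make_occ("g1", "P1", 1, 50), make_occ("g2", "P1", 1, 50),
               make_occ("g3", "P1", 1, 50), make_occ("g4", "P1", 1, 50),
               make_occ("g1", "P2", 60, 90), make_occ("g2", "P2", 60, 90),
               make_occ("g3", "P2", 60, 90),
               make_occ("g1", "P9", 100, 130))
  cl <- classify_domain_types(ddi, occ)
  row <- function(t) cl[cl$domain_type == t, ]
  # P1 partners: A B C D E + itself = 6 -> promiscuous; self-pair present
  expect_equal(row("P1")$n_partners, 6L)
  expect_equal(as.character(row("P1")$promiscuity), "promiscuous")
  expect_true(row("P1")$self_interacting)
  expect_equal(as.character(row("P1")$abundance), "high")     # 4 occurrences
  # P2: only the self-pair -> 1 partner, self-interacting, 3 occ -> low
  expect_equal(as.character(row("P2")$promiscuity), "non_promiscuous_DI")
  expect_true(row("P2")$self_interacting)
  expect_equal(as.character(row("P2")$abundance), "low")
  # P9 absent from DDI: non_DI and not self-interacting
  expect_equal(as.character(row("P9")$promiscuity), "non_DI")
  expect_false(row("P9")$self_interacting)
  # row order of the DDI table does not matter
  perm <- ddi[sample(nrow(ddi)), ]
  expect_equal(classify_domain_types(perm, occ), cl)
})

test_that("bilateral intron flanking of a domain matches the window oracle", {
  # domain residues 21..40: nt span [61, 120]; borders at junctions 60, 120
  intronless <- make_gene("gA", 100L)
  occ <- make_occ("gA", "P1", 21, 40)
  expect_false(domain_flanked(occ, intronless))
  both <- make_gene("gA", 100L, c(60L, 120L))
  expect_true(domain_flanked(occ, both))
  one_side <- make_gene("gA", 100L, 60L)
  expect_false(domain_flanked(occ, one_side))
  # exterior reach: junction 28 = 60 - 32 is in; 27 is out
  expect_true(domain_flanked(occ, make_gene("gA", 100L, c(28L, 120L))))
  expect_false(domain_flanked(occ, make_gene("gA", 100L, c(27L, 120L))))
  expect_error(domain_flanked(make_occ("gA", "P1", 90, 110), intronless),
               "outside")

  set.seed(71)
  for (i in 1:40) {
    g <- random_gene("gA", 80L, sample(0:10, 1))
    o <- make_occ("gA", "P1", 15, 55)
    nt <- residue_span_to_nt(15, 55)
    j <- g$intron_junctions
    n_ok <- any(j >= nt[1] - 1 - 32 & j <= nt[1] - 1 + 3)
    c_ok <- any(j >= nt[2] - 3 & j <= nt[2] + 32)
    expect_equal(domain_flanked(o, g), n_ok && c_ok)
  }
})

test_that("weighted flank tables apply 1/k weights and preserve order", {
  genes <- list(gA = make_gene("gA", 100L, c(60L, 120L)),  # flanks 21..40
                gB = make_gene("gB", 100L),
                gC = make_gene("gC", 100L, c(60L, 120L)))
  f <- withr::local_tempfile()
  writeLines("gA\tgB", f)                     # family {gA,gB}, k = 2
  fam <- read_paralog_list(f, names(genes))
  ddi <- ddi_table(c("PS", "PN"), c("PS", "PX"))
  occ <- rbind(make_occ("gA", "PS", 21, 40),  # flanked, weight .5
               make_occ("gB", "PS", 21, 40),  # unflanked, weight .5
               make_occ("gC", "PN", 21, 40),  # flanked, weight 1
               make_occ("gC", "PZ", 21, 40))  # flanked non-DI, weight 1
  cl <- classify_domain_types(ddi, occ)
  tab <- weighted_flank_table(occ, genes, fam, cl, "self_interaction")
  expect_equal(tab$group, c("I", "II", "III"))
  expect_equal(tab$flanked_weighted[tab$group == "I"], 0.5)
  expect_equal(tab$total_weighted[tab$group == "I"], 1.0)
  expect_equal(tab$flanking_percentage[tab$group == "I"], 50)
  expect_equal(tab$total_weighted[tab$group == "II"], 1.0)
  expect_equal(tab$total_weighted[tab$group == "III"], 1.0)
  expect_true(all(tab$flanked_weighted <= tab$total_weighted))

  # direct summation oracle over a random proteome
  set.seed(73)
  genes2 <- lapply(sprintf("h%02d", 1:15), function(id)
    random_gene(id, 120L, sample(0:8, 1)))
  names(genes2) <- vapply(genes2, `[[`, "", "gene_id")
  fam2 <- exshuffle:::families_from_pairs(
    list(c("h01", "h02"), c("h02", "h03"), c("h04", "h05")), names(genes2))
  occ2 <- do.call(rbind, lapply(1:30, function(i)
    make_occ(sample(names(genes2), 1), sample(c("PS", "PN", "PZ"), 1),
             20, 70)))
  cl2 <- classify_domain_types(ddi, occ2)
  tab2 <- weighted_flank_table(occ2, genes2, fam2, cl2, "abundance")
  w <- family_weight(fam2, occ2$gene_id)
  fl <- vapply(seq_len(nrow(occ2)), function(i)
    domain_flanked(occ2[i, ], genes2[[occ2$gene_id[i]]]), TRUE)
  abclass <- as.character(cl2$abundance[match(occ2$domain_type,
                                              cl2$domain_type)])
  expect_equal(tab2$total_weighted[tab2$group == "I"],
               sum(w[abclass == "high"]))
  expect_equal(tab2$flanked_weighted[tab2$group == "I"],
               sum(w[abclass == "high" & fl]))
  expect_equal(tab2$total_weighted[tab2$group == "II"],
               sum(w[abclass == "low"]))
})

test_that("property association tables tally domain types with shared margins", {
  set.seed(79)
  n <- 60
  cl <- data.frame(
    domain_type = sprintf("P%02d", 1:n),
    self_interacting = sample(c(TRUE, FALSE), n, replace = TRUE),
    n_partners = 1L,
    promiscuity = factor(sample(c("promiscuous", "non_promiscuous_DI",
                                  "non_DI"), n, replace = TRUE),
                         levels = c("promiscuous", "non_promiscuous_DI",
                                    "non_DI")),
    n_occurrences = 1L,
    abundance = factor(sample(c("high", "low"), n, replace = TRUE),
                       levels = c("high", "low")),
    stringsAsFactors = FALSE)
  cl$self_interacting[cl$promiscuity == "non_DI"] <- FALSE
  tabs <- property_association_tables(cl)
  di <- cl[cl$promiscuity != "non_DI", ]
  expect_equal(tabs$self_vs_promiscuity["self_interacting", "promiscuous"],
               sum(di$self_interacting & di$promiscuity == "promiscuous"))
  expect_equal(tabs$self_vs_abundance["non_self_interacting", "rare"],
               sum(!di$self_interacting & di$abundance == "low"))
  # all three tables share the DI-type denominator
  expect_equal(sum(tabs$self_vs_promiscuity), nrow(di))
  expect_equal(sum(tabs$self_vs_abundance), nrow(di))
  expect_equal(sum(tabs$promiscuity_vs_abundance), nrow(di))
  # margins agree across tables
  expect_equal(rowSums(tabs$self_vs_promiscuity),
               rowSums(tabs$self_vs_abundance))
  expect_equal(colSums(tabs$self_vs_promiscuity),
               rowSums(tabs$promiscuity_vs_abundance))
})
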