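test_that("interaction records parse from MITAB and edge TSV dialects", {
  f <- withr::local_tempfile()
  mitab <- paste(c('uniprotkb:P1', 'uniprotkb:P2', '-', '-', '-', '-',
                   'psi-mi:"MI:0018"(two hybrid)', '-', '-', '-', '-',
                   'psi-mi:"MI:0915"(physical association)',
                   'psi-mi:"MI:0471"(MINT)', '-'), collapse = "\t")
  writeLines(c(mitab, "too\tshort"), f)
  expect_warning(rec <- read_interactions(f, "mitab_min"), "short")
  expect_equal(rec$id_a, "P1")
  expect_match(rec$detection_method, "two hybrid")
  expect_match(rec$source_db, "MINT")

  writeLines(c("A\tB", "A\tB"), f)
  rec2 <- read_interactions(f, "edge_tsv")
  # duplicates retained at read time (deduplication happens at build)
  expect_equal(nrow(rec2), 2L)
  expect_equal(rec2$detection_method, c("", ""))
})

test_that("network build filters, collapses, deduplicates and flags selfs", {
  rec <- data.frame(
    id_a = c("p1", "p2", "p3", "p4", "p5", "p5"),
    id_b = c("p2", "p1", "p3", "p5", "p4", "p6"),
    detection_method = c("two hybrid", "x-ray", "two hybrid",
                         "anti tag coimmunoprecipitation",
                         "tandem ms fishing", "two hybrid"),
    interaction_type = c("physical association", "direct interaction",
                         "physical association", "physical association",
                         "physical association", "genetic interaction"),
    source_db = "db", stringsAsFactors = FALSE)
  idmap <- data.frame(raw_id = c("p1", "p2", "p3", "p4", "p5", "p6"),
                      gene_id = c("gA", "gB", "gC", "gD", "gE", "gF"),
                      stringsAsFactors = FALSE)
  net <- build_network(rec, network_filter_config(id_map = idmap))
  # p1-p2 and p2-p1 collapse to one edge; MS record and genetic record excluded
  expect_equal(nrow(net$edges), 2L)
  v <- net$vertices
  expect_equal(v$degree[v$gene_id == "gA"], 1)
  # self-interaction only: vertex kept with degree 0, flag set
  expect_true(v$self_interacting[v$gene_id == "gC"])
  expect_equal(v$degree[v$gene_id == "gC"], 0)
  # excluded records leave no vertex behind
  expect_false("gF" %in% v$gene_id)
  # adding an excluded pattern never adds edges
  net2 <- build_network(rec, network_filter_config(
    excluded_method_patterns = c(default_exclusions()$methods, "two hybrid"),
    id_map = idmap))
  expect_lte(nrow(net2$edges), nrow(net$edges))
})

test_that("a multi-mapped identifier contributes an edge per mapped gene", {
  rec <- data.frame(id_a = "p1", id_b = "p2",
                    detection_method = "", interaction_type = "",
                    source_db = "", stringsAsFactors = FALSE)
  idmap <- data.frame(raw_id = c("p1", "p1", "p2"),
                      gene_id = c("gA", "gB", "gC"), stringsAsFactors = FALSE)
  net <- build_network(rec, network_filter_config(id_map = idmap))
  expect_equal(nrow(net$edges), 2L)
  expect_setequal(net$vertices$gene_id, c("gA", "gB", "gC"))
  expect_equal(net$vertices$degree[net$vertices$gene_id == "gC"], 2)
})

test_that("degree sums to twice the edge count on random networks", {
  set.seed(53)
  for (i in 1:10) {
    ids <- paste0("g", 1:30)
    pairs <- unique(t(replicate(40, sort(sample(ids, 2)))))
    net <- edge_network(split(pairs, row(pairs)))
    expect_equal(sum(net$vertices$degree), 2 * nrow(net$edges))
  }
})

test_that("orthology projection preserves edges iff both orthologs map", {
  src <- edge_network(list(c("a", "b"), c("b", "c")), self = "a")
  ot <- data.frame(target_gene = c("x", "y"), source_gene = c("a", "b"),
                   stringsAsFactors = FALSE)
  proj <- project_by_orthology(src, ot)
  expect_equal(nrow(proj$edges), 1L)
  expect_setequal(unlist(proj$edges[1, ]), c("x", "y"))
  # self-interaction of a inherited by x
  expect_true(proj$vertices$self_interacting[proj$vertices$gene_id == "x"])
  # b-c edge lost: c has no ortholog
  expect_false("c" %in% proj$vertices$gene_id)
  # identity orthology reproduces the network
  idm <- data.frame(target_gene = c("a", "b", "c"),
                    source_gene = c("a", "b", "c"), stringsAsFactors = FALSE)
  same <- project_by_orthology(src, idm)
  expect_equal(same$edges[order(same$edges$gene_a), ],
               src$edges[order(src$edges$gene_a), ], ignore_attr = TRUE)
  expect_equal(same$vertices$degree, src$vertices$degree)
  # empty mapping gives an empty network
  empty <- project_by_orthology(
    src, data.frame(target_gene = character(0), source_gene = character(0)))
  expect_equal(nrow(empty$vertices), 0L)
  # many-to-many ortholog rows are rejected
  mm <- data.frame(target_gene = c("x", "x", "y"),
                   source_gene = c("a", "b", "b"), stringsAsFactors = FALSE)
  expect_warning(project_by_orthology(src, mm), "many-to-many")
})

test_that("presence contingency equals a direct tally", {
  set.seed(57)
  ids <- sprintf("g%03d", 1:60)
  calls <- data.frame(gene_id = ids,
                      category = factor(sample(c("ES", "SS", "WS"), 60,
                                               replace = TRUE),
                                        levels = c("ES", "SS", "WS")),
                      stringsAsFactors = FALSE)
  member <- sample(ids, 35)
  net <- edge_network(lapply(seq(1, 34, by = 2),
                             function(i) member[c(i, i + 1)]),
                      self = member[35])
  ct <- presence_contingency(calls, net, c("ES", "SS"))
  for (ci in 1:2) {
    cc <- c("ES", "SS")[ci]
    expect_equal(ct[ci, "in_network"],
                 sum(calls$category == cc &
                       calls$gene_id %in% net$vertices$gene_id))
    expect_equal(sum(ct[ci, ]), sum(calls$category == cc))
  }
})
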