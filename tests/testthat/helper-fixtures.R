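# Small builders shared across test files.

# deterministic "protein" of length n (cycles through 20 AA letters)
aa_seq <- function(n) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste(rep_len(aa, n), collapse = "")
}

make_gene <- function(id, len, junctions = integer(0))
  gene_model(id, aa_seq(len), junctions)

random_gene <- function(id, len, n_junc = 0L) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  j <- if (n_junc > 0L) sort(sample.int(3L * len - 1L, n_junc)) else integer(0)
  gene_model(id, paste(sample(aa, len, replace = TRUE), collapse = ""), j)
}

make_region <- function(gene_a, gene_b, a_start, a_end, b_start, b_end,
                        evalue = 1e-10)
  data.frame(gene_a = gene_a, gene_b = gene_b,
             a_start = a_start, a_end = a_end,
             b_start = b_start, b_end = b_end,
             evalue = evalue, stringsAsFactors = FALSE)

make_hit <- function(q, s, qs, qe, ss, se, evalue = 1e-10, bitscore = 100)
  data.frame(query_id = q, subject_id = s, q_start = qs, q_end = qe,
             s_start = ss, s_end = se, evalue = evalue, bitscore = bitscore,
             stringsAsFactors = FALSE)

edge_network <- function(pairs, self = character(0), lengths = NULL) {
  edges <- if (length(pairs))
    data.frame(gene_a = pmin(vapply(pairs, `[`, "", 1L),
                             vapply(pairs, `[`, "", 2L)),
               gene_b = pmax(vapply(pairs, `[`, "", 1L),
                             vapply(pairs, `[`, "", 2L)),
               stringsAsFactors = FALSE)
  else data.frame(gene_a = character(0), gene_b = character(0))
  exshuffle:::new_ppi_network(unique(edges), self, lengths)
}
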