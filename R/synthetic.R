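#' Parameters for the synthetic-data generator
#'
#' One object holds every knob of the generator: genome shape, planted
#' shuffling events, the degree model of the PPI network and the domain
#' model. All randomness flows from `seed` through fixed per-stage
#' substreams, so each stage is individually reproducible.
#'
#' @param n_genes Number of genes.
#' @param mean_protein_length Mean protein length in residues (lognormal).
#' @param length_spread Lognormal sdlog of protein length.
#' @param min_protein_length Lower clip on protein length; keeps planted
#'   segments under the 50 percent coverage cap.
#' @param intron_density Expected intron junctions per kb of CDS.
#' @param n_shuffle_events Number of planted exon-shuffling events
#'   (donor/acceptor pairs with intron-flanked copied segments).
#' @param shuffled_segment_length Copied segment length in residues.
#' @param intron_loss_rate Probability that each planted flanking intron
#'   is deleted.
#' @param n_ss_pairs Pairs receiving a copied segment with no intron
#'   support (sequence-shuffling truth).
#' @param baseline_degree Expected vertex degree of a non-ES gene.
#' @param es_degree_multiplier Multiplier on the expected degree of
#'   truth-ES genes.
#' @param self_prob Named probabilities of a self-interaction flag per
#'   category (`ES`, `SS`, `WS`).
#' @param n_domain_types,mean_occurrences_per_type,ddi_density,self_pair_prob
#'   Domain model: number of Pfam-like types, mean occurrences per type,
#'   probability that an unordered type pair is in the DDI table, and the
#'   probability that a DDI-listed type also has its self-pair.
#' @param seed Mandatory integer master seed.
#' @return A list with class `synth_params`.
#' @export
synth_params <- function(n_genes = 500L,
                         mean_protein_length = 400,
                         length_spread = 0.25,
                         min_protein_length = 150L,
                         intron_density = 6,
                         n_shuffle_events = 40L,
                         shuffled_segment_length = 60L,
                         intron_loss_rate = 0,
                         n_ss_pairs = 20L,
                         baseline_degree = 4,
                         es_degree_multiplier = 3,
                         self_prob = c(ES = 0.30, SS = 0.25, WS = 0.20),
                         n_domain_types = 60L,
                         mean_occurrences_per_type = 5,
                         ddi_density = 0.04,
                         self_pair_prob = 0.3,
                         seed) {
  if (missing(seed)) stop("synth_params() requires an explicit seed")
  stopifnot(intron_loss_rate >= 0, intron_loss_rate <= 1,
            es_degree_multiplier > 0,
            all(self_prob >= 0), all(self_prob <= 1),
            2L * (n_shuffle_events + n_ss_pairs) <= n_genes)
  structure(as.list(environment()), class = "synth_params")
}

# deterministic per-stage substream seeds derived from the master seed
stage_seed <- function(params, stage) {
  offsets <- c(genome = 101L, events = 211L, network = 307L,
               domains = 401L, ddi = 503L)
  (params$seed * 7919L + offsets[[stage]]) %% 2147483647L
}

#' Generate a random genome of gene models
#'
#' Protein sequences are uniform random over the 20 amino-acid alphabet;
#' lengths are lognormal (clipped below); intron junctions are placed
#' uniformly along each CDS at the configured expected density
#' (Poisson-distributed counts). Deterministic under the master seed.
#'
#' @param params A [synth_params()].
#' @return A named list of `gene_model`s (`g0001`, `g0002`, ...).
#' @export
generate_genome <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(stage_seed(params, "genome"))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  n <- params$n_genes
  lens <- pmax(params$min_protein_length,
               round(stats::rlnorm(n, log(params$mean_protein_length),
                                   params$length_spread)))
  genes <- vector("list", n)
  ids <- sprintf("g%04d", seq_len(n))
  for (i in seq_len(n)) {
    seq_i <- paste(sample(aa, lens[i], replace = TRUE), collapse = "")
    cds <- 3L * lens[i]
    k <- stats::rpois(1L, params$intron_density * cds / 1000)
    j <- if (k > 0L) sort(sample.int(cds - 1L, min(k, cds - 1L))) else integer(0)
    genes[[i]] <- gene_model(ids[i], seq_i, j, species = "synthetic")
  }
  names(genes) <- ids
  genes
}

#' Plant exon-shuffling and sequence-shuffling events in a genome
#'
#' For each shuffling event a donor segment of
#' `params$shuffled_segment_length` residues is copied over a random
#' interior position of a distinct acceptor gene, and intron junctions
#' are planted at the four segment-border junctions (both genes); each
#' planted junction is then independently deleted with probability
#' `params$intron_loss_rate`. Truth-SS pairs receive the copied segment
#' with no planted introns, and any background junction falling in the
#' four border flanking windows is removed, so these pairs carry
#' sequence-level homology without intron support by construction. All
#' participating genes are distinct.
#'
#' @param genome Named list of `gene_model`s from [generate_genome()].
#' @param params A [synth_params()].
#' @param window_exterior,window_interior Flanking-window extents used
#'   when scrubbing SS-pair backgrounds (defaults 20, 3, matching the
#'   classifier).
#' @return A list with `genome` (modified models) and `truth`
#'   (data.frame `gene_a, gene_b, type, a_start, a_end, b_start, b_end`).
#' @export
plant_shuffling_events <- function(genome, params,
                                   window_exterior = 20L,
                                   window_interior = 3L) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(stage_seed(params, "events"))
  seg <- params$shuffled_segment_length
  n_ev <- params$n_shuffle_events; n_ss <- params$n_ss_pairs
  ids <- names(genome)
  lens <- protein_lengths_of(genome)
  eligible <- ids[lens >= seg + 4L]
  if (length(eligible) < 2L * (n_ev + n_ss))
    stop("genome too small for the requested event count")
  picked <- sample(eligible, 2L * (n_ev + n_ss))
  truth <- vector("list", n_ev + n_ss)
  for (e in seq_len(n_ev + n_ss)) {
    is_es <- e <= n_ev
    donor <- picked[2L * e - 1L]; acceptor <- picked[2L * e]
    dl <- lens[[donor]]; al <- lens[[acceptor]]
    # interior placement keeps all four border junctions internal to the CDS
    ds <- sample(2:(dl - seg), 1L)
    as_ <- sample(2:(al - seg), 1L)
    dseq <- substr(genome[[donor]]$protein_seq, ds, ds + seg - 1L)
    aseq <- genome[[acceptor]]$protein_seq
    substr(aseq, as_, as_ + seg - 1L) <- dseq
    junc_at <- function(start_res) {
      nt <- residue_span_to_nt(start_res, start_res + seg - 1L)
      c(nt[1L, "nt_start"] - 1L, nt[1L, "nt_end"])
    }
    dj <- junc_at(ds); aj <- junc_at(as_)
    upd <- function(model, new_seq, borders) {
      j <- model$intron_junctions
      if (is_es) {
        keep <- stats::runif(2L) >= params$intron_loss_rate
        j <- union(j, borders[keep])
      } else {
        # scrub both flanking windows of each border
        lo <- c(borders[1L] - window_exterior, borders[2L] - window_interior)
        hi <- c(borders[1L] + window_interior, borders[2L] + window_exterior)
        drop <- (j >= lo[1L] & j <= hi[1L]) | (j >= lo[2L] & j <= hi[2L])
        j <- j[!drop]
      }
      gene_model(model$gene_id, new_seq, sort(j), species = model$species)
    }
    genome[[donor]] <- upd(genome[[donor]], genome[[donor]]$protein_seq, dj)
    genome[[acceptor]] <- upd(genome[[acceptor]], aseq, aj)
    truth[[e]] <- data.frame(
      gene_a = donor, gene_b = acceptor,
      type = if (is_es) "ES" else "SS",
      a_start = ds, a_end = ds + seg - 1L,
      b_start = as_, b_end = as_ + seg - 1L,
      stringsAsFactors = FALSE)
  }
  list(genome = genome, truth = do.call(rbind, truth))
}

#' Alignment hits for a synthetic genome's planted pairs
#'
#' Either reconstructs the hits directly from the planted segment
#' coordinates (`method = "coordinates"`, exact and instantaneous) or
#' runs the package's Smith-Waterman front end on each truth pair
#' (`method = "align"`), exercising the real homology path.
#'
#' @param genome Modified genome from [plant_shuffling_events()].
#' @param truth Truth data.frame from [plant_shuffling_events()].
#' @param method `"coordinates"` or `"align"`.
#' @return A hits data.frame (see [read_blast_tab()]).
#' @export
synth_alignment_hits <- function(genome, truth,
                                 method = c("coordinates", "align")) {
  method <- match.arg(method)
  if (method == "coordinates") {
    seg_nt <- 3L * (truth$a_end - truth$a_start + 1L)
    return(data.frame(
      query_id = truth$gene_a, subject_id = truth$gene_b,
      q_start = truth$a_start, q_end = truth$a_end,
      s_start = truth$b_start, s_end = truth$b_end,
      evalue = 1e-30, bitscore = as.numeric(2L * seg_nt),
      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
    h <- local_align(genome[[truth$gene_a[i]]]$protein_seq,
                     genome[[truth$gene_b[i]]]$protein_seq,
                     id_a = truth$gene_a[i], id_b = truth$gene_b[i])
    h$score <- NULL
    h
  }))
}

#' Generate a degree-structured PPI network over a gene set
#'
#' Expected-degree (Chung-Lu style) random graph: gene i's weight is
#' `baseline_degree`, multiplied by `es_degree_multiplier` when its
#' category is ES; the probability of edge (i, j) is
#' `min(1, w_i * w_j / sum(w))`. Self-interaction flags are drawn per
#' category with `params$self_prob`. Zero-degree vertices without a
#' self-interaction flag are absent from the result (as in any built
#' network).
#'
#' @param genome Named list of `gene_model`s (supplies ids and protein
#'   lengths).
#' @param categories Named character vector (or factor) of ES/SS/WS
#'   labels covering the genome; truth labels or classifier calls.
#' @param params A [synth_params()].
#' @param seed_offset Optional extra offset added to the network
#'   substream seed, for replicated network draws over one genome.
#' @return A `ppi_network` with category-annotated vertices.
#' @export
generate_network <- function(genome, categories, params, seed_offset = 0L) {
  stopifnot(inherits(params, "synth_params"))
  set.seed((stage_seed(params, "network") + as.integer(seed_offset)) %%
             2147483647L)
  ids <- names(genome)
  cat_v <- as.character(categories[ids])
  cat_v[is.na(cat_v)] <- "WS"
  w <- params$baseline_degree *
    ifelse(cat_v == "ES", params$es_degree_multiplier, 1)
  if (any(w > length(ids) - 1L))
    stop("expected degree exceeds n_genes - 1")
  n <- length(ids)
  S <- sum(w)
  i_idx <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j_idx <- sequence((n - 1L):1L, from = 2L:n)
  p <- pmin(1, w[i_idx] * w[j_idx] / S)
  hit <- stats::runif(length(p)) < p
  edges <- data.frame(gene_a = ids[i_idx[hit]], gene_b = ids[j_idx[hit]],
                      stringsAsFactors = FALSE)
  self_set <- ids[stats::runif(n) < params$self_prob[cat_v]]
  net <- new_ppi_network(edges, self_set, protein_lengths_of(genome),
                         category = stats::setNames(cat_v, ids))
  net
}

#' Generate domain occurrences and a DDI table for a synthetic genome
#'
#' Each Pfam-like domain type receives a Poisson number of occurrences
#' (at least one), placed at random positions in random genes; the DDI
#' table includes each unordered type pair independently with
#' `ddi_density` and each type's self-pair with `self_pair_prob`.
#'
#' @param genome Named list of `gene_model`s.
#' @param params A [synth_params()].
#' @return A list with `occurrences` (data.frame as from
#'   [read_domain_hits()]) and `ddi` (data.frame as from [read_ddi()]).
#' @export
generate_domains <- function(genome, params) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(stage_seed(params, "domains"))
  ids <- names(genome)
  lens <- protein_lengths_of(genome)
  types <- sprintf("PFS%04d", seq_len(params$n_domain_types))
  occ <- list()
  for (t in types) {
    k <- 1L + stats::rpois(1L, params$mean_occurrences_per_type - 1)
    for (q in seq_len(k)) {
      g <- sample(ids, 1L)
      dl <- min(sample(30:90, 1L), lens[[g]] - 2L)
      st <- sample.int(lens[[g]] - dl, 1L)
      occ[[length(occ) + 1L]] <- data.frame(
        gene_id = g, domain_type = t, start_res = st,
        end_res = st + dl - 1L, evalue = stats::runif(1L, 1e-10, 1e-3),
        stringsAsFactors = FALSE)
    }
  }
  occurrences <- do.call(rbind, occ)
  occurrences <- occurrences[order(occurrences$gene_id,
                                   occurrences$start_res), ]
  rownames(occurrences) <- NULL
  set.seed(stage_seed(params, "ddi"))
  nt <- length(types)
  i_idx <- rep(seq_len(nt - 1L), times = (nt - 1L):1L)
  j_idx <- sequence((nt - 1L):1L, from = 2L:nt)
  keep <- stats::runif(length(i_idx)) < params$ddi_density
  pairs <- data.frame(domain_a = types[i_idx[keep]],
                      domain_b = types[j_idx[keep]],
                      stringsAsFactors = FALSE)
  listed <- unique(c(pairs$domain_a, pairs$domain_b))
  selfers <- listed[stats::runif(length(listed)) < params$self_pair_prob]
  ddi <- ddi_table(c(pairs$domain_a, selfers), c(pairs$domain_b, selfers))
  list(occurrences = occurrences, ddi = ddi)
}

#' Generate a complete synthetic analysis bundle
#'
#' Runs every generator stage in order and returns all intermediate
#' products: the planted genome, truth labels (per gene and per pair),
#' alignment hits, a degree-structured PPI network and domain
#' annotations.
#'
#' @param params A [synth_params()].
#' @param hits_method Passed to [synth_alignment_hits()].
#' @return A list with elements `params, genome, truth, truth_categories,
#'   hits, network, domains`.
#' @export
simulate_bundle <- function(params, hits_method = "coordinates") {
  genome0 <- generate_genome(params)
  planted <- plant_shuffling_events(genome0, params)
  truth <- planted$truth
  cats <- stats::setNames(rep("WS", length(planted$genome)),
                          names(planted$genome))
  ss_genes <- unique(c(truth$gene_a[truth$type == "SS"],
                       truth$gene_b[truth$type == "SS"]))
  es_genes <- unique(c(truth$gene_a[truth$type == "ES"],
                       truth$gene_b[truth$type == "ES"]))
  cats[ss_genes] <- "SS"; cats[es_genes] <- "ES"
  hits <- synth_alignment_hits(planted$genome, truth, method = hits_method)
  network <- generate_network(planted$genome, cats, params)
  domains <- generate_domains(planted$genome, params)
  list(params = params, genome = planted$genome, truth = truth,
       truth_categories = cats, hits = hits, network = network,
       domains = domains)
}

#' Write a synthetic bundle in the package's on-disk input formats
#'
#' Emits exactly the files the readers consume: protein FASTA, intron
#' table TSV, BLAST-tabular hits, edge TSV of interactions, domain-hit
#' TSV, DDI TSV and a truth TSV.
#'
#' @param bundle A list from [simulate_bundle()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of paths written.
#' @export
write_synthetic_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "proteins.fasta"),
             introns = file.path(dir, "introns.tsv"),
             hits = file.path(dir, "alignments.blast6"),
             edges = file.path(dir, "interactions.tsv"),
             domains = file.path(dir, "domain_hits.tsv"),
             ddi = file.path(dir, "ddi.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_genes(bundle$genome, paths[["fasta"]], paths[["introns"]])
  write_blast_tab(bundle$hits, paths[["hits"]])
  e <- bundle$network$edges
  v <- bundle$network$vertices
  self_rows <- v$gene_id[v$self_interacting]
  writeLines(c(paste(e$gene_a, e$gene_b, "two hybrid",
                     "physical association", "synthetic", sep = "\t"),
               paste(self_rows, self_rows, "two hybrid",
                     "physical association", "synthetic", sep = "\t")),
             paths[["edges"]])
  occ <- bundle$domains$occurrences
  writeLines(sprintf("%s\t%s\t%d\t%d\t%.3g", occ$gene_id, occ$domain_type,
                     occ$start_res, occ$end_res, occ$evalue),
             paths[["domains"]])
  writeLines(paste(bundle$domains$ddi$domain_a, bundle$domains$ddi$domain_b,
                   sep = "\t"), paths[["ddi"]])
  utils::write.table(bundle$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
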