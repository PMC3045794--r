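# Independent brute-force oracles. These deliberately share no code with
# the implementation paths they check.

# Full Gotoh dynamic-programming matrices for local alignment with affine
# gaps (a gap of length L costs gap_open + L * gap_ext). Returns the
# optimal local score (empty alignment allowed, so never negative).
sw_score_oracle <- function(a, b, mat, gap_open = 11, gap_ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(0, n + 1L, m + 1L)
  Ix <- matrix(NEG, n + 1L, m + 1L)  # gap in b (vertical)
  Iy <- matrix(NEG, n + 1L, m + 1L)  # gap in a (horizontal)
  best <- 0
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      s <- mat[av[i - 1L], bv[j - 1L]]
      M[i, j] <- max(0, M[i - 1L, j - 1L] + s, Ix[i - 1L, j - 1L] + s,
                     Iy[i - 1L, j - 1L] + s)
      Ix[i, j] <- max(M[i - 1L, j] - gap_open - gap_ext,
                      Ix[i - 1L, j] - gap_ext)
      Iy[i, j] <- max(M[i, j - 1L] - gap_open - gap_ext,
                      Iy[i, j - 1L] - gap_ext)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

# Exact two-sided Mann-Whitney p by exhaustive enumeration of all rank
# assignments: for group sizes (nx, ny) returns the full U distribution.
mw_u_distribution <- function(nx, ny) {
  ranks <- seq_len(nx + ny)
  picks <- utils::combn(nx + ny, nx)
  apply(picks, 2L, function(ix) sum(ix) - nx * (nx + 1L) / 2L)
}

mw_exact_p_oracle <- function(u, u_dist) {
  mu <- mean(u_dist)
  tail <- if (u > mu) mean(u_dist >= u) else mean(u_dist <= u)
  min(2 * tail, 1)
}

# Connected components by explicit breadth-first traversal over an
# adjacency list.
components_oracle <- function(genes, pairs) {
  adj <- stats::setNames(vector("list", length(genes)), genes)
  for (p in pairs) {
    adj[[p[1L]]] <- c(adj[[p[1L]]], p[2L])
    adj[[p[2L]]] <- c(adj[[p[2L]]], p[1L])
  }
  comp <- stats::setNames(integer(length(genes)), genes)
  cur <- 0L
  for (g in genes) {
    if (comp[g] != 0L) next
    cur <- cur + 1L
    queue <- g
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (comp[v] != 0L) next
      comp[v] <- cur
      queue <- c(queue, adj[[v]])
    }
  }
  comp
}

# Membership check for intron junctions in windows, junction by junction.
count_windows_oracle <- function(windows, models) {
  total <- 0L
  for (i in seq_len(nrow(windows))) {
    found <- FALSE
    for (j in models[[windows$gene_id[i]]]$intron_junctions)
      if (j >= windows$lo[i] && j <= windows$hi[i]) found <- TRUE
    total <- total + as.integer(found)
  }
  total
}
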