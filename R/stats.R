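#' Continuity-corrected chi-square for a 2x2 table
#'
#' Yates-corrected statistic
#' `n * (max(|ad - bc| - n/2, 0))^2 / (r1 * r2 * c1 * c2)` with one degree
#' of freedom. Fractional counts are accepted: the formula is well-defined
#' for the 1/k-weighted domain tables and the correction clamps at zero
#' when `|ad - bc| <= n/2`.
#'
#' @param a,b,c,d Cell counts (row-wise: a, b on row 1; c, d on row 2), or
#'   `a` may be a 2x2 matrix.
#' @return A list with `statistic`, `p_value` (1-df upper tail), `df`.
#' @examples
#' chi2_yates(328, 705, 927, 2855)$statistic  # ~21.7
#' @export
chi2_yates <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2L, 2L)))
    b <- a[1L, 2L]; c <- a[2L, 1L]; d <- a[2L, 2L]; a <- a[1L, 1L]
  }
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (any(c(r1, r2, c1, c2) == 0)) stop("zero margin in 2x2 table")
  num <- max(abs(a * d - b * c) - n / 2, 0)
  stat <- n * num^2 / (r1 * r2 * c1 * c2)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       df = 1L)
}

#' Two-sample Mann-Whitney U test
#'
#' Wraps `stats::wilcox.test`: the exact two-sided p-value (full
#' enumeration of rank assignments) is used when both samples have at
#' most `exact_max` observations and there are no ties; otherwise the
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param x,y Numeric samples (non-empty).
#' @param exact_max Largest per-sample size for the exact p (default 8).
#' @return A list with `statistic` (U for `x`), `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 8L) {
  if (!length(x) || !length(y)) stop("samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (use_exact) "exact" else "normal_approx")
}

#' Resampling-test configuration
#'
#' @param n_iter Number of null resamples (default 100000).
#' @param seed Optional integer seed applied before drawing.
#' @param stat `"arithmetic"` or `"geometric"` mean.
#' @param length_tolerance Relative protein-length tolerance for matched
#'   sampling (default 0.10).
#' @param two_sided_factor Multiplier turning the one-sided exceedance
#'   fraction into a two-sided p (default 2).
#' @return A list with class `resample_config`.
#' @export
resample_config <- function(n_iter = 100000L, seed = NULL,
                            stat = c("arithmetic", "geometric"),
                            length_tolerance = 0.10,
                            two_sided_factor = 2) {
  stat <- match.arg(stat)
  n_iter <- as.integer(n_iter)
  stopifnot(n_iter >= 1000L, length_tolerance > 0)
  structure(list(n_iter = n_iter, seed = seed, stat = stat,
                 length_tolerance = length_tolerance,
                 two_sided_factor = two_sided_factor),
            class = "resample_config")
}

stat_fun <- function(stat)
  if (stat == "geometric") function(v) exp(mean(log(v))) else mean

# shared tail logic: observed vs null distribution, doubled, capped;
# a zero exceedance count is reported as the bound 2/n_iter.
resample_p <- function(observed, nulls, reference, config) {
  upper <- observed >= reference
  exceed <- if (upper) sum(nulls >= observed) else sum(nulls <= observed)
  n_iter <- length(nulls)
  sd_null <- stats::sd(nulls)
  z <- if (sd_null > 0) (observed - mean(nulls)) / sd_null else 0
  if (exceed == 0L) {
    list(statistic = observed,
         p_value = config$two_sided_factor / n_iter, p_is_bound = TRUE,
         z_score = z, n_resamples = n_iter)
  } else {
    list(statistic = observed,
         p_value = min(config$two_sided_factor * exceed / n_iter, 1),
         p_is_bound = FALSE, z_score = z, n_resamples = n_iter)
  }
}

#' Resampling test for a difference of (arithmetic or geometric) means
#'
#' Null samples of the size of the smaller of the two sets are drawn
#' without replacement from the union of the sets; the observed statistic
#' is the mean of the smaller real set. The one-sided exceedance fraction
#' (on the side of the pooled mean where the observation falls) is
#' doubled and capped at 1; when no null sample is as extreme the p-value
#' is reported as the bound `2/n_iter` with `p_is_bound = TRUE`. The
#' z-score is the observed statistic standardized against the null
#' distribution.
#'
#' @param x,y Numeric samples (strictly positive when
#'   `config$stat == "geometric"`).
#' @param config A [resample_config()].
#' @return A list with `statistic, p_value, p_is_bound, z_score,
#'   n_resamples, method`.
#' @export
resample_mean_diff <- function(x, y, config = resample_config()) {
  stopifnot(inherits(config, "resample_config"))
  if (config$stat == "geometric" && any(c(x, y) <= 0))
    stop("geometric mean requires strictly positive values")
  if (!is.null(config$seed)) set.seed(config$seed)
  smaller <- if (length(x) <= length(y)) x else y
  pool <- c(x, y)
  f <- stat_fun(config$stat)
  m <- length(smaller); n <- length(pool)
  # log-transform once so each iteration is a plain arithmetic mean
  pv <- if (config$stat == "geometric") log(pool) else pool
  nulls <- vapply(seq_len(config$n_iter),
                  function(i) mean(pv[sample.int(n, m)]), 0)
  if (config$stat == "geometric") nulls <- exp(nulls)
  res <- resample_p(f(smaller), nulls, f(pool), config)
  res$method <- paste0("resample_", config$stat)
  res
}

#' Length-matched resampling test for mean degree
#'
#' Like [resample_mean_diff()], but each null sample is built by a
#' one-to-one correspondence with the real set: for every vertex of `x` a
#' pool vertex is drawn whose protein length lies within
#' `config$length_tolerance` (relative) of that vertex's length, without
#' replacement within a draw. This holds the null samples' length profile
#' at the real set's, removing the known length-degree confound. Vertices
#' are matched scarcest-first so draws rarely exhaust a candidate set; an
#' x vertex with no length-compatible pool candidate at all is an error
#' naming the vertex.
#'
#' @param x_vertices,pool_vertices Data.frames with columns `gene_id`,
#'   `degree`, `protein_length` (e.g. rows of a `ppi_network`'s
#'   `vertices`).
#' @param config A [resample_config()] (`stat` applies to the degree
#'   mean).
#' @return As [resample_mean_diff()].
#' @export
length_matched_resample <- function(x_vertices, pool_vertices,
                                    config = resample_config()) {
  stopifnot(inherits(config, "resample_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  f <- stat_fun(config$stat)
  xl <- x_vertices$protein_length
  pl <- pool_vertices$protein_length
  pd <- pool_vertices$degree
  candidates <- lapply(xl, function(L)
    which(abs(pl - L) <= config$length_tolerance * L))
  none <- lengths(candidates) == 0L
  if (any(none))
    stop("no length-compatible pool candidate for vertex ",
         x_vertices$gene_id[which(none)[1L]], " (length ",
         xl[which(none)[1L]], ")")
  ord <- order(lengths(candidates))
  nulls <- vapply(seq_len(config$n_iter), function(i) {
    used <- logical(length(pl))
    deg <- numeric(length(ord))
    for (k in seq_along(ord)) {
      avail <- candidates[[ord[k]]]
      avail <- avail[!used[avail]]
      if (!length(avail))
        stop("candidate set exhausted during matched draw; ",
             "increase length_tolerance or pool size")
      pick <- if (length(avail) == 1L) avail else
        avail[sample.int(length(avail), 1L)]
      used[pick] <- TRUE
      deg[k] <- pd[pick]
    }
    f(deg)
  }, 0)
  res <- resample_p(f(x_vertices$degree), nulls, f(pd), config)
  res$method <- paste0("length_matched_resample_", config$stat)
  res
}

#' Bonferroni correction
#'
#' Multiplies a p-value by the number of tests performed, capping at 1.
#'
#' @param p P-value(s).
#' @param m Number of tests (>= 1).
#' @return Adjusted p-value(s).
#' @export
bonferroni <- function(p, m) {
  stopifnot(m >= 1)
  pmin(p * m, 1)
}
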