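# Cohesive triplet/quadruple screen: pairwise Pearson correlation with
# two-sided t-test p-values, staged to avoid the full SDP x miRNA x gene
# cross-product while returning exactly the brute-force result.

#' Pearson correlation with a two-sided p-value
#'
#' Sample Pearson correlation (point-biserial when one vector is 0/1) with the
#' two-sided p-value of t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of
#' freedom; perfect correlation gives p = 0.
#'
#' @param x,y numeric vectors of equal length (n >= 4), each with nonzero
#'   variance.
#' @return Named numeric vector `c(r, p)`.
#' @export
pearson_with_pvalue <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 4L) stop("need at least 4 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance input: degenerate marker or flat expression")
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  c(r = r, p = p)
}

# Vectorized correlation + p-value over column pairs of two matrices.
# Zero-variance columns yield NA correlations, reported with p = NA so they
# can never pass a threshold.
cor_pvalue_matrices <- function(A, B) {
  n <- nrow(A)
  r <- suppressWarnings(stats::cor(A, B))
  t_stat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  p[!is.na(r) & abs(r) >= 1] <- 0
  list(r = r, p = p, n = n)
}

#' Screen for cohesive SDP-miRNA-gene triplets
#'
#' Returns every (SDP, miRNA, gene) triplet whose three pairwise Pearson
#' correlations are all significant at `p_threshold`. The search prunes in
#' stages (SDP-miRNA pairs, then SDP-gene pairs, then miRNA-gene within
#' survivors) but is exactly equivalent to the exhaustive triple loop.
#'
#' @param dataset an [align_for_phenotype()] result.
#' @param p_threshold nominal two-sided p-value cutoff for the three
#'   molecular-trait correlations (default 1e-3).
#' @return Data frame with one row per cohesive triplet: ids, the three
#'   correlations `r_sm`, `r_sg`, `r_mg`, their p-values and `n_used`.
#' @export
find_cohesive_triplets <- function(dataset, p_threshold = 1e-3) {
  stopifnot(inherits(dataset, "aligned_dataset"))
  empty <- data.frame(sdp_id = character(), mirna_id = character(),
                      gene_id = character(), r_sm = numeric(),
                      r_sg = numeric(), r_mg = numeric(), p_sm = numeric(),
                      p_sg = numeric(), p_mg = numeric(),
                      n_used = integer(), stringsAsFactors = FALSE)
  S <- t(dataset$sdps$patterns)
  M <- dataset$mirna$values
  G <- dataset$genes$values
  if (!ncol(S) || !ncol(M) || !ncol(G)) return(empty)
  sm <- cor_pvalue_matrices(S, M)
  sg <- cor_pvalue_matrices(S, G)
  pass_sm <- !is.na(sm$p) & sm$p < p_threshold
  pass_sg <- !is.na(sg$p) & sg$p < p_threshold
  live_sdp <- which(rowSums(pass_sm) > 0L & rowSums(pass_sg) > 0L)
  if (!length(live_sdp)) return(empty)
  live_m <- which(colSums(pass_sm[live_sdp, , drop = FALSE]) > 0L)
  live_g <- which(colSums(pass_sg[live_sdp, , drop = FALSE]) > 0L)
  mg <- cor_pvalue_matrices(M[, live_m, drop = FALSE],
                            G[, live_g, drop = FALSE])
  pass_mg <- !is.na(mg$p) & mg$p < p_threshold
  rows <- vector("list", length(live_sdp))
  for (i in seq_along(live_sdp)) {
    k <- live_sdp[i]
    ms <- live_m[pass_sm[k, live_m]]
    gs <- live_g[pass_sg[k, live_g]]
    if (!length(ms) || !length(gs)) next
    mi <- match(ms, live_m); gi <- match(gs, live_g)
    ok <- which(pass_mg[mi, gi, drop = FALSE], arr.ind = TRUE)
    if (!nrow(ok)) next
    m_idx <- ms[ok[, 1L]]; g_idx <- gs[ok[, 2L]]
    rows[[i]] <- data.frame(
      sdp_id = colnames(S)[k],
      mirna_id = colnames(M)[m_idx],
      gene_id = colnames(G)[g_idx],
      r_sm = sm$r[k, m_idx], r_sg = sg$r[k, g_idx],
      r_mg = mg$r[cbind(match(m_idx, live_m), match(g_idx, live_g))],
      p_sm = sm$p[k, m_idx], p_sg = sg$p[k, g_idx],
      p_mg = mg$p[cbind(match(m_idx, live_m), match(g_idx, live_g))],
      n_used = dataset$n, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out)) return(empty)
  out <- out[order(out$sdp_id, out$mirna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extend cohesive triplets to phenotype quadruples
#'
#' Keeps the triplets whose SDP, miRNA and gene are each significantly
#' correlated with the dataset's phenotype at `p_threshold`.
#'
#' @param triplets output of [find_cohesive_triplets()] computed on the same
#'   strain alignment.
#' @param dataset the [align_for_phenotype()] result carrying the phenotype.
#' @param p_threshold nominal two-sided p-value cutoff for the three
#'   phenotype correlations (default 0.05).
#' @return Data frame of cohesive quadruples: the triplet columns plus
#'   `phenotype_id`, `r_sp`, `r_mp`, `r_gp` and their p-values.
#' @export
extend_to_quadruples <- function(triplets, dataset, p_threshold = 0.05) {
  stopifnot(inherits(dataset, "aligned_dataset"))
  empty <- cbind(triplets[0, , drop = FALSE],
                 data.frame(phenotype_id = character(), r_sp = numeric(),
                            r_mp = numeric(), r_gp = numeric(),
                            p_sp = numeric(), p_mp = numeric(),
                            p_gp = numeric(), stringsAsFactors = FALSE))
  if (!nrow(triplets)) return(empty)
  y <- matrix(dataset$phenotype, ncol = 1L,
              dimnames = list(NULL, dataset$phenotype_id))
  corr_with_y <- function(ids, mat) {
    u <- unique(ids)
    cp <- cor_pvalue_matrices(mat[, u, drop = FALSE], y)
    list(r = cp$r[match(ids, u), 1L], p = cp$p[match(ids, u), 1L])
  }
  sp <- corr_with_y(triplets$sdp_id, t(dataset$sdps$patterns))
  mp <- corr_with_y(triplets$mirna_id, dataset$mirna$values)
  gp <- corr_with_y(triplets$gene_id, dataset$genes$values)
  keep <- !is.na(sp$p) & !is.na(mp$p) & !is.na(gp$p) &
    sp$p < p_threshold & mp$p < p_threshold & gp$p < p_threshold
  out <- cbind(triplets[keep, , drop = FALSE],
               data.frame(phenotype_id = rep(dataset$phenotype_id, sum(keep)),
                          r_sp = sp$r[keep], r_mp = mp$r[keep],
                          r_gp = gp$r[keep], p_sp = sp$p[keep],
                          p_mp = mp$p[keep], p_gp = gp$p[keep],
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
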