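# In-code fixtures shared across test files.

# sdp_table built directly from a strains x SDPs 0/1 matrix
make_sdp_table <- function(S, pos = NULL) {
  sdp_ids <- colnames(S)
  strains <- rownames(S)
  if (is.null(pos))
    pos <- data.frame(sdp_id = sdp_ids, chrom = "1",
                      start = seq_along(sdp_ids) * 1e6,
                      end = seq_along(sdp_ids) * 1e6,
                      stringsAsFactors = FALSE)
  structure(list(
    sdp_ids = sdp_ids, strain_ids = strains, patterns = t(S),
    members = stats::setNames(as.list(paste0("snp_", sdp_ids)), sdp_ids),
    span = pos,
    span_by_chrom = stats::setNames(lapply(seq_along(sdp_ids), function(i)
      data.frame(chrom = pos$chrom[i], start = pos$start[i],
                 end = pos$end[i], n_snps = 1L)), sdp_ids)),
    class = "sdp_table")
}

# aligned dataset from raw matrices (rownames = strains everywhere)
aligned_from_matrices <- function(S, M, G, y, phenotype_id = "pheno",
                                  pos = NULL) {
  pt <- phenotype_table(matrix(y, ncol = 1,
                               dimnames = list(rownames(S), phenotype_id)))
  align_for_phenotype(make_sdp_table(S, pos), expression_matrix(M),
                      expression_matrix(G), pt, phenotype_id)
}

# random screening panel with one strong planted triplet (index 1,1,1)
make_screen_panel <- function(seed, n = 30, n_sdp = 6, n_mir = 5, n_gene = 5) {
  set.seed(seed)
  strains <- sprintf("s%02d", seq_len(n))
  S <- matrix(rbinom(n * n_sdp, 1, 0.5), n,
              dimnames = list(strains, sprintf("sdp%02d", seq_len(n_sdp))))
  M <- matrix(rnorm(n * n_mir), n,
              dimnames = list(strains, sprintf("mir%02d", seq_len(n_mir))))
  G <- matrix(rnorm(n * n_gene), n,
              dimnames = list(strains, sprintf("gene%02d", seq_len(n_gene))))
  M[, 1] <- 1.6 * S[, 1] + rnorm(n, 0, 0.6)
  G[, 1] <- 0.9 * M[, 1] + rnorm(n, 0, sqrt(0.19))
  y <- -0.7 * G[, 1] + rnorm(n, 0, sqrt(0.51))
  aligned_from_matrices(S, M, G, y)
}

# exhaustive triple loop over the full cross-product (independent of the
# staged screen)
brute_force_triplets <- function(dataset, p_threshold) {
  S <- t(dataset$sdps$patterns)
  M <- dataset$mirna$values
  G <- dataset$genes$values
  rows <- list()
  for (s in colnames(S)) for (m in colnames(M)) for (g in colnames(G)) {
    sm <- pearson_with_pvalue(S[, s], M[, m])
    sg <- pearson_with_pvalue(S[, s], G[, g])
    mg <- pearson_with_pvalue(M[, m], G[, g])
    if (sm["p"] < p_threshold && sg["p"] < p_threshold &&
        mg["p"] < p_threshold)
      rows[[length(rows) + 1]] <- data.frame(
        sdp_id = s, mirna_id = m, gene_id = g,
        r_sm = unname(sm["r"]), r_sg = unname(sg["r"]),
        r_mg = unname(mg["r"]), p_sm = unname(sm["p"]),
        p_sg = unname(sg["p"]), p_mg = unname(mg["p"]),
        n_used = dataset$n, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out <- out[order(out$sdp_id, out$mirna_id, out$gene_id), ]
  rownames(out) <- NULL
  out
}

# strains x 4 data matrix and roles from a simulated quadruple
chain_data <- function(seed, scenario = "full_mediation", n_strains = 60) {
  spec <- scenario_spec(scenario, n_strains = n_strains, seed = seed)
  sim <- simulate_quadruple(spec)
  nodes <- c("SDP_1", "miR_1", "Gene_1", "phenotype")
  dat <- cbind(t(sim$dataset$sdps$patterns),
               sim$dataset$mirna$values,
               sim$dataset$genes$values,
               phenotype = sim$dataset$phenotype)
  colnames(dat) <- nodes
  list(dat = dat,
       roles = node_roles("SDP_1", c("miR_1", "Gene_1"), "phenotype"),
       sim = sim)
}

# random linear-Gaussian dataset over 3-4 role-typed nodes with a random
# admissible generating DAG (for optimizer-vs-oracle comparisons)
make_small_bn_dataset <- function(seed, n = 60) {
  set.seed(seed)
  k_inter <- sample(1:2, 1)
  inter <- sort(sample(c("miR_a", "Gene_b", "Gene_a", "miR_b"), k_inter))
  roles <- node_roles("SDP_x", inter, "pheno")
  nodes <- names(roles)
  dat <- matrix(NA_real_, n, length(nodes), dimnames = list(NULL, nodes))
  dat[, "SDP_x"] <- rbinom(n, 1, 0.5)
  ord <- c("SDP_x", sample(inter), "pheno")
  for (i in 2:length(ord)) {
    v <- ord[i]
    pa <- ord[seq_len(i - 1)][runif(i - 1) < 0.5]
    mu <- rep(0, n)
    for (p in pa)
      mu <- mu + runif(1, 0.4, 0.9) * sign(runif(1) - 0.3) *
        as.vector(scale(dat[, p]))
    dat[, v] <- mu + rnorm(n)
  }
  list(dat = dat, roles = roles)
}

# independent per-structure rescoring via lm()/logLik() (oracle route)
oracle_score <- function(structure, data) {
  df <- as.data.frame(data)
  ll <- 0
  d <- 0
  for (v in structure$nodes) {
    if (structure$roles[[v]] == "sdp_binary_root") {
      x <- df[[v]]
      p <- mean(x)
      ll <- ll + sum(x * log(p) + (1 - x) * log(1 - p))
      d <- d + 1
    } else {
      pa <- structure$edges[structure$edges[, 2] == v, 1]
      form <- if (length(pa))
        stats::reformulate(sprintf("`%s`", pa), sprintf("`%s`", v))
      else stats::reformulate("1", sprintf("`%s`", v))
      fit <- stats::lm(form, data = df)
      ll <- ll + as.numeric(stats::logLik(fit))
      d <- d + length(pa) + 2
    }
  }
  ll - d / 2 * log(nrow(df))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
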