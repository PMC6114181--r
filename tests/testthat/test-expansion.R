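fake_decisions <- function(sdp_ids, phenotype = "pheno", gene_pass = TRUE) {
  data.frame(sdp_id = sdp_ids,
             mirna_id = paste0("m_", sdp_ids),
             gene_id = paste0("g_", sdp_ids),
             phenotype_id = phenotype,
             mediation_pass = TRUE,
             gene_pass = gene_pass, stringsAsFactors = FALSE)
}

sdp_table_at <- function(mids, chrom = rep("1", length(mids))) {
  ids <- sprintf("sdp%d", seq_along(mids))
  S <- matrix(0, 4, length(ids), dimnames = list(paste0("s", 1:4), ids))
  make_sdp_table(S, pos = data.frame(sdp_id = ids, chrom = chrom,
                                     start = mids, end = mids,
                                     stringsAsFactors = FALSE))
}

test_that("locus grouping chains SDPs within the window by single linkage", {
  # 10 Mb and 45 Mb on one chromosome: 35 Mb gap -> one group
  g <- group_by_locus(fake_decisions(c("sdp1", "sdp2")),
                      sdp_table_at(c(10e6, 45e6)))
  expect_length(g, 1L)
  expect_setequal(g[[1]]$sdp_ids, c("sdp1", "sdp2"))

  # same positions on different chromosomes -> two groups
  g2 <- group_by_locus(fake_decisions(c("sdp1", "sdp2")),
                       sdp_table_at(c(10e6, 45e6), chrom = c("1", "2")))
  expect_length(g2, 2L)

  # 0 / 35 / 70 Mb: chained into one group although 0 and 70 are 70 Mb apart
  g3 <- group_by_locus(fake_decisions(c("sdp1", "sdp2", "sdp3")),
                       sdp_table_at(c(0, 35e6, 70e6)))
  expect_length(g3, 1L)
  expect_setequal(g3[[1]]$sdp_ids, c("sdp1", "sdp2", "sdp3"))

  # a gap beyond the window splits the locus
  g4 <- group_by_locus(fake_decisions(c("sdp1", "sdp2")),
                       sdp_table_at(c(10e6, 55e6)))
  expect_length(g4, 2L)

  # genes enter the node set only when the gene step passed
  g5 <- group_by_locus(fake_decisions(c("sdp1", "sdp2"),
                                      gene_pass = c(TRUE, FALSE)),
                       sdp_table_at(c(10e6, 20e6)))
  expect_setequal(g5[[1]]$mirna_ids, c("m_sdp1", "m_sdp2"))
  expect_identical(g5[[1]]$gene_ids, "g_sdp1")

  # nothing passes -> nothing to group; grouping ignores row order
  none <- fake_decisions("sdp1")
  none$mediation_pass <- FALSE
  expect_length(group_by_locus(none, sdp_table_at(10e6)), 0L)
  d <- fake_decisions(c("sdp1", "sdp2", "sdp3"))
  t1 <- group_by_locus(d, sdp_table_at(c(0, 35e6, 70e6)))
  t2 <- group_by_locus(d[3:1, ], sdp_table_at(c(0, 35e6, 70e6)))
  expect_equal(t1, t2)
})

test_that("hill-climbing finds the exhaustive optimum on small instances", {
  agree <- 0L
  for (seed in 1:10) {
    x <- make_small_bn_dataset(seed)
    space <- mirmednet:::structure_space(x$roles)
    exh <- max(mirmednet:::score_structure_space(space, x$dat))
    hc <- hill_climb(x$dat, x$roles)
    expect_true(attr(hc, "converged"))
    if (abs(hc$bic - exh) < 1e-6) agree <- agree + 1L
  }
  expect_gte(agree, 9L)
})

test_that("the exhaustive optimum is a fixed point of hill-climbing", {
  x <- chain_data(41)
  space <- mirmednet:::structure_space(x$roles)
  bic <- mirmednet:::score_structure_space(space, x$dat)
  best <- space$structures[[mirmednet:::pick_best_structure(space, bic)]]
  hc <- hill_climb(x$dat, x$roles, start = best)
  expect_equal(hc$bic, max(bic), tolerance = 1e-10)
  expect_identical(mirmednet:::structure_space(x$roles)$edge_keys[[1]] == "",
                   TRUE) # sanity: space includes the empty graph
})

test_that("BIC suppresses edges between independent nodes", {
  set.seed(61)
  total_edges <- 0L
  for (i in 1:30) {
    n <- 60
    dat <- cbind(S = rbinom(n, 1, 0.5), M = rnorm(n), G = rnorm(n),
                 P = rnorm(n))
    hc <- hill_climb(dat, node_roles("S", c("M", "G"), "P"))
    total_edges <- total_edges + nrow(hc$structure$edges)
  }
  expect_lt(total_edges / 30, 1)
})

test_that("the retention rule is strict majority for presence and direction", {
  stats_df <- data.frame(
    node_a = c("A", "A", "B"), node_b = c("B", "C", "C"),
    n_present = c(250L, 251L, 400L),
    n_a_to_b = c(250L, 150L, 200L),
    n_b_to_a = c(0L, 101L, 200L))
  kept <- retain_averaged_edges(stats_df, n_boot = 500)
  # 250/500 is not > 50%: dropped despite a unanimous direction
  expect_false(any(kept$from == "A" & kept$to == "B"))
  # 251/500 present and 150/251 in the winning direction: retained
  expect_true(any(kept$from == "A" & kept$to == "C"))
  # a 200/200 direction tie is not > 50% in either direction: dropped
  expect_false(any((kept$from == "B" & kept$to == "C") |
                     (kept$from == "C" & kept$to == "B")))

  # unconditional denominator: 150/500 direction support fails
  kept2 <- retain_averaged_edges(stats_df, n_boot = 500,
                                 direction_denominator = "all_bootstraps")
  expect_identical(nrow(kept2), 0L)
})

test_that("cycle-closing retained edges are skipped in presence order", {
  stats_df <- data.frame(
    node_a = c("A", "B", "A"), node_b = c("B", "C", "C"),
    n_present = c(490L, 480L, 300L),
    n_a_to_b = c(490L, 480L, 0L),
    n_b_to_a = c(0L, 0L, 300L))
  expect_warning(
    kept <- retain_averaged_edges(stats_df, n_boot = 500,
                                  nodes = c("A", "B", "C")),
    "cycle")
  expect_identical(nrow(kept), 2L) # A->B and B->C survive, C->A is skipped
  expect_false(any(kept$from == "C"))
})

test_that("bootstrap averaging is deterministic and internally consistent", {
  x <- chain_data(43)
  avg <- bootstrap_average(x$dat, x$roles, n_boot = 60, seed = 17)
  avg2 <- bootstrap_average(x$dat, x$roles, n_boot = 60, seed = 17)
  expect_identical(avg$edge_stats, avg2$edge_stats)
  expect_identical(avg$retained_edges, avg2$retained_edges)

  es <- avg$edge_stats
  expect_true(all(es$n_a_to_b + es$n_b_to_a == es$n_present))
  expect_true(all(es$presence_freq >= 0 & es$presence_freq <= 1))
  expect_true(all(avg$retained_edges$presence_freq > 0.5))
  expect_true(all(avg$retained_edges$direction_freq > 0.5))

  # retained graph is a subgraph of the threshold-passing pairs
  pairs_ok <- es[es$presence_freq > 0.5, c("node_a", "node_b")]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  expect_true(all(key(avg$retained_edges$from, avg$retained_edges$to) %in%
                    key(pairs_ok$node_a, pairs_ok$node_b)))

  # strong chain edges are recovered
  got <- paste(avg$retained_edges$from, avg$retained_edges$to, sep = ">")
  expect_true(all(c("SDP_1>miR_1", "miR_1>Gene_1", "Gene_1>phenotype") %in%
                    got))
  expect_s3_class(as_network_structure(avg), "network_structure")
})

test_that("hill-climbing and exhaustive bootstrap routes agree on frequencies", {
  x <- chain_data(44)
  a <- bootstrap_average(x$dat, x$roles, n_boot = 40, seed = 5,
                         exhaustive_max_nodes = 5)
  b <- bootstrap_average(x$dat, x$roles, n_boot = 40, seed = 5,
                         exhaustive_max_nodes = 0) # force hill-climbing
  # same resamples; the chain edges should be found by both routes
  for (e in c("SDP_1>miR_1", "miR_1>Gene_1", "Gene_1>phenotype")) {
    fa <- a$retained_edges[paste(a$retained_edges$from,
                                 a$retained_edges$to, sep = ">") == e, ]
    fb <- b$retained_edges[paste(b$retained_edges$from,
                                 b$retained_edges$to, sep = ">") == e, ]
    expect_identical(nrow(fa), 1L)
    expect_identical(nrow(fb), 1L)
    expect_lt(abs(fa$presence_freq - fb$presence_freq), 0.15)
  }
})
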