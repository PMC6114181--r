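# brute-force enumeration oracle: all directed graphs over the node set,
# filtered by the role constraints and acyclicity (igraph)
brute_force_structures <- function(roles) {
  nodes <- names(roles)
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- list()
  for (mask in 0:(2^nrow(pairs) - 1)) {
    sel <- pairs[bitwAnd(mask, 2^(seq_len(nrow(pairs)) - 1)) > 0, ,
                 drop = FALSE]
    ok <- TRUE
    for (i in seq_len(nrow(sel))) {
      if (roles[[sel$from[i]]] == "continuous_phenotype" ||
          roles[[sel$to[i]]] == "sdp_binary_root") { ok <- FALSE; break }
    }
    if (!ok) next
    g <- igraph::graph_from_data_frame(sel, directed = TRUE, vertices = nodes)
    if (!igraph::is_dag(g)) next
    key <- paste(sort(paste(sel$from, sel$to, sep = ">")), collapse = ";")
    keep[[length(keep) + 1]] <- key
  }
  unlist(keep)
}

edge_key <- function(s) {
  if (!nrow(s$edges)) return("")
  paste(sort(paste(s$edges[, 1], s$edges[, 2], sep = ">")), collapse = ";")
}

test_that("constrained enumeration matches a brute-force filter on small node sets", {
  r2 <- node_roles("S", character(), "P")
  e2 <- enumerate_constrained_structures(r2)
  expect_length(e2, 2L) # edge absent / present

  r3 <- node_roles("S", "M", "P")
  e3 <- enumerate_constrained_structures(r3)
  expect_length(e3, 8L)
  oracle <- brute_force_structures(r3)
  expect_setequal(vapply(e3, edge_key, character(1)), oracle)
  expect_false(anyDuplicated(vapply(e3, edge_key, character(1))) > 0)
})

test_that("structure validation rejects role violations and cycles", {
  roles <- node_roles("S", c("M", "G"), "P")
  expect_error(network_structure(roles, rbind(c("M", "S"))), "role")
  expect_error(network_structure(roles, rbind(c("P", "M"))), "role")
  expect_error(network_structure(roles, rbind(c("M", "G"), c("G", "M"))),
               "cycle")
  expect_silent(network_structure(roles, rbind(c("S", "M"), c("M", "G"),
                                               c("G", "P"))))
})

test_that("node log-likelihoods match closed forms", {
  # no parents, values (-1, 1): RSS = 2, ML variance 1
  f <- node_loglik_continuous(c(-1, 1))
  expect_equal(f$loglik, -(2 / 2) * (log(2 * pi * 1) + 1))
  expect_identical(f$param_count, 2L)
  expect_equal(f$params$intercept, 0)

  expect_error(node_loglik_continuous(c(0, 0, 0, 0)), "zero residual")
  x <- rnorm(20)
  expect_error(node_loglik_continuous(rnorm(20), cbind(x, x)), "singular")

  expect_equal(node_loglik_binary_root(rep(1, 7))$loglik, 0)
  expect_equal(node_loglik_binary_root(rep(c(0, 1), 5))$loglik, 10 * log(0.5))
  expect_equal(node_loglik_binary_root(c(rep(1, 3), rep(0, 7)))$loglik,
               3 * log(0.3) + 7 * log(0.7))
  expect_error(node_loglik_binary_root(c(0, 1, 2)), "0/1")
})

test_that("regression log-likelihood agrees with lm()/logLik()", {
  set.seed(55)
  for (i in 1:20) {
    n <- 30
    k <- sample(0:3, 1)
    X <- matrix(rnorm(n * max(k, 1)), n)[, seq_len(k), drop = FALSE]
    y <- rnorm(n) + if (k) X %*% runif(k, -1, 1) else 0
    got <- node_loglik_continuous(y, X)
    fit <- if (k) lm(y ~ X) else lm(y ~ 1)
    expect_equal(got$loglik, as.numeric(logLik(fit)), tolerance = 1e-8)
    expect_identical(got$param_count, k + 2L)
    expect_equal(unname(got$params$intercept), unname(coef(fit)[1]),
                 tolerance = 1e-8)
  }
})

test_that("network BIC decomposes over families and is order invariant", {
  x <- chain_data(31)
  s <- network_structure(x$roles, rbind(c("SDP_1", "miR_1"),
                                        c("miR_1", "Gene_1"),
                                        c("Gene_1", "phenotype")))
  sc <- score_network(s, x$dat)
  expect_equal(sc$bic, sc$loglik - sc$d / 2 * log(sc$n), tolerance = 1e-12)
  expect_equal(sc$bic, oracle_score(s, x$dat), tolerance = 1e-8)
  expect_identical(sc$d, 1L + 3L + 3L + 3L)

  # strain permutation and column reordering leave the score unchanged
  perm <- sample(nrow(x$dat))
  expect_equal(score_network(s, x$dat[perm, ])$bic, sc$bic, tolerance = 1e-10)
  expect_equal(score_network(s, x$dat[, c(4, 2, 1, 3)])$bic, sc$bic,
               tolerance = 1e-10)
})

test_that("adding an edge never decreases the maximized log-likelihood", {
  x <- chain_data(32)
  base <- network_structure(x$roles, rbind(c("SDP_1", "miR_1"),
                                           c("miR_1", "Gene_1"),
                                           c("Gene_1", "phenotype")))
  bigger <- network_structure(x$roles, rbind(c("SDP_1", "miR_1"),
                                             c("miR_1", "Gene_1"),
                                             c("Gene_1", "phenotype"),
                                             c("SDP_1", "phenotype")))
  expect_gte(score_network(bigger, x$dat)$loglik,
             score_network(base, x$dat)$loglik)
})

test_that("likelihood-equivalent orientations score identically", {
  # complete DAG on (SDP, M, G): both M-G orientations span the same
  # trivariate model, so the total scores must agree to rounding error
  x <- chain_data(33)
  a <- network_structure(x$roles, rbind(c("SDP_1", "miR_1"),
                                        c("SDP_1", "Gene_1"),
                                        c("miR_1", "Gene_1"),
                                        c("Gene_1", "phenotype")))
  b <- network_structure(x$roles, rbind(c("SDP_1", "miR_1"),
                                        c("SDP_1", "Gene_1"),
                                        c("Gene_1", "miR_1"),
                                        c("Gene_1", "phenotype")))
  expect_equal(score_network(a, x$dat)$bic, score_network(b, x$dat)$bic,
               tolerance = 1e-9)
})

test_that("path mediation is detected by directed reachability", {
  roles <- node_roles("S", c("M", "G"), "P")
  chain <- network_structure(roles, rbind(c("S", "M"), c("M", "P")))
  expect_true(is_mediator(chain, "S", "M", "P"))
  direct <- network_structure(roles, rbind(c("S", "P")))
  expect_false(is_mediator(direct, "S", "M", "P"))
  both <- network_structure(roles, rbind(c("S", "M"), c("M", "G"),
                                         c("G", "P"), c("S", "P")))
  expect_true(is_mediator(both, "S", "M", "P"))
  expect_true(is_mediator(both, "S", "G", "P"))
  leaf <- network_structure(roles, rbind(c("S", "M"), c("M", "G"),
                                         c("S", "P")))
  expect_false(is_mediator(leaf, "S", "M", "P")) # M has no route to P
})

test_that("the generating chain wins the 96-structure search at strong effects", {
  # structure recovery presumed by the screening procedure: standardized
  # paths 0.8/0.9/-0.7 at n = 60
  space <- mirmednet:::structure_space(
    node_roles("SDP_1", c("miR_1", "Gene_1"), "phenotype"))
  true_key <- "Gene_1>phenotype;SDP_1>miR_1;miR_1>Gene_1"
  hits <- 0L
  for (seed in 1:200) {
    x <- chain_data(seed)
    bic <- mirmednet:::score_structure_space(space, x$dat)
    best <- mirmednet:::pick_best_structure(space, bic)
    if (space$edge_keys[best] == true_key) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.7)
})
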