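# Node role labels used throughout. SDP nodes are binary causal anchors and
# may only have outgoing edges; the phenotype is a pure sink.
ROLE_SDP <- "sdp_binary_root"
ROLE_INTERMEDIATE <- "continuous_intermediate"
ROLE_PHENOTYPE <- "continuous_phenotype"

#' Construct a node-role vector
#'
#' Builds the named role vector consumed by the structure enumeration,
#' scoring, hill-climbing and bootstrap-averaging functions. SDP nodes are
#' binary genetic anchors restricted to outgoing edges, the phenotype is
#' restricted to incoming edges, and miRNA/gene expression nodes are
#' unconstrained continuous intermediates.
#'
#' @param sdp character vector of SDP node labels.
#' @param intermediate character vector of miRNA/gene node labels.
#' @param phenotype single phenotype node label.
#' @return Named character vector mapping node label to role.
#' @export
node_roles <- function(sdp = character(), intermediate = character(),
                       phenotype = character()) {
  if (length(phenotype) > 1L)
    stop("at most one phenotype node is supported")
  roles <- c(
    stats::setNames(rep(ROLE_SDP, length(sdp)), sdp),
    stats::setNames(rep(ROLE_INTERMEDIATE, length(intermediate)), intermediate),
    stats::setNames(rep(ROLE_PHENOTYPE, length(phenotype)), phenotype)
  )
  if (anyDuplicated(names(roles)))
    stop("node labels must be unique")
  roles
}

# Is a directed edge from -> to admissible under the role constraints?
edge_allowed <- function(roles, from, to) {
  from != to &&
    roles[[from]] != ROLE_PHENOTYPE &&
    roles[[to]] != ROLE_SDP
}

empty_edges <- function() {
  matrix(character(), ncol = 2L, dimnames = list(NULL, c("from", "to")))
}

#' Create a network structure
#'
#' A directed acyclic graph over role-typed nodes. Edges into an SDP node or
#' out of the phenotype node are rejected, as are self-loops and cycles.
#'
#' @param roles named role vector from [node_roles()].
#' @param edges two-column character matrix (from, to); may have zero rows.
#' @return An object of class `network_structure`.
#' @export
network_structure <- function(roles, edges = empty_edges()) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) edges <- empty_edges()
  if (ncol(edges) != 2L) stop("edges must have two columns (from, to)")
  colnames(edges) <- c("from", "to")
  nodes <- names(roles)
  if (!all(edges %in% nodes)) stop("edge endpoints must be declared nodes")
  for (i in seq_len(nrow(edges))) {
    if (!edge_allowed(roles, edges[i, 1L], edges[i, 2L]))
      stop(sprintf("edge %s -> %s violates the role constraints",
                   edges[i, 1L], edges[i, 2L]))
  }
  if (anyDuplicated(paste(edges[, 1L], edges[, 2L])))
    stop("duplicate edges")
  adj <- edges_to_adjacency(nodes, edges)
  if (!is_acyclic(adj)) stop("edges contain a directed cycle")
  structure(list(nodes = nodes, roles = roles, edges = edges),
            class = "network_structure")
}

#' @export
print.network_structure <- function(x, ...) {
  cat(sprintf("<network_structure> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges))
    cat(paste0("  ", x$edges[, 1L], " -> ", x$edges[, 2L], collapse = "\n"),
        "\n")
  invisible(x)
}

edges_to_adjacency <- function(nodes, edges) {
  k <- length(nodes)
  adj <- matrix(FALSE, k, k, dimnames = list(nodes, nodes))
  if (nrow(edges)) adj[edges] <- TRUE
  adj
}

# Kahn-style acyclicity test on a logical adjacency matrix.
is_acyclic <- function(adj) {
  remaining <- rep(TRUE, nrow(adj))
  repeat {
    indeg <- colSums(adj[remaining, remaining, drop = FALSE])
    src <- which(indeg == 0L)
    if (!length(src)) break
    remaining[which(remaining)[src]] <- FALSE
    if (!any(remaining)) return(TRUE)
  }
  !any(remaining)
}

# All nodes reachable from `from` by directed paths (excluding `from` itself
# unless on a cycle, which cannot occur in validated structures).
reachable_set <- function(adj, from) {
  frontier <- from
  seen <- rep(FALSE, nrow(adj))
  names(seen) <- rownames(adj)
  repeat {
    nxt <- rownames(adj)[colSums(adj[frontier, , drop = FALSE]) > 0L]
    nxt <- nxt[!seen[nxt]]
    if (!length(nxt)) break
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  names(seen)[seen]
}

#' Test whether a node mediates a source-sink relationship
#'
#' TRUE when some directed path from `source` to `sink` passes through `via`,
#' i.e. `via` is reachable from `source` and `sink` is reachable from `via`.
#' In a DAG the concatenation of the two path segments is itself a directed
#' path, so the two reachability checks are equivalent to path membership.
#'
#' @param structure a [network_structure()].
#' @param source,via,sink node labels.
#' @return Logical scalar.
#' @export
is_mediator <- function(structure, source, via, sink) {
  stopifnot(all(c(source, via, sink) %in% structure$nodes))
  adj <- edges_to_adjacency(structure$nodes, structure$edges)
  via %in% reachable_set(adj, source) && sink %in% reachable_set(adj, via)
}

topological_order <- function(structure) {
  adj <- edges_to_adjacency(structure$nodes, structure$edges)
  order <- character()
  remaining <- structure$nodes
  while (length(remaining)) {
    indeg <- colSums(adj[remaining, remaining, drop = FALSE])
    src <- remaining[indeg == 0L]
    if (!length(src)) stop("cycle detected")
    order <- c(order, src)
    remaining <- setdiff(remaining, src)
  }
  order
}

node_parents <- function(structure, node) {
  structure$edges[structure$edges[, 2L] == node, 1L]
}

#' Enumerate all admissible network structures
#'
#' Exhaustively lists every DAG over the given role-typed nodes in which all
#' edges incident to an SDP node leave the SDP and all edges incident to the
#' phenotype enter the phenotype. For the canonical one-SDP, one-miRNA,
#' one-gene, one-phenotype node set this yields 96 structures.
#'
#' @param roles named role vector from [node_roles()].
#' @param max_structures guard on the size of the candidate space before the
#'   acyclicity filter; larger spaces should be searched by [hill_climb()].
#' @return List of [network_structure()] objects, each admissible DAG exactly
#'   once.
#' @export
enumerate_constrained_structures <- function(roles, max_structures = 2^20) {
  nodes <- names(roles)
  if (length(nodes) > 6L)
    stop("exhaustive enumeration supports at most 6 nodes; use hill_climb()")
  if (length(nodes) < 2L) {
    return(list(network_structure(roles)))
  }
  pairs <- utils::combn(nodes, 2L)
  opts <- lapply(seq_len(ncol(pairs)), function(i) {
    u <- pairs[1L, i]; v <- pairs[2L, i]
    o <- list(NULL)
    if (edge_allowed(roles, u, v)) o <- c(o, list(c(u, v)))
    if (edge_allowed(roles, v, u)) o <- c(o, list(c(v, u)))
    o
  })
  n_comb <- prod(lengths(opts))
  if (n_comb > max_structures)
    stop("candidate space too large for exhaustive enumeration; use hill_climb()")
  grid <- expand.grid(lapply(opts, seq_along), KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(grid))
  n_kept <- 0L
  for (i in seq_len(nrow(grid))) {
    picked <- lapply(seq_along(opts), function(j) opts[[j]][[grid[i, j]]])
    picked <- picked[!vapply(picked, is.null, logical(1L))]
    edges <- if (length(picked)) do.call(rbind, picked) else empty_edges()
    colnames(edges) <- c("from", "to")
    if (is_acyclic(edges_to_adjacency(nodes, edges))) {
      n_kept <- n_kept + 1L
      out[[n_kept]] <- structure(list(nodes = nodes, roles = roles,
                                      edges = edges),
                                 class = "network_structure")
    }
  }
  out[seq_len(n_kept)]
}

#' Gaussian node log-likelihood
#'
#' Maximized log-likelihood of a continuous node given its parents under the
#' linear-Gaussian conditional: ordinary least squares on an intercept plus
#' the parent columns, with the maximum-likelihood residual variance RSS/n.
#' The parameter count is `number of parents + 2` (intercept, slopes,
#' residual variance).
#'
#' @param child numeric vector of child values.
#' @param parents numeric matrix of parent columns (may have zero columns).
#' @return List with `loglik`, `param_count` and `params` (intercept,
#'   per-parent coefficients, residual variance `sigma2`).
#' @export
node_loglik_continuous <- function(child, parents = NULL) {
  y <- as.numeric(child)
  n <- length(y)
  if (is.null(parents)) {
    parents <- matrix(numeric(), nrow = n, ncol = 0L)
  }
  parents <- as.matrix(parents)
  p <- ncol(parents)
  if (n <= p + 1L) stop("need n > number of parents + 1")
  X <- cbind(`(Intercept)` = 1, parents)
  fit <- .lm.fit(X, y)
  if (fit$rank < ncol(X)) stop("singular design: collinear parents")
  rss <- sum(fit$residuals^2)
  if (rss <= 0)
    stop("zero residual variance: degenerate node data")
  loglik <- -(n / 2) * (log(2 * pi * rss / n) + 1)
  coefs <- fit$coefficients[order(fit$pivot)]
  names(coefs) <- colnames(X)
  list(loglik = loglik,
       param_count = p + 2L,
       params = list(intercept = unname(coefs[1L]),
                     coef = coefs[-1L],
                     sigma2 = rss / n))
}

#' Bernoulli root node log-likelihood
#'
#' Log-likelihood of a binary root (SDP) node under its unconditional
#' Bernoulli density with the maximum-likelihood success probability, using
#' the convention 0*log(0) = 0. A single parameter is counted.
#'
#' @param values 0/1 vector.
#' @return List with `loglik`, `param_count = 1` and `params$p`.
#' @export
node_loglik_binary_root <- function(values) {
  v <- as.numeric(values)
  if (!all(v %in% c(0, 1))) stop("binary root values must be 0/1")
  p_hat <- mean(v)
  k1 <- sum(v); k0 <- length(v) - k1
  ll <- 0
  if (k1 > 0) ll <- ll + k1 * log(p_hat)
  if (k0 > 0) ll <- ll + k0 * log(1 - p_hat)
  list(loglik = ll, param_count = 1L, params = list(p = p_hat))
}

#' Score a network structure by BIC
#'
#' Computes the decomposable network score BIC = logL - (d/2) log(n), where
#' logL is the sum of maximized per-family log-likelihoods, d the total
#' parameter count and n the number of strains. Higher values indicate
#' stronger support.
#'
#' @param structure a [network_structure()].
#' @param data numeric matrix or data frame with one named column per node
#'   (strains in rows).
#' @return Object of class `scored_network` with elements `structure`,
#'   `loglik`, `d`, `n`, `bic` and `node_params`.
#' @export
score_network <- function(structure, data) {
  data <- as.matrix(data)
  if (!all(structure$nodes %in% colnames(data)))
    stop("data must contain a column for every node")
  n <- nrow(data)
  loglik <- 0
  d <- 0L
  node_params <- vector("list", length(structure$nodes))
  names(node_params) <- structure$nodes
  for (v in structure$nodes) {
    if (structure$roles[[v]] == ROLE_SDP) {
      fam <- node_loglik_binary_root(data[, v])
    } else {
      pa <- node_parents(structure, v)
      fam <- node_loglik_continuous(data[, v], data[, pa, drop = FALSE])
    }
    loglik <- loglik + fam$loglik
    d <- d + fam$param_count
    node_params[[v]] <- fam$params
  }
  structure(list(structure = structure, loglik = loglik, d = d, n = n,
                 bic = loglik - (d / 2) * log(n), node_params = node_params),
            class = "scored_network")
}

#' @export
print.scored_network <- function(x, ...) {
  cat(sprintf("<scored_network> BIC = %.4f (logL = %.4f, d = %d, n = %d)\n",
              x$bic, x$loglik, x$d, x$n))
  print(x$structure)
  invisible(x)
}

# ---- vectorized exhaustive scoring over a fixed structure space -------------
#
# The BIC decomposes over node families (child, parent set). For repeated
# scoring of the same node set (96-structure mediation search, bootstrap
# resamples) we enumerate the structures once, index each structure's families
# into the per-child family lists, and score a dataset by fitting each unique
# family once and summing via the index.

structure_space <- function(roles, max_structures = 2^20) {
  structures <- enumerate_constrained_structures(roles, max_structures)
  nodes <- names(roles)
  children <- nodes[roles != ROLE_SDP]
  roots <- nodes[roles == ROLE_SDP]
  fam_sets <- stats::setNames(vector("list", length(children)), children)
  fidx <- matrix(0L, nrow = length(structures), ncol = length(children),
                 dimnames = list(NULL, children))
  for (v in children) {
    keys_seen <- character()
    sets <- list()
    for (i in seq_along(structures)) {
      pa <- sort(node_parents(structures[[i]], v))
      key <- paste(pa, collapse = ",")
      j <- match(key, keys_seen)
      if (is.na(j)) {
        keys_seen <- c(keys_seen, key)
        sets[[length(sets) + 1L]] <- pa
        j <- length(sets)
      }
      fidx[i, v] <- j
    }
    fam_sets[[v]] <- sets
  }
  nparams <- vapply(structures, function(s) {
    length(roots) + sum(vapply(children, function(v)
      length(node_parents(s, v)) + 2L, integer(1L)))
  }, numeric(1L))
  nedges <- vapply(structures, function(s) nrow(s$edges), integer(1L))
  edge_keys <- vapply(structures, function(s) {
    if (!nrow(s$edges)) return("")
    paste(sort(paste(s$edges[, 1L], s$edges[, 2L], sep = ">")), collapse = ";")
  }, character(1L))
  list(roles = roles, structures = structures, children = children,
       roots = roots, fam_sets = fam_sets, fidx = fidx,
       nparams = nparams, nedges = nedges, edge_keys = edge_keys)
}

# BIC of every structure in the space on `data`; -Inf marks structures whose
# families are singular on this dataset (possible in bootstrap resamples).
score_structure_space <- function(space, data) {
  data <- as.matrix(data)
  n <- nrow(data)
  total <- 0
  for (r in space$roots)
    total <- total + node_loglik_binary_root(data[, r])$loglik
  bic <- rep(total, length(space$structures))
  for (v in space$children) {
    fam_ll <- vapply(space$fam_sets[[v]], function(pa) {
      tryCatch(
        node_loglik_continuous(data[, v], data[, pa, drop = FALSE])$loglik,
        error = function(e) -Inf)
    }, numeric(1L))
    bic <- bic + fam_ll[space$fidx[, v]]
  }
  bic - (space$nparams / 2) * log(n)
}

# Deterministic argmax: highest BIC, ties (within 1e-9) broken by fewer
# edges, then lexicographic edge list.
pick_best_structure <- function(space, bic) {
  top <- which(bic >= max(bic) - 1e-9)
  top <- top[order(space$nedges[top], space$edge_keys[top])]
  top[1L]
}
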