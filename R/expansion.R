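# Combining passing quadruples into locus-level node sets and learning
# averaged network structures over strain bootstraps.

#' Group passing quadruples by phenotype and genomic locus
#'
#' Per phenotype, SDPs from mediation-passing quadruples are clustered by
#' single-linkage on the midpoint distance of their member-SNP spans, with
#' links allowed only on the same chromosome and within `window_bp`. Each
#' group accumulates the miRNAs of its member decisions and the genes of
#' member decisions that passed the gene-inclusion step.
#'
#' @param decisions mediation screen summary (data frame from
#'   [run_mediation_screen()]).
#' @param sdp_table the `sdp_table` the SDP ids refer to.
#' @param window_bp maximum same-chromosome midpoint gap joining two SDPs
#'   (default 40 Mb).
#' @return List of `locus_group` objects with fields `phenotype_id`, `chrom`,
#'   `sdp_ids`, `mirna_ids`, `gene_ids` and `nodes`.
#' @export
group_by_locus <- function(decisions, sdp_table, window_bp = 40e6) {
  passing <- decisions[decisions$mediation_pass, , drop = FALSE]
  if (!nrow(passing)) return(list())
  span <- sdp_table$span
  mid <- stats::setNames((span$start + span$end) / 2, span$sdp_id)
  chrom <- stats::setNames(span$chrom, span$sdp_id)
  groups <- list()
  for (ph in unique(passing$phenotype_id)) {
    rows <- passing[passing$phenotype_id == ph, , drop = FALSE]
    sdps <- unique(rows$sdp_id)
    for (ch in unique(chrom[sdps])) {
      s <- sdps[chrom[sdps] == ch]
      s <- s[order(mid[s])]
      # single-linkage in 1D: chain SDPs while consecutive gaps <= window
      cluster_id <- cumsum(c(1, diff(mid[s]) > window_bp))
      for (k in unique(cluster_id)) {
        members <- s[cluster_id == k]
        in_group <- rows$sdp_id %in% members
        # sorted for invariance to decision row order
        mirnas <- sort(unique(rows$mirna_id[in_group]))
        genes <- sort(unique(rows$gene_id[in_group & rows$gene_pass]))
        nodes <- c(members, mirnas, genes, ph)
        groups[[length(groups) + 1L]] <-
          structure(list(phenotype_id = ph, chrom = ch, sdp_ids = members,
                         mirna_ids = mirnas, gene_ids = genes, nodes = nodes),
                    class = "locus_group")
      }
    }
  }
  groups
}

#' @export
print.locus_group <- function(x, ...) {
  cat(sprintf("<locus_group> %s @ chr %s: %d SDP(s), %d miRNA(s), %d gene(s)\n",
              x$phenotype_id, x$chrom, length(x$sdp_ids),
              length(x$mirna_ids), length(x$gene_ids)))
  invisible(x)
}

# role vector + node data matrix for a locus group
group_roles <- function(group) {
  node_roles(sdp = group$sdp_ids,
             intermediate = c(group$mirna_ids, group$gene_ids),
             phenotype = group$phenotype_id)
}

# family score with cache; -Inf for singular families
cached_family_score <- function(cache, data, child, parents, is_root) {
  key <- paste(child, paste(sort(parents), collapse = ","), sep = "|")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- tryCatch({
    if (is_root) {
      f <- node_loglik_binary_root(data[, child])
    } else {
      f <- node_loglik_continuous(data[, child],
                                  data[, parents, drop = FALSE])
    }
    f$loglik - (f$param_count / 2) * log(nrow(data))
  }, error = function(e) -Inf)
  cache[[key]] <- val
  val
}

#' Greedy BIC hill-climbing over constrained structures
#'
#' Local search over single-edge additions, deletions and reversals that
#' respect the role constraints and acyclicity. A move is accepted only when
#' it strictly improves the network BIC; among equal-improvement moves,
#' additions are preferred over reversals over deletions, then the
#' lexicographically first edge, so the search is deterministic. At a local
#' optimum the search additionally probes score-neutral edge reversals
#' (likelihood-equivalent reorientations) followed by further climbing, and
#' commits such an excursion only when it strictly improves the total BIC;
#' this escapes the plateaus that score equivalence creates around
#' misoriented edges.
#'
#' @param data strains x nodes numeric matrix with named columns.
#' @param roles named role vector from [node_roles()].
#' @param start optional starting [network_structure()] (default empty graph).
#' @param max_iter maximum accepted moves before the result is flagged
#'   non-converged.
#' @return A `scored_network` with attributes `converged` and `iterations`.
#' @export
hill_climb <- function(data, roles, start = NULL, max_iter = 200L) {
  data <- as.matrix(data)
  nodes <- names(roles)
  stopifnot(all(nodes %in% colnames(data)))
  data <- data[, nodes, drop = FALSE]
  if (is.null(start)) start <- network_structure(roles)
  adj <- edges_to_adjacency(nodes, start$edges)
  cache <- new.env(parent = emptyenv())
  fam <- function(child, parents)
    cached_family_score(cache, data, child, parents,
                        roles[[child]] == ROLE_SDP)
  parents_of <- function(a, v) nodes[a[, v]]
  rescore <- function(a) stats::setNames(
    vapply(nodes, function(v) fam(v, parents_of(a, v)), numeric(1L)), nodes)
  eps <- 1e-9
  iterations <- 0L
  converged <- FALSE

  # one greedy descent-to-local-optimum pass; returns updated state
  climb <- function(adj, node_score) {
    while (iterations < max_iter) {
      best <- list(delta = eps, priority = NULL)
      for (u in nodes) for (v in nodes) {
        if (u == v || !edge_allowed(roles, u, v)) next
        if (adj[u, v]) {
          d_del <- fam(v, setdiff(parents_of(adj, v), u)) - node_score[v]
          best <- better_move(best, list(delta = d_del, type = 3L, u = u,
                                         v = v, move = "del"))
          if (edge_allowed(roles, v, u)) {
            a2 <- adj; a2[u, v] <- FALSE
            if (!(u %in% reachable_set(a2, v))) { # no other v->u path
              d_rev <- (fam(v, setdiff(parents_of(adj, v), u)) -
                          node_score[v]) +
                (fam(u, c(parents_of(adj, u), v)) - node_score[u])
              best <- better_move(best, list(delta = d_rev, type = 2L, u = u,
                                             v = v, move = "rev"))
            }
          }
        } else if (!adj[v, u]) {
          if (!(u %in% reachable_set(adj, v))) { # addition stays acyclic
            d_add <- fam(v, c(parents_of(adj, v), u)) - node_score[v]
            best <- better_move(best, list(delta = d_add, type = 1L, u = u,
                                           v = v, move = "add"))
          }
        }
      }
      if (is.null(best$priority)) break
      u <- best$u; v <- best$v
      if (best$move == "add") {
        adj[u, v] <- TRUE
      } else if (best$move == "del") {
        adj[u, v] <- FALSE
      } else {
        adj[u, v] <- FALSE; adj[v, u] <- TRUE
        node_score[u] <- fam(u, parents_of(adj, u))
      }
      node_score[v] <- fam(v, parents_of(adj, v))
      iterations <<- iterations + 1L
    }
    list(adj = adj, node_score = node_score)
  }

  state <- climb(adj, rescore(adj))
  # plateau exploration: score-neutral reversals + renewed climbing
  repeat {
    if (iterations >= max_iter) break
    improved <- FALSE
    cur_bic <- sum(state$node_score)
    cand <- which(state$adj, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(nodes[cand[, 1L]], nodes[cand[, 2L]])
      cand <- cand[ord, , drop = FALSE]
    }
    for (i in seq_len(nrow(cand))) {
      u <- nodes[cand[i, 1L]]; v <- nodes[cand[i, 2L]]
      if (!edge_allowed(roles, v, u)) next
      a2 <- state$adj; a2[u, v] <- FALSE
      if (u %in% reachable_set(a2, v)) next
      d_rev <- (fam(v, setdiff(parents_of(state$adj, v), u)) -
                  state$node_score[v]) +
        (fam(u, c(parents_of(state$adj, u), v)) - state$node_score[u])
      if (abs(d_rev) > eps) next # only score-neutral reorientations
      a2[v, u] <- TRUE
      trial <- climb(a2, rescore(a2))
      if (sum(trial$node_score) > cur_bic + eps) {
        state <- trial
        improved <- TRUE
        break
      }
    }
    if (!improved) { converged <- TRUE; break }
  }
  adj <- state$adj
  edges <- which(adj, arr.ind = TRUE)
  edges <- cbind(from = nodes[edges[, 1L]], to = nodes[edges[, 2L]])
  result <- score_network(network_structure(roles, edges), data)
  attr(result, "converged") <- converged
  attr(result, "iterations") <- iterations
  result
}

# compare candidate move against incumbent: larger delta wins; ties (within
# 1e-9) by type priority (add < rev < del), then lexicographic edge
better_move <- function(best, cand) {
  accept <- function() c(cand, list(priority = cand$type))
  if (is.null(best$priority)) {
    # incumbent is the minimum-improvement threshold, not a move
    if (cand$delta > best$delta) return(accept())
    return(best)
  }
  if (cand$delta > best$delta + 1e-9) return(accept())
  if (cand$delta < best$delta - 1e-9) return(best)
  if (cand$type < best$priority) return(accept())
  if (cand$type == best$priority &&
      paste(cand$u, cand$v) < paste(best$u, best$v)) return(accept())
  best
}

# single structure-learning call used per bootstrap replicate
learn_structure <- function(data, roles, space = NULL, restarts = 0L) {
  nodes <- names(roles)
  if (!is.null(space)) {
    bic <- score_structure_space(space, data)
    return(space$structures[[pick_best_structure(space, bic)]])
  }
  fit <- hill_climb(data, roles)
  if (restarts > 0L) {
    for (r in seq_len(restarts)) {
      start <- random_admissible_dag(roles)
      alt <- hill_climb(data, roles, start = start)
      if (alt$bic > fit$bic + 1e-9) fit <- alt
    }
  }
  fit$structure
}

# random admissible DAG: random topological order of intermediates, each
# allowed edge included with probability 0.3
random_admissible_dag <- function(roles, p_edge = 0.3) {
  nodes <- names(roles)
  inter <- nodes[roles == ROLE_INTERMEDIATE]
  ord <- c(nodes[roles == ROLE_SDP], sample(inter),
           nodes[roles == ROLE_PHENOTYPE])
  edges <- empty_edges()
  for (i in seq_along(ord)) for (j in seq_along(ord)) {
    if (i < j && edge_allowed(roles, ord[i], ord[j]) &&
        stats::runif(1) < p_edge)
      edges <- rbind(edges, c(ord[i], ord[j]))
  }
  network_structure(roles, edges)
}

#' Apply the majority retention rule to bootstrap edge statistics
#'
#' An edge is retained when its presence frequency over the bootstraps
#' exceeds `retention` (strictly) and its winning direction also exceeds
#' `retention` (strictly) in the chosen denominator. If the retained edges
#' would close a directed cycle, edges are admitted in decreasing presence
#' frequency and any cycle-closing edge is skipped with a warning.
#'
#' @param edge_stats data frame with columns `node_a`, `node_b`, `n_present`,
#'   `n_a_to_b`, `n_b_to_a` (as built by [bootstrap_average()]).
#' @param n_boot number of bootstrap replicates behind the counts.
#' @param retention frequency threshold (default 0.5, strict).
#' @param direction_denominator `"edge_present"` computes the direction
#'   frequency among bootstraps containing the edge (model-averaging
#'   convention); `"all_bootstraps"` uses all replicates.
#' @param nodes optional node ordering used for the acyclicity guard.
#' @return Data frame of retained directed edges with `presence_freq` and
#'   `direction_freq`.
#' @export
retain_averaged_edges <- function(edge_stats, n_boot, retention = 0.5,
                                  direction_denominator = c("edge_present",
                                                            "all_bootstraps"),
                                  nodes = NULL) {
  direction_denominator <- match.arg(direction_denominator)
  pres <- edge_stats$n_present / n_boot
  win_ab <- edge_stats$n_a_to_b >= edge_stats$n_b_to_a
  n_win <- pmax(edge_stats$n_a_to_b, edge_stats$n_b_to_a)
  denom <- if (direction_denominator == "edge_present")
    edge_stats$n_present else rep(n_boot, nrow(edge_stats))
  dir_freq <- ifelse(denom > 0, n_win / denom, 0)
  keep <- pres > retention & dir_freq > retention
  out <- data.frame(
    from = ifelse(win_ab, edge_stats$node_a, edge_stats$node_b),
    to = ifelse(win_ab, edge_stats$node_b, edge_stats$node_a),
    presence_freq = pres, direction_freq = dir_freq,
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out <- out[order(-out$presence_freq, out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out)) return(out)
  if (is.null(nodes)) nodes <- unique(c(out$from, out$to))
  adj <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  ok <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    adj[out$from[i], out$to[i]] <- TRUE
    if (is_acyclic(adj)) {
      ok[i] <- TRUE
    } else {
      adj[out$from[i], out$to[i]] <- FALSE
      warning(sprintf("retained edge %s -> %s would close a cycle; skipped",
                      out$from[i], out$to[i]))
    }
  }
  out[ok, , drop = FALSE]
}

#' Bootstrap-averaged network learning
#'
#' Learns a structure on each of `n_boot` strain resamples (with replacement,
#' resample size n) and averages: per undirected node pair the presence
#' frequency, and per direction the frequency among resamples containing the
#' edge. Small node sets are searched exhaustively, larger ones by
#' [hill_climb()] from the empty structure. Edges and directions appearing in
#' more than `retention` of the replicates are retained; nodes left without a
#' retained edge are reported as dropped.
#'
#' @param data strains x nodes numeric matrix with named columns.
#' @param roles named role vector from [node_roles()].
#' @param n_boot number of bootstrap replicates (default 500).
#' @param retention retention threshold (default 0.5, strict).
#' @param seed integer seed making the resampling reproducible.
#' @param direction_denominator see [retain_averaged_edges()].
#' @param exhaustive_max_nodes use exhaustive search for node sets up to this
#'   size (default 5), hill-climbing beyond.
#' @param restarts extra random hill-climbing starts per replicate.
#' @param max_redraw attempts to redraw a degenerate replicate (a resample
#'   with a zero-variance node) before failing.
#' @return Object of class `averaged_network` with `nodes`, `edge_stats`,
#'   `retained_edges`, `dropped_nodes`, `n_boot` and `retention`.
#' @export
bootstrap_average <- function(data, roles, n_boot = 500L, retention = 0.5,
                              seed = NULL,
                              direction_denominator = c("edge_present",
                                                        "all_bootstraps"),
                              exhaustive_max_nodes = 5L, restarts = 0L,
                              max_redraw = 10L) {
  direction_denominator <- match.arg(direction_denominator)
  data <- as.matrix(data)
  nodes <- names(roles)
  data <- data[, nodes, drop = FALSE]
  n <- nrow(data)
  if (n < 6L) stop("need at least 6 strains for bootstrap averaging")
  if (!is.null(seed)) set.seed(seed)
  space <- NULL
  if (length(nodes) <= exhaustive_max_nodes)
    space <- structure_space(roles)
  k <- length(nodes)
  pres_dir <- matrix(0L, k, k, dimnames = list(nodes, nodes))
  for (b in seq_len(n_boot)) {
    db <- NULL
    for (attempt in seq_len(max_redraw)) {
      idx <- sample.int(n, n, replace = TRUE)
      cand <- data[idx, , drop = FALSE]
      if (all(apply(cand, 2L, stats::var) > 0)) { db <- cand; break }
      message("degenerate bootstrap replicate redrawn")
    }
    if (is.null(db))
      stop("bootstrap replicate with zero-variance node after ", max_redraw,
           " redraws")
    s <- learn_structure(db, roles, space = space, restarts = restarts)
    if (nrow(s$edges)) pres_dir[s$edges] <- pres_dir[s$edges] + 1L
  }
  pairs <- utils::combn(nodes, 2L)
  edge_stats <- data.frame(
    node_a = pairs[1L, ], node_b = pairs[2L, ],
    n_present = pres_dir[t(pairs)] + pres_dir[t(pairs[2:1, , drop = FALSE])],
    n_a_to_b = pres_dir[t(pairs)],
    n_b_to_a = pres_dir[t(pairs[2:1, , drop = FALSE])],
    stringsAsFactors = FALSE)
  edge_stats$presence_freq <- edge_stats$n_present / n_boot
  retained <- retain_averaged_edges(edge_stats, n_boot, retention,
                                    direction_denominator, nodes = nodes)
  connected <- unique(c(retained$from, retained$to))
  structure(list(nodes = nodes, roles = roles, edge_stats = edge_stats,
                 retained_edges = retained,
                 dropped_nodes = setdiff(nodes, connected),
                 n_boot = n_boot, retention = retention,
                 direction_denominator = direction_denominator),
            class = "averaged_network")
}

#' @export
print.averaged_network <- function(x, ...) {
  cat(sprintf("<averaged_network> %d nodes, %d retained edges (%d bootstraps)\n",
              length(x$nodes), nrow(x$retained_edges), x$n_boot))
  if (nrow(x$retained_edges))
    print(x$retained_edges)
  if (length(x$dropped_nodes))
    cat("  dropped (disconnected):", paste(x$dropped_nodes, collapse = ", "),
        "\n")
  invisible(x)
}

#' Retained averaged network as a network structure
#'
#' @param averaged an `averaged_network`.
#' @param drop_disconnected drop nodes without retained edges (default TRUE),
#'   matching how final networks are reported.
#' @return A [network_structure()] over the connected nodes.
#' @export
as_network_structure <- function(averaged, drop_disconnected = TRUE) {
  stopifnot(inherits(averaged, "averaged_network"))
  nodes <- averaged$nodes
  if (drop_disconnected) nodes <- setdiff(nodes, averaged$dropped_nodes)
  roles <- averaged$roles[nodes]
  edges <- as.matrix(averaged$retained_edges[, c("from", "to")])
  if (!nrow(edges)) edges <- empty_edges()
  network_structure(roles, edges)
}

#' Serialize an averaged network to JSON
#'
#' @param averaged an `averaged_network`.
#' @param path output file.
#' @export
write_averaged_network <- function(averaged, path) {
  jsonlite::write_json(
    list(nodes = averaged$nodes,
         roles = as.list(averaged$roles),
         edge_stats = averaged$edge_stats,
         retained_edges = averaged$retained_edges,
         dropped_nodes = averaged$dropped_nodes,
         n_boot = averaged$n_boot, retention = averaged$retention),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
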