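# Parameter fitting on a final structure and interventional prediction of
# phenotype change for quartile-scale shifts of a miRNA or gene node.

#' Fit linear-Gaussian parameters on a network structure
#'
#' Ordinary least squares of every continuous node on its parents (intercept,
#' per-parent coefficients, maximum-likelihood residual variance) and the
#' Bernoulli probability for binary roots, plus the per-node training-data
#' quantiles (minimum, first quartile, third quartile, maximum) used to scale
#' interventions.
#'
#' @param structure a [network_structure()].
#' @param data strains x nodes numeric matrix with named columns.
#' @param quantile_type `"linear"` for the interpolation convention
#'   (`stats::quantile` type 7, the scientific-software default) or
#'   `"nearest_rank"` (type 1).
#' @return Object of class `fitted_network` with `structure`, `params`,
#'   `quantiles` and `n`.
#' @export
fit_network_parameters <- function(structure, data,
                                   quantile_type = c("linear",
                                                     "nearest_rank")) {
  quantile_type <- match.arg(quantile_type)
  qtype <- if (quantile_type == "linear") 7L else 1L
  scored <- score_network(structure, data)
  data <- as.matrix(data)
  quantiles <- do.call(rbind, lapply(structure$nodes, function(v) {
    q <- stats::quantile(data[, v], probs = c(0, 0.25, 0.75, 1),
                         type = qtype, names = FALSE)
    data.frame(node = v, min = q[1L], q1 = q[2L], q3 = q[3L], max = q[4L],
               stringsAsFactors = FALSE)
  }))
  structure(list(structure = structure, params = scored$node_params,
                 quantiles = quantiles, n = nrow(data),
                 loglik = scored$loglik, bic = scored$bic),
            class = "fitted_network")
}

#' @export
print.fitted_network <- function(x, ...) {
  cat(sprintf("<fitted_network> %d nodes, %d edges, n = %d\n",
              length(x$structure$nodes), nrow(x$structure$edges), x$n))
  invisible(x)
}

# all directed paths from -> to as lists of node vectors
directed_paths <- function(structure, from, to) {
  adj <- edges_to_adjacency(structure$nodes, structure$edges)
  paths <- list()
  walk <- function(path) {
    tail_node <- path[length(path)]
    if (tail_node == to) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (nxt in structure$nodes[adj[tail_node, ]]) walk(c(path, nxt))
  }
  walk(from)
  paths
}

edge_coefficient <- function(fitted, from, to) {
  unname(fitted$params[[to]]$coef[from])
}

# expected node values under do(target = value); upstream nodes keep their
# unconditional expectations, descendants propagate through the structural
# equations in topological order.
propagate_expectation <- function(fitted, target = NULL, value = NULL) {
  s <- fitted$structure
  ord <- topological_order(s)
  ev <- stats::setNames(numeric(length(ord)), ord)
  for (v in ord) {
    if (!is.null(target) && v == target) { ev[v] <- value; next }
    p <- fitted$params[[v]]
    if (s$roles[[v]] == ROLE_SDP) {
      ev[v] <- p$p
    } else {
      pa <- node_parents(s, v)
      ev[v] <- p$intercept + sum(p$coef[pa] * ev[pa])
    }
  }
  ev
}

#' Predict the phenotype change for a quartile intervention
#'
#' Sets a miRNA or gene node from its first to its third training quartile
#' (`two_quartile`) or from its minimum to its maximum (`four_quartile`) and
#' propagates expected values through the structural equations of the fitted
#' network (do-intervention semantics: upstream nodes, including the SDP, are
#' untouched). Equivalently, the change equals the input change times the sum
#' over directed target-to-phenotype paths of the products of edge
#' coefficients; both computations are performed and cross-checked to 1e-10.
#'
#' @param fitted a [fit_network_parameters()] result.
#' @param target a miRNA or gene node label.
#' @param span `"two_quartile"` (Q3 - Q1) or `"four_quartile"` (max - min).
#' @return Object of class `intervention_result`: `target`, `span`,
#'   `delta_input`, `delta_phenotype` and the per-path coefficient-product
#'   decomposition.
#' @export
predict_phenotype_change <- function(fitted,
                                     target,
                                     span = c("two_quartile",
                                              "four_quartile")) {
  span <- match.arg(span)
  stopifnot(inherits(fitted, "fitted_network"))
  s <- fitted$structure
  if (!target %in% s$nodes) stop("unknown target node: ", target)
  if (s$roles[[target]] != ROLE_INTERMEDIATE)
    stop("intervention target must be a miRNA or gene node, not the ",
         "phenotype or an SDP")
  phen <- s$nodes[s$roles == ROLE_PHENOTYPE]
  if (length(phen) != 1L) stop("fitted network must have one phenotype node")
  q <- fitted$quantiles[fitted$quantiles$node == target, ]
  lo <- if (span == "two_quartile") q$q1 else q$min
  hi <- if (span == "two_quartile") q$q3 else q$max
  delta_input <- hi - lo
  paths <- directed_paths(s, target, phen)
  path_df <- if (length(paths)) {
    do.call(rbind, lapply(paths, function(p) {
      coefs <- vapply(seq_len(length(p) - 1L), function(i)
        edge_coefficient(fitted, p[i], p[i + 1L]), numeric(1L))
      data.frame(path = paste(p, collapse = "->"),
                 coefficient_product = prod(coefs), stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(path = character(), coefficient_product = numeric(),
               stringsAsFactors = FALSE)
  }
  delta_paths <- delta_input * sum(path_df$coefficient_product)
  ev_lo <- propagate_expectation(fitted, target, lo)
  ev_hi <- propagate_expectation(fitted, target, hi)
  delta_prop <- ev_hi[[phen]] - ev_lo[[phen]]
  if (abs(delta_prop - delta_paths) > 1e-10 * max(1, abs(delta_paths)))
    stop("internal inconsistency between propagation and path-product ",
         "predictions")
  structure(list(target = target, span = span, delta_input = delta_input,
                 delta_phenotype = delta_paths, phenotype = phen,
                 path_decomposition = path_df),
            class = "intervention_result")
}

#' @export
print.intervention_result <- function(x, ...) {
  cat(sprintf("<intervention_result> do(%s: %+.4g) => %s changes by %+.4g\n",
              x$target, x$delta_input, x$phenotype, x$delta_phenotype))
  if (nrow(x$path_decomposition)) {
    for (i in seq_len(nrow(x$path_decomposition)))
      cat(sprintf("  %s : %+.4g\n", x$path_decomposition$path[i],
                  x$path_decomposition$coefficient_product[i]))
  } else cat("  (no directed path to the phenotype)\n")
  invisible(x)
}
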