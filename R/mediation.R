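# Exhaustive 96-structure mediation decision per cohesive quadruple: score
# every admissible DAG, compare the best miRNA-mediated network with the best
# non-mediated one (step 1), then evaluate gene inclusion on the
# genotype-to-phenotype path among mediated networks (step 2).

# The quadruple space (one SDP root, miRNA + gene intermediates, one
# phenotype) is fixed, so it is enumerated once with canonical labels and
# cached; quadruple data are mapped onto the canonical columns.
.mirmednet_cache <- new.env(parent = emptyenv())

QUAD_SDP <- ".S"; QUAD_MIR <- ".M"; QUAD_GENE <- ".G"; QUAD_PHEN <- ".P"

quadruple_space <- function() {
  if (!is.null(.mirmednet_cache$quad_space)) return(.mirmednet_cache$quad_space)
  roles <- node_roles(sdp = QUAD_SDP,
                      intermediate = c(QUAD_MIR, QUAD_GENE),
                      phenotype = QUAD_PHEN)
  space <- structure_space(roles)
  space$mirna_mediates <- vapply(space$structures, is_mediator,
                                 logical(1L), source = QUAD_SDP,
                                 via = QUAD_MIR, sink = QUAD_PHEN)
  space$gene_in_path <- vapply(space$structures, is_mediator,
                               logical(1L), source = QUAD_SDP,
                               via = QUAD_GENE, sink = QUAD_PHEN)
  .mirmednet_cache$quad_space <- space
  space
}

relabel_structure <- function(structure, mapping) {
  edges <- structure$edges
  if (nrow(edges)) {
    edges[, 1L] <- mapping[edges[, 1L]]
    edges[, 2L] <- mapping[edges[, 2L]]
  }
  roles <- structure$roles
  names(roles) <- mapping[names(roles)]
  network_structure(roles, edges)
}

#' Evaluate miRNA mediation for one quadruple
#'
#' Scores all 96 admissible network structures over (SDP, miRNA, gene,
#' phenotype) and applies the two BIC-difference decision steps. Step 1
#' passes when the best network with the miRNA on a directed
#' SDP-to-phenotype path beats the best network without it by more than
#' `threshold_step1` (and the best network overall is itself mediated).
#' Step 2, evaluated only after step 1 and only among mediated structures,
#' includes the gene when the best network with the gene also on an
#' SDP-to-phenotype path scores within `-threshold_step2` of (i.e. at least
#' `threshold_step2` above) the best miRNA-only-path network.
#'
#' @param dataset an [align_for_phenotype()] result.
#' @param sdp_id,mirna_id,gene_id node identifiers of the quadruple; the
#'   phenotype is the dataset's phenotype.
#' @param threshold_step1 BIC difference required for miRNA mediation
#'   (default 2).
#' @param threshold_step2 BIC difference required for gene inclusion
#'   (default -1, a non-inferiority margin).
#' @return Object of class `mediation_decision`: the best scored network, the
#'   two BIC differences, pass flags and the node labels promoted to the
#'   expansion stage.
#' @export
evaluate_quadruple <- function(dataset, sdp_id, mirna_id, gene_id,
                               threshold_step1 = 2, threshold_step2 = -1) {
  stopifnot(inherits(dataset, "aligned_dataset"))
  if (dataset$n < 6L) stop("need at least 6 strains for the 96-structure search")
  space <- quadruple_space()
  actual <- c(sdp_id, mirna_id, gene_id, dataset$phenotype_id)
  canon <- c(QUAD_SDP, QUAD_MIR, QUAD_GENE, QUAD_PHEN)
  data <- node_matrix(dataset, actual)
  colnames(data) <- canon
  bic <- score_structure_space(space, data)
  med <- space$mirna_mediates
  best_idx <- pick_best_structure(space, bic)
  best_mediated_bic <- max(bic[med])
  best_nonmediated_bic <- max(bic[!med])
  delta_mediation <- best_mediated_bic - best_nonmediated_bic
  mediation_pass <- delta_mediation > threshold_step1 && med[best_idx]
  delta_gene <- NA_real_
  gene_pass <- FALSE
  if (mediation_pass) {
    both <- med & space$gene_in_path
    mirna_only <- med & !space$gene_in_path
    if (!any(mirna_only)) {
      warning("no mediated structure without the gene in the path; including gene")
      gene_pass <- TRUE
    } else {
      delta_gene <- max(bic[both]) - max(bic[mirna_only])
      gene_pass <- delta_gene > threshold_step2
    }
  }
  selected <- character()
  if (mediation_pass) {
    selected <- c(sdp_id, mirna_id, dataset$phenotype_id)
    if (gene_pass) selected <- c(sdp_id, mirna_id, gene_id,
                                 dataset$phenotype_id)
  }
  mapping <- stats::setNames(actual, canon)
  best_structure <- relabel_structure(space$structures[[best_idx]], mapping)
  best_overall <- score_network(best_structure,
                                node_matrix(dataset, actual))
  structure(list(sdp_id = sdp_id, mirna_id = mirna_id, gene_id = gene_id,
                 phenotype_id = dataset$phenotype_id,
                 best_overall = best_overall,
                 best_mediated_bic = best_mediated_bic,
                 best_nonmediated_bic = best_nonmediated_bic,
                 delta_mediation = delta_mediation,
                 mediation_pass = mediation_pass,
                 delta_gene = delta_gene, gene_pass = gene_pass,
                 selected_nodes = selected,
                 n_structures = length(space$structures),
                 n_mediated = sum(med)),
            class = "mediation_decision")
}

#' @export
print.mediation_decision <- function(x, ...) {
  cat(sprintf("<mediation_decision> %s / %s / %s -> %s\n",
              x$sdp_id, x$mirna_id, x$gene_id, x$phenotype_id))
  cat(sprintf("  step 1 (miRNA mediation): dBIC = %.3f -> %s\n",
              x$delta_mediation, if (x$mediation_pass) "PASS" else "fail"))
  if (x$mediation_pass)
    cat(sprintf("  step 2 (gene inclusion):  dBIC = %.3f -> %s\n",
                x$delta_gene, if (x$gene_pass) "include gene" else "miRNA only"))
  invisible(x)
}

#' Run the mediation screen over cohesive quadruples
#'
#' Applies [evaluate_quadruple()] to each row of a cohesive-quadruple table.
#' The stage is deterministic and row-order independent.
#'
#' @param quadruples data frame with columns `sdp_id`, `mirna_id`, `gene_id`
#'   (e.g. from [extend_to_quadruples()]).
#' @param dataset the matching [align_for_phenotype()] result.
#' @param threshold_step1,threshold_step2 BIC-difference thresholds, see
#'   [evaluate_quadruple()].
#' @return List with `decisions` (list of `mediation_decision`) and `summary`
#'   (one data-frame row per quadruple).
#' @export
run_mediation_screen <- function(quadruples, dataset,
                                 threshold_step1 = 2, threshold_step2 = -1) {
  decisions <- lapply(seq_len(nrow(quadruples)), function(i) {
    evaluate_quadruple(dataset,
                       quadruples$sdp_id[i], quadruples$mirna_id[i],
                       quadruples$gene_id[i],
                       threshold_step1 = threshold_step1,
                       threshold_step2 = threshold_step2)
  })
  summary <- do.call(rbind, lapply(decisions, function(d) {
    e <- d$best_overall$structure$edges
    data.frame(sdp_id = d$sdp_id, mirna_id = d$mirna_id, gene_id = d$gene_id,
               phenotype_id = d$phenotype_id,
               best_bic = d$best_overall$bic,
               best_edges = paste(e[, 1L], e[, 2L], sep = "->",
                                  collapse = ";"),
               delta_mediation = d$delta_mediation,
               mediation_pass = d$mediation_pass,
               delta_gene = d$delta_gene, gene_pass = d$gene_pass,
               stringsAsFactors = FALSE)
  }))
  if (is.null(summary))
    summary <- data.frame(sdp_id = character(), mirna_id = character(),
                          gene_id = character(), phenotype_id = character(),
                          best_bic = numeric(), best_edges = character(),
                          delta_mediation = numeric(),
                          mediation_pass = logical(), delta_gene = numeric(),
                          gene_pass = logical(), stringsAsFactors = FALSE)
  list(decisions = decisions, summary = summary)
}
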