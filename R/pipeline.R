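# End-to-end orchestration: per-phenotype alignment, cohesive screen,
# mediation decisions, locus grouping and bootstrap-averaged networks.

#' Run the full screening and network pipeline for one phenotype
#'
#' Aligns the sources on the phenotype's strain set, screens for cohesive
#' triplets and quadruples, applies the 96-structure mediation decision to
#' each quadruple, groups passing quadruples by genomic locus and learns a
#' bootstrap-averaged network per locus group. Fitted parameters for each
#' retained network are included so interventional predictions can be made
#' directly.
#'
#' @param sdps an `sdp_table` (see [collapse_to_sdps()]).
#' @param mirna,genes [expression_matrix()] objects.
#' @param phenotypes a [phenotype_table()].
#' @param phenotype_id phenotype to analyze.
#' @param triplet_p,quadruple_p cohesive screen thresholds (defaults 1e-3 and
#'   0.05).
#' @param bic_delta_mediation,bic_delta_gene mediation decision thresholds
#'   (defaults 2 and -1).
#' @param locus_window_bp SDP grouping window (default 40 Mb).
#' @param n_boot,retention bootstrap averaging controls.
#' @param seed integer seed for the bootstrap resampling.
#' @param exhaustive_max_nodes exhaustive search bound, see
#'   [bootstrap_average()].
#' @return List of class `pipeline_result`: `dataset`, `triplets`,
#'   `quadruples`, `mediation` (screen output), `groups` and `networks`
#'   (per group: the `averaged_network` plus a `fitted_network` on the
#'   retained structure when it has edges).
#' @export
run_pipeline <- function(sdps, mirna, genes, phenotypes, phenotype_id,
                         triplet_p = 1e-3, quadruple_p = 0.05,
                         bic_delta_mediation = 2, bic_delta_gene = -1,
                         locus_window_bp = 40e6, n_boot = 500L,
                         retention = 0.5, seed = 1L,
                         exhaustive_max_nodes = 5L) {
  dataset <- align_for_phenotype(sdps, mirna, genes, phenotypes, phenotype_id)
  triplets <- find_cohesive_triplets(dataset, p_threshold = triplet_p)
  quadruples <- extend_to_quadruples(triplets, dataset,
                                     p_threshold = quadruple_p)
  mediation <- run_mediation_screen(quadruples, dataset,
                                    threshold_step1 = bic_delta_mediation,
                                    threshold_step2 = bic_delta_gene)
  groups <- group_by_locus(mediation$summary, dataset$sdps,
                           window_bp = locus_window_bp)
  seeds <- if (length(groups)) derive_seeds(seed, length(groups)) else integer()
  networks <- lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    roles <- group_roles(g)
    data <- node_matrix(dataset, g$nodes)
    avg <- bootstrap_average(data, roles, n_boot = n_boot,
                             retention = retention, seed = seeds[i],
                             exhaustive_max_nodes = exhaustive_max_nodes)
    fitted <- NULL
    if (nrow(avg$retained_edges)) {
      s <- as_network_structure(avg)
      fitted <- fit_network_parameters(s, data[, s$nodes, drop = FALSE])
    }
    list(group = g, averaged = avg, fitted = fitted)
  })
  structure(list(phenotype_id = phenotype_id, dataset = dataset,
                 triplets = triplets, quadruples = quadruples,
                 mediation = mediation, groups = groups,
                 networks = networks),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %s: %d cohesive triplet(s), %d quadruple(s), %d passing, %d locus group(s)\n",
    x$phenotype_id, nrow(x$triplets), nrow(x$quadruples),
    sum(x$mediation$summary$mediation_pass), length(x$groups)))
  invisible(x)
}

#' Run the pipeline on a simulated panel
#'
#' Convenience wrapper: filters and collapses the panel genotypes, collapses
#' expression replicates and runs [run_pipeline()] for the requested
#' phenotypes.
#'
#' @param panel an [simulate_panel()] result.
#' @param phenotype_ids phenotypes to analyze (default: all).
#' @param ... passed to [run_pipeline()].
#' @return Named list of `pipeline_result`, one per phenotype.
#' @export
run_panel_pipeline <- function(panel, phenotype_ids = NULL, ...) {
  stopifnot(inherits(panel, "ri_panel"))
  sdps <- collapse_to_sdps(filter_informative_snps(panel$genotypes))
  mir_pos <- panel$mirna_positions
  gene_pos <- panel$gene_positions
  mirna <- collapse_replicates(panel$mirna_replicates, mir_pos)
  genes <- collapse_replicates(panel$gene_replicates, gene_pos)
  if (is.null(phenotype_ids))
    phenotype_ids <- panel$phenotypes$phenotype_ids
  out <- lapply(phenotype_ids, function(ph)
    run_pipeline(sdps, mirna, genes, panel$phenotypes, ph, ...))
  names(out) <- phenotype_ids
  out
}

#' Write cohesive quadruples or mediation summaries as TSV
#'
#' @param x a data frame (quadruple table or mediation summary).
#' @param path output file.
#' @export
write_result_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
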