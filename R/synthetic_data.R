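# Synthetic two-parent RI panel generator: LD-blocked binary genotypes,
# replicate-level Gaussian expression and phenotypes wired by known
# linear-Gaussian causal scenarios, so downstream stages have ground truth.

SCENARIOS <- c("full_mediation", "mediation_no_gene", "direct_only", "null",
               "reverse_gene_to_mirna")

# per-scenario causal wiring; coefficients are standardized path coefficients
# (pairwise correlations along single-parent chains)
scenario_edges <- function(scenario, sdp, mirna, gene, phenotype) {
  e <- switch(scenario,
    full_mediation = rbind(c(sdp, mirna, "sm"), c(mirna, gene, "mg"),
                           c(gene, phenotype, "gp")),
    mediation_no_gene = rbind(c(sdp, mirna, "sm"), c(mirna, phenotype, "mp"),
                              c(mirna, gene, "mg")),
    direct_only = rbind(c(sdp, phenotype, "sp")),
    null = NULL,
    reverse_gene_to_mirna = rbind(c(sdp, gene, "sg"), c(gene, mirna, "gm"),
                                  c(mirna, phenotype, "mp")),
    stop("unknown scenario: ", scenario))
  if (is.null(e)) {
    e <- matrix(character(), ncol = 3L)
  }
  colnames(e) <- c("from", "to", "label")
  e
}

#' Specify a simulation scenario
#'
#' Describes one SDP-miRNA-gene-phenotype quadruple under a known causal
#' wiring. Coefficients are standardized path coefficients: every node is
#' generated with marginal variance ~1 and a single-parent edge coefficient
#' equals the population correlation along that edge. Defaults (paths
#' 0.8/0.9/-0.7 at n = 60) give pairwise associations that clear the cohesive
#' screen thresholds with high power at RI-panel-like sample sizes.
#'
#' @param scenario one of `"full_mediation"` (SDP -> miRNA -> gene ->
#'   phenotype), `"mediation_no_gene"` (SDP -> miRNA -> phenotype, gene a
#'   correlated leaf of the miRNA), `"direct_only"` (SDP -> phenotype only),
#'   `"null"` (no edges) or `"reverse_gene_to_mirna"` (SDP -> gene -> miRNA ->
#'   phenotype).
#' @param n_strains number of RI strains (>= 4).
#' @param path_coefs named standardized path coefficients; entries `sm`, `mg`,
#'   `gp`, `sp`, `mp`, `sg`, `gm` are used as needed by the scenario.
#' @param noise_sds optional named per-node residual standard deviations;
#'   defaults to the values giving unit marginal variance.
#' @param replicates_per_strain biological replicates emitted per strain for
#'   the expression nodes.
#' @param replicate_sd within-strain measurement noise of a replicate.
#' @param seed integer seed.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario = "full_mediation", n_strains = 60L,
                          path_coefs = c(sm = 0.8, mg = 0.9, gp = -0.7,
                                         sp = 0.8, mp = -0.7, sg = 0.8,
                                         gm = 0.9),
                          noise_sds = NULL, replicates_per_strain = 3L,
                          replicate_sd = 0.25, seed = 1L) {
  scenario <- match.arg(scenario, SCENARIOS)
  if (n_strains < 4L) stop("n_strains must be at least 4")
  if (replicates_per_strain < 1L) stop("need at least one replicate")
  nodes <- c(sdp = "SDP_1", mirna = "miR_1", gene = "Gene_1",
             phenotype = "phenotype")
  edges <- scenario_edges(scenario, nodes["sdp"], nodes["mirna"],
                          nodes["gene"], nodes["phenotype"])
  coefs <- path_coefs[edges[, "label"]]
  if (anyNA(coefs)) stop("path_coefs missing entries for this scenario")
  if (any(!is.finite(coefs))) stop("coefficients must be finite")
  if (any(abs(coefs) >= 1))
    stop("standardized path coefficients must lie in (-1, 1)")
  cont <- unname(nodes[-1L])
  default_noise <- stats::setNames(rep(1, length(cont)), cont)
  for (v in cont) {
    b <- coefs[edges[, "to"] == v]
    if (length(b)) default_noise[v] <- sqrt(1 - sum(b^2))
  }
  if (is.null(noise_sds)) noise_sds <- default_noise
  if (!all(cont %in% names(noise_sds))) stop("noise_sds must cover all nodes")
  if (any(noise_sds < 0)) stop("noise standard deviations must be >= 0")
  structure(list(scenario = scenario, n_strains = as.integer(n_strains),
                 nodes = nodes,
                 edges = data.frame(from = edges[, "from"],
                                    to = edges[, "to"],
                                    path_coef = unname(coefs),
                                    stringsAsFactors = FALSE),
                 noise_sds = noise_sds[cont],
                 replicates_per_strain = as.integer(replicates_per_strain),
                 replicate_sd = replicate_sd, seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Ground-truth record of a simulated quadruple or panel element
#'
#' @param edges data frame with columns `from`, `to` (and optionally
#'   coefficients) over SDP/miRNA/gene/phenotype labels.
#' @param roles named role vector covering the nodes.
#' @param params list of generating parameters to carry along.
#' @return Object of class `truth_record`; construction validates that the
#'   DAG is acyclic, SDP nodes are roots and the phenotype is a sink.
#' @export
truth_record <- function(edges, roles, params = list()) {
  em <- if (nrow(edges)) cbind(edges$from, edges$to) else empty_edges()
  structure_check <- network_structure(roles, em) # validates roles + acyclic
  structure(list(true_dag = edges, roles = roles, params = params,
                 structure = structure_check),
            class = "truth_record")
}

# deterministic child seeds from one global integer seed
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  sample.int(2147483646L, n)
}

# strain-level values of one quadruple given the SDP vector; nodes sampled in
# topological order of the scenario DAG, single-parent standardized paths
# rescaled by the parent's empirical/theoretical sd so that edge coefficient
# = correlation.
sim_quadruple_values <- function(spec, S) {
  n <- length(S)
  nodes <- spec$nodes
  vals <- list()
  vals[[nodes[["sdp"]]]] <- S
  sd_of <- function(v) {
    if (v == nodes[["sdp"]]) {
      s <- stats::sd(S)
      if (s == 0) stop("degenerate SDP vector (no allele variation)")
      s
    } else 1
  }
  pending <- unname(nodes[-1L])
  while (length(pending)) {
    progressed <- FALSE
    for (v in pending) {
      e <- spec$edges[spec$edges$to == v, , drop = FALSE]
      if (!all(e$from %in% names(vals))) next # parent not yet sampled
      mu <- rep(0, n)
      for (i in seq_len(nrow(e))) {
        raw_b <- e$path_coef[i] / sd_of(e$from[i])
        mu <- mu + raw_b * vals[[e$from[i]]]
      }
      vals[[v]] <- mu + stats::rnorm(n, 0, spec$noise_sds[[v]])
      pending <- setdiff(pending, v)
      progressed <- TRUE
      break # restart the scan to keep sampling order deterministic
    }
    if (!progressed) stop("scenario wiring is not acyclic")
  }
  vals
}

replicate_table <- function(strains, values, feature, k, rep_sd) {
  data.frame(strain = rep(strains, each = k),
             replicate = rep(seq_len(k), times = length(strains)),
             value = rep(values, each = k) + stats::rnorm(length(strains) * k,
                                                          0, rep_sd),
             stringsAsFactors = FALSE,
             check.names = FALSE) -> long
  wide <- data.frame(strain = rep(strains, each = k),
                     replicate = rep(seq_len(k), times = length(strains)),
                     stringsAsFactors = FALSE)
  wide[[feature]] <- long$value
  wide
}

#' Simulate one quadruple under a causal scenario
#'
#' Draws the SDP as Bernoulli(0.5) per strain, samples the continuous nodes
#' in topological order of the scenario DAG via linear-Gaussian structural
#' equations, and emits replicate-level expression. The strain-level aligned
#' dataset (replicates collapsed by the mean) is returned alongside the
#' replicate tables and the ground-truth record.
#'
#' @param spec a [scenario_spec()].
#' @return List with `dataset` (an `aligned_dataset`), `replicates` (miRNA and
#'   gene replicate-level tables), `strain_values` (latent strain-level node
#'   values) and `truth` (a [truth_record()]).
#' @export
simulate_quadruple <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  n <- spec$n_strains
  strains <- sprintf("strain_%03d", seq_len(n))
  S <- stats::rbinom(n, 1L, 0.5)
  names(S) <- strains
  vals <- sim_quadruple_values(spec, S)
  k <- spec$replicates_per_strain
  mir_rep <- replicate_table(strains, vals[[spec$nodes[["mirna"]]]],
                             spec$nodes[["mirna"]], k, spec$replicate_sd)
  gene_rep <- replicate_table(strains, vals[[spec$nodes[["gene"]]]],
                              spec$nodes[["gene"]], k, spec$replicate_sd)
  sdp_tab <- structure(list(
    sdp_ids = spec$nodes[["sdp"]], strain_ids = strains,
    patterns = matrix(S, nrow = 1L, dimnames = list(spec$nodes[["sdp"]],
                                                    strains)),
    members = stats::setNames(list("SNP_1"), spec$nodes[["sdp"]]),
    span = data.frame(sdp_id = spec$nodes[["sdp"]], chrom = "1",
                      start = 5e6, end = 5e6, stringsAsFactors = FALSE),
    span_by_chrom = stats::setNames(
      list(data.frame(chrom = "1", start = 5e6, end = 5e6, n_snps = 1L)),
      spec$nodes[["sdp"]])), class = "sdp_table")
  mirna <- collapse_replicates(mir_rep)
  genes <- collapse_replicates(gene_rep)
  ph <- matrix(vals[[spec$nodes[["phenotype"]]]], ncol = 1L,
               dimnames = list(strains, spec$nodes[["phenotype"]]))
  dataset <- align_for_phenotype(sdp_tab, mirna, genes, phenotype_table(ph),
                                 spec$nodes[["phenotype"]])
  roles <- node_roles(sdp = spec$nodes[["sdp"]],
                      intermediate = unname(spec$nodes[c("mirna", "gene")]),
                      phenotype = spec$nodes[["phenotype"]])
  truth <- truth_record(spec$edges, roles,
                        params = list(scenario = spec$scenario,
                                      noise_sds = spec$noise_sds,
                                      replicate_sd = spec$replicate_sd,
                                      seed = spec$seed))
  list(dataset = dataset,
       replicates = list(mirna = mir_rep, gene = gene_rep),
       strain_values = vals, truth = truth)
}

#' Simulate RI-panel genotypes
#'
#' Recombinant inbred strains are mosaics of the two parental genomes. Per
#' strain and chromosome the parental origin follows a two-state Markov chain
#' along SNP order: the first SNP's origin is Bernoulli(0.5) and each
#' interval switches origin with probability `flip_prob`, producing
#' LD-blocked genotypes that collapse into strain distribution patterns. A
#' fraction of SNPs is emitted with identical parental alleles
#' (non-informative) and a small rate of missing calls, mimicking raw
#' genotype tables prior to the informative-marker filter.
#'
#' @param n_strains number of RI strains.
#' @param n_snps total SNPs, allocated to chromosomes proportionally to
#'   length.
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param flip_prob per-interval origin switch probability in [0, 0.5].
#' @param seed integer seed.
#' @param prop_noninformative fraction of SNPs with equal parental alleles.
#' @param missing_rate per-call missing probability.
#' @return A [genotype_matrix()] with nucleotide calls and parental alleles.
#' @export
simulate_ri_genotypes <- function(n_strains, n_snps = 200L,
                                  chrom_lengths = c(chr1 = 1.2e8,
                                                    chr2 = 1.2e8,
                                                    chr3 = 1.2e8),
                                  flip_prob = 0.1, seed = 1L,
                                  prop_noninformative = 0.1,
                                  missing_rate = 0.005) {
  if (flip_prob < 0 || flip_prob > 0.5)
    stop("flip_prob must lie in [0, 0.5]")
  set.seed(seed)
  strains <- sprintf("strain_%03d", seq_len(n_strains))
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  alloc <- floor(n_snps * chrom_lengths / sum(chrom_lengths))
  rem <- n_snps - sum(alloc)
  if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1L
  snp_ids <- sprintf("SNP_%05d", seq_len(n_snps))
  chroms <- rep(names(chrom_lengths), times = alloc)
  pos <- unlist(lapply(names(chrom_lengths), function(ch)
    sort(round(stats::runif(alloc[[ch]], 1, chrom_lengths[[ch]])))),
    use.names = FALSE)
  origin <- matrix(0L, n_strains, n_snps,
                   dimnames = list(strains, snp_ids))
  start <- 1L
  for (ch in names(chrom_lengths)) {
    k <- alloc[[ch]]
    if (k == 0L) next
    init <- stats::rbinom(n_strains, 1L, 0.5)
    block <- matrix(0L, n_strains, k)
    block[, 1L] <- init
    if (k > 1L) {
      flips <- matrix(stats::rbinom(n_strains * (k - 1L), 1L, flip_prob),
                      n_strains, k - 1L)
      block <- (matrix(init, n_strains, k) +
                  cbind(0L, t(apply(flips, 1L, cumsum)))) %% 2L
    }
    origin[, start:(start + k - 1L)] <- block
    start <- start + k
  }
  bases <- c("A", "C", "G", "T")
  allele_L <- sample(bases, n_snps, replace = TRUE)
  allele_S <- vapply(allele_L, function(a)
    sample(setdiff(bases, a), 1L), character(1L))
  noninf <- stats::runif(n_snps) < prop_noninformative
  allele_S[noninf] <- allele_L[noninf]
  calls <- matrix(allele_L[col(origin)], n_strains, n_snps,
                  dimnames = dimnames(origin))
  calls[origin == 1L] <- allele_S[col(origin)][origin == 1L]
  if (missing_rate > 0) {
    miss <- stats::runif(length(calls)) < missing_rate
    calls[miss] <- NA_character_
  }
  genotype_matrix(calls,
                  data.frame(snp_id = snp_ids, allele_L = allele_L,
                             allele_S = allele_S, stringsAsFactors = FALSE),
                  data.frame(snp_id = snp_ids, chrom = chroms, pos = pos,
                             stringsAsFactors = FALSE))
}

#' Simulate a full panel with embedded causal quadruples
#'
#' Generates RI genotypes, replicate-level miRNA and gene expression and
#' phenotype tables in which all background features are independent
#' Gaussian noise and `n_embedded_quadruples` quadruples are wired onto real
#' SDP loci (anchor patterns drawn from the simulated genotypes with
#' intermediate allele frequencies) according to their causal scenarios.
#' Embedded miRNA and gene features are positioned near their anchor locus,
#' emulating cis regulation.
#'
#' @param n_strains,n_mirna,n_genes,n_phenotypes panel dimensions.
#' @param n_embedded_quadruples number of causal quadruples to embed.
#' @param scenario scenario label (recycled) for the embedded quadruples.
#' @param seed global integer seed; all sub-generators derive child seeds
#'   from it.
#' @param n_snps,chrom_lengths,flip_prob genotype simulation controls.
#' @param path_coefs,replicates_per_strain,replicate_sd see [scenario_spec()].
#' @param maf_range anchor SDPs are sampled among those with allele frequency
#'   in this range.
#' @return Object of class `ri_panel` bundling the data_io-ready inputs and
#'   one [truth_record()] per embedded quadruple.
#' @export
simulate_panel <- function(n_strains = 60L, n_mirna = 60L, n_genes = 60L,
                           n_phenotypes = 2L, n_embedded_quadruples = 1L,
                           scenario = "full_mediation", seed = 1L,
                           n_snps = 180L,
                           chrom_lengths = c(chr1 = 1.2e8, chr2 = 1.2e8,
                                             chr3 = 1.2e8),
                           flip_prob = 0.1,
                           path_coefs = c(sm = 0.8, mg = 0.9, gp = -0.7,
                                          sp = 0.8, mp = -0.7, sg = 0.8,
                                          gm = 0.9),
                           replicates_per_strain = 3L, replicate_sd = 0.25,
                           maf_range = c(0.25, 0.75)) {
  if (n_embedded_quadruples > min(n_mirna, n_genes))
    stop("cannot embed more quadruples than features")
  scenario <- rep(scenario, length.out = max(n_embedded_quadruples, 1L))
  seeds <- derive_seeds(seed, 6L + max(n_embedded_quadruples, 1L))
  genotypes <- simulate_ri_genotypes(n_strains, n_snps, chrom_lengths,
                                     flip_prob, seed = seeds[1L])
  strains <- genotypes$strain_ids
  sdps <- collapse_to_sdps(filter_informative_snps(genotypes))
  set.seed(seeds[2L])
  mir_ids <- sprintf("miR_%04d", seq_len(n_mirna))
  gene_ids <- sprintf("Gene_%04d", seq_len(n_genes))
  ph_ids <- sprintf("phenotype_%d", seq_len(n_phenotypes))
  mir_strain <- matrix(stats::rnorm(n_strains * n_mirna), n_strains,
                       dimnames = list(strains, mir_ids))
  gene_strain <- matrix(stats::rnorm(n_strains * n_genes), n_strains,
                        dimnames = list(strains, gene_ids))
  ph_vals <- matrix(stats::rnorm(n_strains * n_phenotypes), n_strains,
                    dimnames = list(strains, ph_ids))
  # feature positions: background uniform over the genome
  rand_pos <- function(k) {
    ch <- sample(names(chrom_lengths), k, replace = TRUE)
    data.frame(chrom = ch,
               start = round(stats::runif(k, 1, chrom_lengths[ch])),
               stringsAsFactors = FALSE)
  }
  mir_pos <- cbind(data.frame(feature_id = mir_ids), rand_pos(n_mirna))
  gene_pos <- cbind(data.frame(feature_id = gene_ids), rand_pos(n_genes))
  # anchors: SDPs with intermediate allele frequency
  freq <- rowMeans(sdps$patterns)
  candidates <- sdps$sdp_ids[freq >= maf_range[1L] & freq <= maf_range[2L]]
  truth <- list()
  if (n_embedded_quadruples > 0L) {
    if (length(candidates) < n_embedded_quadruples)
      stop("not enough intermediate-frequency SDPs to anchor the quadruples")
    set.seed(seeds[3L])
    anchors <- sample(candidates, n_embedded_quadruples)
    emb_m <- sample(n_mirna, n_embedded_quadruples)
    emb_g <- sample(n_genes, n_embedded_quadruples)
    for (q in seq_len(n_embedded_quadruples)) {
      spec <- scenario_spec(scenario[q], n_strains = n_strains,
                            path_coefs = path_coefs,
                            replicates_per_strain = replicates_per_strain,
                            replicate_sd = replicate_sd,
                            seed = seeds[6L + q])
      set.seed(seeds[6L + q])
      S <- sdps$patterns[anchors[q], ]
      vals <- sim_quadruple_values(spec, S)
      ph_id <- ph_ids[((q - 1L) %% n_phenotypes) + 1L]
      mir_strain[, emb_m[q]] <- vals[[spec$nodes[["mirna"]]]]
      gene_strain[, emb_g[q]] <- vals[[spec$nodes[["gene"]]]]
      ph_vals[, ph_id] <- vals[[spec$nodes[["phenotype"]]]]
      # cis placement near the anchor locus
      span <- sdps$span[sdps$span$sdp_id == anchors[q], ]
      mid <- (span$start + span$end) / 2
      near <- function() max(1, round(mid + stats::runif(1, -1e7, 1e7)))
      mir_pos[emb_m[q], c("chrom", "start")] <- list(span$chrom, near())
      gene_pos[emb_g[q], c("chrom", "start")] <- list(span$chrom, near())
      edges <- spec$edges
      map <- c(stats::setNames(anchors[q], spec$nodes[["sdp"]]),
               stats::setNames(mir_ids[emb_m[q]], spec$nodes[["mirna"]]),
               stats::setNames(gene_ids[emb_g[q]], spec$nodes[["gene"]]),
               stats::setNames(ph_id, spec$nodes[["phenotype"]]))
      edges$from <- unname(map[edges$from])
      edges$to <- unname(map[edges$to])
      roles <- node_roles(sdp = anchors[q],
                          intermediate = c(mir_ids[emb_m[q]],
                                           gene_ids[emb_g[q]]),
                          phenotype = ph_id)
      truth[[q]] <- truth_record(
        edges, roles,
        params = list(scenario = scenario[q],
                      anchor_sdp = anchors[q],
                      anchor_pattern = paste(S, collapse = ""),
                      anchor_members = sdps$members[[anchors[q]]],
                      mirna_id = mir_ids[emb_m[q]],
                      gene_id = gene_ids[emb_g[q]],
                      phenotype_id = ph_id, seed = seeds[6L + q]))
    }
  }
  set.seed(seeds[4L])
  k <- replicates_per_strain
  make_reps <- function(strain_mat) {
    out <- data.frame(strain = rep(strains, each = k),
                      replicate = rep(seq_len(k), times = length(strains)),
                      stringsAsFactors = FALSE)
    noise <- matrix(stats::rnorm(nrow(out) * ncol(strain_mat), 0,
                                 replicate_sd),
                    nrow(out), ncol(strain_mat))
    vals <- strain_mat[out$strain, , drop = FALSE] + noise
    cbind(out, as.data.frame(vals))
  }
  mirna_replicates <- make_reps(mir_strain)
  gene_replicates <- make_reps(gene_strain)
  structure(list(genotypes = genotypes,
                 mirna_replicates = mirna_replicates,
                 gene_replicates = gene_replicates,
                 phenotypes = phenotype_table(ph_vals),
                 mirna_positions = mir_pos, gene_positions = gene_pos,
                 truth = truth,
                 params = list(seed = seed, n_strains = n_strains,
                               scenario = scenario, flip_prob = flip_prob,
                               replicates_per_strain = replicates_per_strain,
                               replicate_sd = replicate_sd)),
            class = "ri_panel")
}

#' @export
print.ri_panel <- function(x, ...) {
  cat(sprintf(
    "<ri_panel> %d strains, %d SNPs, %d miRNAs, %d genes, %d phenotype(s), %d embedded quadruple(s)\n",
    length(x$genotypes$strain_ids), length(x$genotypes$snp_ids),
    ncol(x$mirna_replicates) - 2L, ncol(x$gene_replicates) - 2L,
    length(x$phenotypes$phenotype_ids), length(x$truth)))
  invisible(x)
}

#' Write a simulated panel as pipeline input files
#'
#' Emits the plain-TSV dialects consumed by the readers plus the parental
#' sidecar and the ground-truth JSON. Output is byte-identical for a given
#' panel object.
#'
#' @param panel an [simulate_panel()] result.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "ri_panel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gm <- panel$genotypes
  geno <- data.frame(snp_id = gm$snp_ids,
                     chrom = gm$positions$chrom, pos = gm$positions$pos,
                     parental_L = gm$parental_alleles$allele_L,
                     parental_S = gm$parental_alleles$allele_S,
                     t(gm$alleles), stringsAsFactors = FALSE,
                     check.names = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE,
    na = "")
  wt(geno, "genotype.tsv")
  jsonlite::write_json(list(parental_L = "parental_L",
                            parental_S = "parental_S"),
                       file.path(dir, "sidecar.json"), auto_unbox = TRUE)
  wt(panel$mirna_replicates, "mirna_expression.tsv")
  wt(panel$gene_replicates, "gene_expression.tsv")
  ph <- data.frame(strain = panel$phenotypes$strain_ids,
                   panel$phenotypes$values, stringsAsFactors = FALSE,
                   check.names = FALSE)
  wt(ph, "phenotypes.tsv")
  wt(panel$mirna_positions, "mirna_positions.tsv")
  wt(panel$gene_positions, "gene_positions.tsv")
  jsonlite::write_json(lapply(panel$truth, function(tr)
    list(true_dag = tr$true_dag, params = tr$params)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read panel input files back into pipeline objects
#'
#' @param dir a directory written by [write_panel()].
#' @return List with `genotypes`, `mirna`, `genes` (replicates collapsed),
#'   `phenotypes` and `truth`.
#' @export
read_panel <- function(dir) {
  list(genotypes = read_genotype_tsv(file.path(dir, "genotype.tsv"),
                                     file.path(dir, "sidecar.json")),
       mirna = read_expression_tsv(file.path(dir, "mirna_expression.tsv"),
                                   file.path(dir, "mirna_positions.tsv")),
       genes = read_expression_tsv(file.path(dir, "gene_expression.tsv"),
                                   file.path(dir, "gene_positions.tsv")),
       phenotypes = read_phenotype_tsv(file.path(dir, "phenotypes.tsv")),
       truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = TRUE))
}
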