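# Input containers and harmonization: genotype -> informative SNPs -> SDPs,
# replicate-level expression -> strain means, per-phenotype strain alignment.

#' Construct a genotype matrix
#'
#' Strain-level SNP calls from a two-parent recombinant inbred panel. Alleles
#' are stored as the raw call characters (e.g. nucleotides) until
#' [filter_informative_snps()] recodes them 0/1 by parental origin.
#'
#' @param alleles strains x SNPs matrix (character or 0/1 numeric); rownames
#'   are strain ids, colnames SNP ids. `NA` marks a missing call.
#' @param parental_alleles data frame with columns `snp_id`, `allele_L`,
#'   `allele_S`: the calls of the two parental strains per SNP.
#' @param positions data frame with columns `snp_id`, `chrom`, `pos`
#'   (1-based base pairs).
#' @param coded set to TRUE when `alleles` are already 0 (parent-L origin) /
#'   1 (parent-S origin).
#' @return Object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(alleles, parental_alleles, positions,
                            coded = FALSE) {
  alleles <- as.matrix(alleles)
  if (is.null(rownames(alleles)) || is.null(colnames(alleles)))
    stop("alleles must have strain rownames and SNP colnames")
  snps <- colnames(alleles)
  if (!setequal(parental_alleles$snp_id, snps) ||
      anyDuplicated(parental_alleles$snp_id))
    stop("parental_alleles must cover every SNP exactly once")
  if (!all(snps %in% positions$snp_id))
    stop("every SNP needs a genomic position")
  parental_alleles <- parental_alleles[match(snps, parental_alleles$snp_id), ]
  positions <- positions[match(snps, positions$snp_id), ]
  if (coded) {
    vals <- suppressWarnings(as.numeric(alleles))
    if (!all(vals %in% c(0, 1), na.rm = TRUE))
      stop("coded alleles must be 0/1")
  }
  structure(list(strain_ids = rownames(alleles), snp_ids = snps,
                 alleles = alleles, parental_alleles = parental_alleles,
                 positions = positions, coded = coded),
            class = "genotype_matrix")
}

#' Keep informative, fully observed SNPs and recode by parental origin
#'
#' Retains exactly the SNPs whose two parental alleles differ and that have no
#' missing call in any strain (a call matching neither parental allele is
#' treated as missing). Retained SNPs are recoded 0 for the parent-L allele
#' and 1 for the parent-S allele; SNP order is preserved.
#'
#' @param genotypes a [genotype_matrix()].
#' @return A coded [genotype_matrix()] restricted to informative SNPs.
#' @export
filter_informative_snps <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  pa <- genotypes$parental_alleles
  if (anyNA(pa$allele_L) || anyNA(pa$allele_S))
    stop("parental alleles must be present for every SNP")
  al <- genotypes$alleles
  coded <- matrix(NA_real_, nrow(al), ncol(al), dimnames = dimnames(al))
  if (genotypes$coded) {
    coded[] <- suppressWarnings(as.numeric(al))
    informative <- pa$allele_L != pa$allele_S
  } else {
    for (j in seq_len(ncol(al))) {
      coded[al[, j] == pa$allele_L[j], j] <- 0
      coded[al[, j] == pa$allele_S[j], j] <- 1
    }
    informative <- pa$allele_L != pa$allele_S
  }
  complete <- colSums(is.na(coded)) == 0L
  keep <- informative & complete
  if (!any(keep)) stop("no informative markers remain")
  genotype_matrix(coded[, keep, drop = FALSE],
                  pa[keep, , drop = FALSE],
                  genotypes$positions[keep, , drop = FALSE],
                  coded = TRUE)
}

#' Collapse completely linked SNPs into strain distribution patterns
#'
#' SNPs whose 0/1 strain vectors are bit-identical are in complete linkage
#' disequilibrium (no recombination separates them in any strain) and are
#' grouped into one SDP. Complementary vectors are distinct SDPs: in a
#' two-parent RI panel a complemented pattern would imply a recombination in
#' every strain. Each SDP records its member SNPs and genomic span; an SDP
#' whose members sit on several chromosomes is assigned to the majority
#' chromosome for locus grouping and a warning is issued.
#'
#' @param genotypes a coded [genotype_matrix()] (see
#'   [filter_informative_snps()]).
#' @return Object of class `sdp_table` with fields `sdp_ids`, `patterns`
#'   (SDPs x strains 0/1 matrix), `members` (list of SNP ids), `span`
#'   (majority-chromosome span per SDP) and `span_by_chrom`.
#' @export
collapse_to_sdps <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!genotypes$coded)
    stop("genotypes must be informative-filtered and 0/1 coded")
  al <- genotypes$alleles
  keys <- apply(al, 2L, paste, collapse = "")
  first <- !duplicated(keys)
  uniq_keys <- keys[first]
  sdp_ids <- sprintf("SDP_%04d", seq_along(uniq_keys))
  group <- match(keys, uniq_keys)
  members <- split(genotypes$snp_ids, group)
  names(members) <- sdp_ids
  patterns <- t(al[, first, drop = FALSE])
  rownames(patterns) <- sdp_ids
  pos <- genotypes$positions
  span_rows <- vector("list", length(sdp_ids))
  span_by_chrom <- vector("list", length(sdp_ids))
  names(span_by_chrom) <- sdp_ids
  multi <- character()
  for (i in seq_along(sdp_ids)) {
    p <- pos[pos$snp_id %in% members[[i]], , drop = FALSE]
    by_chrom <- do.call(rbind, lapply(split(p, p$chrom), function(x)
      data.frame(chrom = x$chrom[1L], start = min(x$pos), end = max(x$pos),
                 n_snps = nrow(x), stringsAsFactors = FALSE)))
    rownames(by_chrom) <- NULL
    span_by_chrom[[i]] <- by_chrom
    maj <- by_chrom[which.max(by_chrom$n_snps), , drop = FALSE]
    if (nrow(by_chrom) > 1L) multi <- c(multi, sdp_ids[i])
    span_rows[[i]] <- data.frame(sdp_id = sdp_ids[i], chrom = maj$chrom,
                                 start = maj$start, end = maj$end,
                                 stringsAsFactors = FALSE)
  }
  if (length(multi))
    warning(sprintf(
      "%d SDP(s) span multiple chromosomes (%s); assigned to majority chromosome",
      length(multi), paste(multi, collapse = ", ")))
  structure(list(sdp_ids = sdp_ids, strain_ids = genotypes$strain_ids,
                 patterns = patterns, members = members,
                 span = do.call(rbind, span_rows),
                 span_by_chrom = span_by_chrom),
            class = "sdp_table")
}

#' Construct an expression matrix
#'
#' @param values strains x features numeric matrix (variance-stabilized or
#'   log2 scale), rownames strain ids, colnames feature ids.
#' @param positions optional data frame with columns `feature_id`, `chrom`,
#'   `start`.
#' @return Object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, positions = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have strain rownames and feature colnames")
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  structure(list(strain_ids = rownames(values),
                 feature_ids = colnames(values),
                 values = values, positions = positions),
            class = "expression_matrix")
}

#' Average expression replicates within strains
#'
#' Collapses replicate-level expression to one value per strain and feature,
#' the arithmetic mean over biological replicates (the strain summary used
#' for all downstream statistics).
#'
#' @param replicates data frame whose first two columns are `strain` and
#'   `replicate`, followed by one numeric column per feature.
#' @param positions optional feature position table, passed through.
#' @return An [expression_matrix()] with one row per strain.
#' @export
collapse_replicates <- function(replicates, positions = NULL) {
  replicates <- as.data.frame(replicates)
  if (!all(c("strain", "replicate") %in% names(replicates)[1:2]))
    stop("first two columns must be 'strain' and 'replicate'")
  feats <- names(replicates)[-(1:2)]
  if (!length(feats)) stop("no feature columns")
  vals <- as.matrix(replicates[feats])
  if (anyNA(vals)) stop("a strain lacks replicates for some feature")
  g <- as.character(replicates$strain)
  means <- rowsum(vals, group = g) / as.vector(table(g))
  # rowsum orders groups by sort(unique(group)); restore first-appearance order
  means <- means[match(unique(g), rownames(means)), , drop = FALSE]
  expression_matrix(means, positions)
}

#' Construct a phenotype table
#'
#' @param values strains x phenotypes numeric matrix; `NA` marks strains not
#'   measured for a phenotype. Each phenotype must keep at least 3 non-missing
#'   strains.
#' @return Object of class `phenotype_table`.
#' @export
phenotype_table <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have strain rownames and phenotype colnames")
  n_ok <- colSums(!is.na(values))
  if (any(n_ok < 3L))
    stop(sprintf("phenotype(s) with fewer than 3 measured strains: %s",
                 paste(colnames(values)[n_ok < 3L], collapse = ", ")))
  structure(list(strain_ids = rownames(values),
                 phenotype_ids = colnames(values), values = values),
            class = "phenotype_table")
}

restrict_sdp_table <- function(sdps, strains) {
  sdps$patterns <- sdps$patterns[, strains, drop = FALSE]
  sdps$strain_ids <- strains
  sdps
}

#' Align all data sources on a phenotype's strain set
#'
#' Restricts SDP genotypes, miRNA expression, gene expression and one
#' phenotype to the strains present in every source with a non-missing
#' phenotype value, in a common strain order. The resulting sample size `n`
#' is the n of the network BIC.
#'
#' @param sdps an `sdp_table`.
#' @param mirna,genes [expression_matrix()] objects.
#' @param phenotypes a [phenotype_table()].
#' @param phenotype_id which phenotype column to analyze.
#' @return Object of class `aligned_dataset` with the strain-intersected
#'   components, the strain-by-node data and `n`.
#' @export
align_for_phenotype <- function(sdps, mirna, genes, phenotypes, phenotype_id) {
  stopifnot(inherits(sdps, "sdp_table"),
            inherits(mirna, "expression_matrix"),
            inherits(genes, "expression_matrix"),
            inherits(phenotypes, "phenotype_table"))
  if (!phenotype_id %in% phenotypes$phenotype_ids)
    stop("unknown phenotype: ", phenotype_id)
  ph_all <- phenotypes$values[, phenotype_id]
  measured <- phenotypes$strain_ids[!is.na(ph_all)]
  strains <- Reduce(intersect, list(sdps$strain_ids, mirna$strain_ids,
                                    genes$strain_ids, measured))
  strains <- sort(strains)
  if (length(strains) < 4L)
    stop(sprintf("only %d strain(s) shared across sources for %s; need >= 4",
                 length(strains), phenotype_id))
  ids <- c(sdps$sdp_ids, mirna$feature_ids, genes$feature_ids, phenotype_id)
  if (anyDuplicated(ids))
    stop("SDP, miRNA, gene and phenotype identifiers must not collide")
  mir_v <- mirna$values[strains, , drop = FALSE]
  gene_v <- genes$values[strains, , drop = FALSE]
  ph <- phenotypes$values[strains, phenotype_id]
  names(ph) <- strains
  if (anyNA(mir_v) || anyNA(gene_v))
    stop("aligned expression values contain missing entries")
  structure(list(strain_ids = strains,
                 sdps = restrict_sdp_table(sdps, strains),
                 mirna = expression_matrix(mir_v, mirna$positions),
                 genes = expression_matrix(gene_v, genes$positions),
                 phenotype = ph, phenotype_id = phenotype_id,
                 n = length(strains)),
            class = "aligned_dataset")
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat(sprintf(
    "<aligned_dataset> %s: n = %d strains, %d SDPs, %d miRNAs, %d genes\n",
    x$phenotype_id, x$n, nrow(x$sdps$patterns),
    length(x$mirna$feature_ids), length(x$genes$feature_ids)))
  invisible(x)
}

# strains x nodes numeric matrix for an arbitrary node subset of an aligned
# dataset (SDP patterns are transposed into columns).
node_matrix <- function(dataset, nodes) {
  stopifnot(inherits(dataset, "aligned_dataset"))
  cols <- lapply(nodes, function(v) {
    if (v %in% dataset$sdps$sdp_ids) return(dataset$sdps$patterns[v, ])
    if (v %in% dataset$mirna$feature_ids) return(dataset$mirna$values[, v])
    if (v %in% dataset$genes$feature_ids) return(dataset$genes$values[, v])
    if (identical(v, dataset$phenotype_id)) return(dataset$phenotype)
    stop("unknown node: ", v)
  })
  m <- do.call(cbind, cols)
  dimnames(m) <- list(dataset$strain_ids, nodes)
  m
}

node_role_of <- function(dataset, v) {
  if (v %in% dataset$sdps$sdp_ids) ROLE_SDP
  else if (identical(v, dataset$phenotype_id)) ROLE_PHENOTYPE
  else ROLE_INTERMEDIATE
}

# ---- file readers (plain TSV dialect + JSON sidecar) ------------------------

#' Read a genotype TSV and its sidecar
#'
#' Dialect: first column SNP id, columns 2-3 chromosome and position, one
#' column per strain thereafter. The JSON sidecar declares which two columns
#' are the parental strains, e.g.
#' `{"parental_L": "ILS", "parental_S": "ISS"}`.
#'
#' @param file genotype TSV path.
#' @param sidecar path to the JSON sidecar.
#' @return A [genotype_matrix()] over the non-parental strains.
#' @export
read_genotype_tsv <- function(file, sidecar) {
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  tab <- utils::read.table(file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  snp_ids <- as.character(tab[[1L]])
  positions <- data.frame(snp_id = snp_ids, chrom = as.character(tab[[2L]]),
                          pos = as.numeric(tab[[3L]]),
                          stringsAsFactors = FALSE)
  calls <- as.matrix(tab[, -(1:3), drop = FALSE])
  rownames(calls) <- snp_ids
  pl <- side$parental_L; ps <- side$parental_S
  if (is.null(pl) || is.null(ps) || !all(c(pl, ps) %in% colnames(calls)))
    stop("sidecar must name parental_L and parental_S strain columns")
  parental <- data.frame(snp_id = snp_ids,
                         allele_L = as.character(calls[, pl]),
                         allele_S = as.character(calls[, ps]),
                         stringsAsFactors = FALSE)
  panel <- t(calls[, setdiff(colnames(calls), c(pl, ps)), drop = FALSE])
  genotype_matrix(panel, parental, positions)
}

#' Read an expression TSV
#'
#' Accepts either the replicate-level layout (`strain`, `replicate`, one
#' column per feature), which is collapsed to strain means, or a pre-collapsed
#' strain x feature matrix whose first column is `strain`.
#'
#' @param file expression TSV path.
#' @param positions_file optional TSV with columns `feature_id`, `chrom`,
#'   `start`.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(file, positions_file = NULL) {
  tab <- utils::read.table(file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  positions <- NULL
  if (!is.null(positions_file))
    positions <- utils::read.table(positions_file, header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE)
  if (identical(names(tab)[2L], "replicate")) {
    names(tab)[1L] <- "strain"
    return(collapse_replicates(tab, positions))
  }
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(vals) <- as.character(tab[[1L]])
  expression_matrix(vals, positions)
}

#' Read a phenotype TSV
#'
#' Strain x phenotype matrix; the first column holds strain ids and empty
#' cells are missing values.
#'
#' @param file phenotype TSV path.
#' @return A [phenotype_table()].
#' @export
read_phenotype_tsv <- function(file) {
  tab <- utils::read.table(file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(vals) <- as.character(tab[[1L]])
  phenotype_table(vals)
}
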