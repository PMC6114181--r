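test_that("informative filter drops monomorphic and incomplete SNPs and recodes by parental origin", {
  strains <- c("s1", "s2", "s3", "s4")
  alleles <- cbind(
    snp_same = c("A", "A", "A", "A"),      # parents share the allele
    snp_miss = c("A", NA, "G", "G"),       # one missing call
    snp_ok   = c("A", "G", "G", "A"),      # informative, complete
    snp_alien = c("A", "T", "G", "G"))     # 'T' matches neither parent
  rownames(alleles) <- strains
  gm <- genotype_matrix(
    alleles,
    data.frame(snp_id = colnames(alleles),
               allele_L = c("A", "A", "A", "A"),
               allele_S = c("A", "G", "G", "G")),
    data.frame(snp_id = colnames(alleles), chrom = "1",
               pos = c(100, 200, 300, 400)))
  filt <- filter_informative_snps(gm)
  expect_identical(filt$snp_ids, "snp_ok")
  expect_identical(unname(filt$alleles[, "snp_ok"]), c(0, 1, 1, 0))
  expect_true(filt$coded)

  gm_bad <- genotype_matrix(
    alleles[, 1, drop = FALSE],
    data.frame(snp_id = "snp_same", allele_L = "A", allele_S = "A"),
    data.frame(snp_id = "snp_same", chrom = "1", pos = 100))
  expect_error(filter_informative_snps(gm_bad), "no informative")
})

make_coded_gm <- function(patterns, chrom = NULL, pos = NULL) {
  # patterns: list of strain vectors, one per SNP
  al <- do.call(cbind, patterns)
  colnames(al) <- sprintf("snp%d", seq_along(patterns))
  rownames(al) <- sprintf("s%d", seq_len(nrow(al)))
  k <- length(patterns)
  genotype_matrix(al,
                  data.frame(snp_id = colnames(al), allele_L = "A",
                             allele_S = "G"),
                  data.frame(snp_id = colnames(al),
                             chrom = chrom %||% rep("1", k),
                             pos = pos %||% seq_len(k) * 1000),
                  coded = TRUE)
}

test_that("SDP collapsing groups bit-identical strain vectors", {
  gm <- make_coded_gm(list(c(0, 0, 1, 1), c(0, 0, 1, 1), c(0, 1, 0, 1),
                           c(0, 1, 0, 1), c(0, 0, 1, 1)))
  sdps <- collapse_to_sdps(gm)
  expect_length(sdps$sdp_ids, 2L)
  expect_setequal(lengths(sdps$members), c(3L, 2L))
  expect_identical(sum(lengths(sdps$members)), 5L) # partition of all SNPs
  expect_identical(unname(sdps$patterns[1, ]), c(0, 0, 1, 1))
  expect_identical(unname(sdps$patterns[2, ]), c(0, 1, 0, 1))
  # spans cover member positions
  expect_equal(sdps$span$start, c(1000, 3000))
  expect_equal(sdps$span$end, c(5000, 4000))

  # complementary patterns are distinct SDPs
  gm2 <- make_coded_gm(list(c(0, 0, 1, 1), c(1, 1, 0, 0)))
  expect_length(collapse_to_sdps(gm2)$sdp_ids, 2L)

  # all-identical vectors give a single SDP
  gm3 <- make_coded_gm(list(c(0, 1, 1, 0), c(0, 1, 1, 0), c(0, 1, 1, 0)))
  expect_length(collapse_to_sdps(gm3)$sdp_ids, 1L)
})

test_that("SDP collapsing is idempotent on its own patterns", {
  gm <- make_coded_gm(list(c(0, 0, 1, 1), c(0, 0, 1, 1), c(0, 1, 0, 1),
                           c(1, 1, 1, 0), c(0, 1, 0, 1)))
  sdps <- collapse_to_sdps(gm)
  gm_again <- make_coded_gm(
    lapply(seq_len(nrow(sdps$patterns)), function(i) sdps$patterns[i, ]))
  again <- collapse_to_sdps(gm_again)
  expect_identical(unname(again$patterns), unname(sdps$patterns))
  expect_length(again$sdp_ids, length(sdps$sdp_ids))
})

test_that("multi-chromosome SDPs warn and take the majority chromosome", {
  gm <- make_coded_gm(list(c(0, 1, 0, 1), c(0, 1, 0, 1), c(0, 1, 0, 1)),
                      chrom = c("1", "1", "2"), pos = c(100, 500, 900))
  expect_warning(sdps <- collapse_to_sdps(gm), "multiple chromosomes")
  expect_identical(sdps$span$chrom, "1")
  expect_identical(nrow(sdps$span_by_chrom[[1]]), 2L)
})

test_that("replicate collapsing averages within strains and commutes with row order", {
  reps <- data.frame(strain = c("a", "a", "b", "c", "c", "c"),
                     replicate = c(1, 2, 1, 1, 2, 3),
                     f1 = c(2, 4, 7.5, 1, 2, 9),
                     f2 = c(0, 1, -3, 2, 2, 2))
  em <- collapse_replicates(reps)
  expect_equal(unname(em$values[, "f1"]), c(3, 7.5, 4))
  expect_equal(unname(em$values[, "f2"]), c(0.5, -3, 2))

  shuffled <- reps[c(5, 1, 6, 3, 2, 4), ]
  em2 <- collapse_replicates(shuffled)
  expect_equal(em2$values[rownames(em$values), ], em$values)

  reps_na <- reps
  reps_na$f1[2] <- NA
  expect_error(collapse_replicates(reps_na), "lacks replicates")
})

test_that("alignment keeps the strain intersection with measured phenotypes", {
  genomic <- sprintf("s%02d", 1:59)
  set.seed(42)
  S <- matrix(rbinom(59 * 3, 1, 0.5), 59, dimnames = list(genomic, c("d1", "d2", "d3")))
  M <- matrix(rnorm(59 * 2), 59, dimnames = list(genomic, c("m1", "m2")))
  G <- matrix(rnorm(59 * 2), 59, dimnames = list(genomic, c("g1", "g2")))
  # phenotype measured on a 33-strain subset
  ph_strains <- genomic[1:33]
  pv <- matrix(NA_real_, 59, 1, dimnames = list(genomic, "did"))
  pv[ph_strains, 1] <- rnorm(33)
  ds <- align_for_phenotype(make_sdp_table(S), expression_matrix(M),
                            expression_matrix(G), phenotype_table(pv), "did")
  expect_identical(ds$n, 33L)
  expect_setequal(ds$strain_ids, ph_strains)
  expect_false(anyNA(ds$phenotype))

  # phenotype superset of the genomic strains -> n limited by genomics
  extra <- c(genomic, "s_extra")
  pv2 <- matrix(rnorm(60), 60, 1, dimnames = list(extra, "p"))
  ds2 <- align_for_phenotype(make_sdp_table(S), expression_matrix(M),
                             expression_matrix(G), phenotype_table(pv2), "p")
  expect_identical(ds2$n, 59L)

  # disjoint strain sets -> error
  rownames(pv2) <- sprintf("x%02d", 1:60)
  expect_error(
    align_for_phenotype(make_sdp_table(S), expression_matrix(M),
                        expression_matrix(G), phenotype_table(pv2), "p"),
    "need >= 4")
})

test_that("alignment output is invariant to input strain order", {
  strains <- sprintf("s%02d", 1:20)
  set.seed(7)
  S <- matrix(rbinom(20 * 2, 1, 0.5), 20, dimnames = list(strains, c("d1", "d2")))
  M <- matrix(rnorm(20), 20, dimnames = list(strains, "m1"))
  G <- matrix(rnorm(20), 20, dimnames = list(strains, "g1"))
  y <- matrix(rnorm(20), 20, dimnames = list(strains, "p"))
  a <- align_for_phenotype(make_sdp_table(S), expression_matrix(M),
                           expression_matrix(G), phenotype_table(y), "p")
  perm <- sample(20)
  b <- align_for_phenotype(make_sdp_table(S[perm, ]),
                           expression_matrix(M[rev(perm), , drop = FALSE]),
                           expression_matrix(G), phenotype_table(y), "p")
  expect_identical(a$strain_ids, b$strain_ids)
  expect_identical(a$mirna$values, b$mirna$values)
  expect_identical(unname(a$sdps$patterns), unname(b$sdps$patterns))
})

test_that("genotype, expression and phenotype TSV round-trips preserve values", {
  panel <- simulate_panel(n_strains = 12, n_mirna = 4, n_genes = 4,
                          n_phenotypes = 1, n_embedded_quadruples = 0,
                          n_snps = 30, seed = 5)
  dir <- withr::local_tempdir()
  write_panel(panel, dir)
  back <- read_panel(dir)
  expect_identical(back$genotypes$snp_ids, panel$genotypes$snp_ids)
  expect_identical(back$genotypes$alleles, panel$genotypes$alleles)
  mir <- collapse_replicates(panel$mirna_replicates)
  expect_equal(back$mirna$values, mir$values, tolerance = 1e-12)
  expect_equal(back$phenotypes$values, panel$phenotypes$values,
               tolerance = 1e-12)
})
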