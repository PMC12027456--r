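toy_matrix <- function(geno, samples = sprintf("S%02d", seq_len(nrow(geno))),
                       chrom = "chr1") {
  nv <- ncol(geno)
  variants <- data.frame(chrom = chrom, pos = seq(100, by = 50, length.out = nv),
                         ref = rep("A", nv), alt = rep("G", nv),
                         stringsAsFactors = FALSE)
  snp_matrix(variants, samples, geno)
}

test_that("snp_matrix validation catches malformed input", {
  g <- matrix(0L, 2, 2)
  v <- data.frame(chrom = "c", pos = c(10L, 10L), ref = "A", alt = "G")
  expect_error(snp_matrix(v, c("a", "b"), g), "strictly increasing")
  v2 <- data.frame(chrom = "c", pos = c(10L, 20L), ref = "A", alt = "G,T")
  expect_error(snp_matrix(v2, c("a", "b"), g), "biallelic")
  expect_error(toy_matrix(matrix(5L, 2, 2)), "codes")
})

test_that("filtering drops het/missing/H0 samples with a complete log", {
  g <- rbind(c(0L, 1L, 0L), c(0L, 2L, 0L), c(3L, 1L, 1L), c(1L, 1L, 1L))
  m <- toy_matrix(g)
  res <- filter_samples(m, h0_carriers = "S04")
  expect_identical(res$matrix$samples, "S01")
  expect_setequal(res$log$sample_id, c("S02", "S03", "S04"))
  expect_identical(res$log$reason[res$log$sample_id == "S02"], "het")
  expect_identical(res$log$reason[res$log$sample_id == "S03"], "missing")
  expect_identical(res$log$reason[res$log$sample_id == "S04"], "h0_deletion")
  # conservation: excluded + retained = input
  expect_identical(nrow(res$log) + length(res$matrix$samples),
                   length(m$samples))
  # clean matrix passes through unchanged
  clean <- toy_matrix(rbind(c(0L, 1L), c(1L, 0L)))
  res2 <- filter_samples(clean)
  expect_identical(res2$matrix$geno, clean$geno)
  expect_identical(nrow(res2$log), 0L)
  # everything excluded: empty matrix, complete log, no exception
  allhet <- toy_matrix(matrix(2L, 3, 2))
  res3 <- filter_samples(allhet)
  expect_identical(length(res3$matrix$samples), 0L)
  expect_identical(nrow(res3$log), 3L)
})

test_that("collapsing orders labels by carrier count with stable ties", {
  g <- rbind(matrix(rep(c(0L, 0L), 5), ncol = 2, byrow = TRUE),
             matrix(rep(c(1L, 0L), 3), ncol = 2, byrow = TRUE),
             matrix(rep(c(1L, 1L), 2), ncol = 2, byrow = TRUE))
  m <- toy_matrix(g)
  hs <- collapse_haplotypes(m)
  expect_identical(hs$table$label, c("H1", "H2", "H3"))
  expect_identical(hs$table$n_carriers, c(5L, 3L, 2L))
  expect_identical(length(hs$carriers$H1), 5L)
  # all identical -> single haplotype
  one <- collapse_haplotypes(toy_matrix(matrix(0L, 4, 3)))
  expect_identical(one$table$label, "H1")
  # H0 is attached with its carrier count, no allele vector
  hs0 <- collapse_haplotypes(m, h0_carriers = c("X1", "X2"))
  expect_identical(hs0$table$label[1], "H0")
  expect_identical(hs0$table$n_carriers[1], 2L)
  expect_false("H0" %in% rownames(hs0$alleles))
  # sum of carriers = retained samples
  expect_identical(sum(hs$table$n_carriers), nrow(g))
  # unfiltered matrix is rejected
  expect_error(collapse_haplotypes(toy_matrix(matrix(2L, 2, 2))),
               "filter_samples")
})

test_that("the haplotype partition is invariant to sample order", {
  set.seed(71)
  g <- matrix(sample(0:1, 60, replace = TRUE), nrow = 15)
  m <- toy_matrix(g)
  hs1 <- collapse_haplotypes(m)
  perm <- sample(15)
  m2 <- toy_matrix(g[perm, , drop = FALSE],
                   samples = sprintf("S%02d", seq_len(15))[perm])
  hs2 <- collapse_haplotypes(m2)
  part1 <- lapply(hs1$carriers, sort)
  part2 <- lapply(hs2$carriers, sort)
  expect_setequal(unname(vapply(part1, paste, "", collapse = ",")),
                  unname(vapply(part2, paste, "", collapse = ",")))
  expect_identical(hs1$table$n_carriers, hs2$table$n_carriers)
})

test_that("generator founders are recovered exactly without noise", {
  cfg <- sim_config(seed = 72, n_accessions = 80L, locus_length = 40000L,
                    deletion_span_length = 20000L, het_rate = 0,
                    missing_rate = 0)
  locus <- simulate_reference(cfg)
  snp <- simulate_snp_matrix(cfg, locus)
  hs <- collapse_haplotypes(snp$matrix)
  expect_identical(nrow(hs$table), cfg$haplotype_count)
  # carriers of one haplotype share one founder in truth
  for (lab in hs$table$label) {
    founders <- snp$truth$founder[match(hs$carriers[[lab]],
                                        snp$truth$sample_id)]
    expect_identical(length(unique(founders)), 1L)
  }
})

test_that("subpopulation frequencies sum to one and keep unassigned carriers", {
  g <- rbind(c(0L, 0L), c(0L, 0L), c(1L, 0L), c(1L, 1L))
  m <- toy_matrix(g)
  hs <- collapse_haplotypes(m)
  meta <- data.frame(sample_id = c("S01", "S02", "S03"),
                     subpopulation = c("XI", "GJ", "XI"))
  tab <- subpop_frequencies(hs, meta)   # S04 missing from metadata
  expect_true("unassigned" %in% tab$subpopulation)
  sums <- tapply(tab$proportion, tab$subpopulation, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # single subpopulation: proportions equal global frequencies
  meta_all <- data.frame(sample_id = sprintf("S%02d", 1:4),
                         subpopulation = "XI")
  tab2 <- subpop_frequencies(hs, meta_all)
  expect_equal(tab2$proportion[order(tab2$haplotype)],
               c(2, 1, 1) / 4)
  # empty haplotype set
  empty <- structure(list(table = data.frame(), alleles = matrix(0L, 0, 0),
                          carriers = list(), variants = data.frame()),
                     class = "haplotype_set")
  expect_identical(nrow(subpop_frequencies(empty, meta)), 0L)
})

test_that("planted founder-subpopulation association is recovered", {
  cfg <- sim_config(seed = 73, n_accessions = 120L, locus_length = 40000L,
                    deletion_span_length = 20000L, het_rate = 0,
                    missing_rate = 0, subpop_confusion = 0)
  locus <- simulate_reference(cfg)
  snp <- simulate_snp_matrix(cfg, locus)
  hs <- collapse_haplotypes(snp$matrix)
  tab <- subpop_frequencies(hs, snp$metadata)
  # with zero confusion every haplotype's carriers sit in exactly one subpop
  for (lab in hs$table$label) {
    nz <- tab$count[tab$haplotype == lab] > 0
    expect_identical(sum(nz), 1L)
  }
})

test_that("NJ solves the 3-taxon closed form and recovers 4-taxon topology", {
  d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("H1", "H2", "H3"), c("H1", "H2", "H3")))
  tr <- nj_tree(d3)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  # closed form: (d12 + d13 - d23)/2 etc.
  expect_equal(unname(bl["H1"]), 1)
  expect_equal(unname(bl["H2"]), 1)
  expect_equal(unname(bl["H3"]), 3)
  d4 <- additive_4taxon()
  tr4 <- nj_tree(d4)
  truth4 <- ape::read.tree(text = "((A:2,B:3):4,(C:2,D:5));")
  expect_identical(as.integer(phangorn::RF.dist(ape::unroot(tr4),
                                                ape::unroot(truth4))), 0L)
  # additive distances are reproduced on the tree exactly
  expect_equal(as.matrix(ape::cophenetic.phylo(tr4))[rownames(d4), rownames(d4)],
               d4)
  expect_warning(nj_tree(d3[1:2, 1:2]), "degenerate")
})

test_that("hamming distances and newick output are consistent", {
  g <- rbind(c(0L, 0L, 0L, 0L), c(0L, 0L, 1L, 1L), c(1L, 1L, 1L, 1L))
  m <- toy_matrix(g)
  hs <- collapse_haplotypes(m)
  d <- hap_distance(hs)
  expect_identical(d["H1", "H2"], 2L)
  expect_identical(d["H1", "H3"], 4L)
  expect_identical(d["H2", "H3"], 2L)
  f <- tempfile(fileext = ".nwk")
  write_newick(nj_tree(d), f)
  back <- ape::read.tree(f)
  expect_setequal(back$tip.label, c("H1", "H2", "H3"))
})
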