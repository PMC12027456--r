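test_that("representative variants are categorised correctly", {
  set.seed(81)
  loc <- make_toy_locus(exon_lens = c(120, 90), intron_len = 40, flank = 60)
  ex <- loc$gene$exons
  intron <- c(ex[1, "end"] + 1, ex[2, "start"] - 1)
  # third-position synonymous change: find a codon where it is synonymous
  cds <- cds_seq(loc)
  found <- FALSE
  for (ci in 2:30) {
    p3 <- (ci - 1) * 3 + 3                     # CDS position of 3rd base
    pos <- ex[1, "start"] + p3 - 1
    if (p3 > 120) break
    refb <- substr(loc$sequence, pos, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), refb)) {
      e <- annotate_variant(list(pos = pos, ref = refb, alt = alt), loc)
      if (e$category == "synonymous") { found <- TRUE; break }
    }
    if (found) break
  }
  expect_true(found)
  # acceptor A (second-to-last intron base) mutated -> splice_acceptor
  accA <- intron[2] - 1
  e <- annotate_variant(list(pos = accA, ref = "A", alt = "C"), loc)
  expect_identical(e$category, "splice_acceptor")
  # donor G (first intron base) -> splice_donor
  e <- annotate_variant(
    list(pos = intron[1], ref = substr(loc$sequence, intron[1], intron[1]),
         alt = "A"), loc)
  expect_identical(e$category, "splice_donor")
  # deep intron -> intronic; flank -> intergenic
  mid <- intron[1] + 10
  e <- annotate_variant(
    list(pos = mid, ref = substr(loc$sequence, mid, mid), alt = "C"), loc)
  expect_true(e$category %in% "intronic")
  e <- annotate_variant(list(pos = 5,
                             ref = substr(loc$sequence, 5, 5), alt = "C"), loc)
  expect_identical(e$category, "intergenic")
  # coding indels by frame arithmetic
  cp <- ex[1, "start"] + 30
  rb <- substr(loc$sequence, cp, cp + 1)
  e <- annotate_variant(list(pos = cp, ref = rb, alt = substr(rb, 1, 1)), loc)
  expect_identical(e$category, "frameshift_indel")
  rb3 <- substr(loc$sequence, cp, cp + 3)
  e <- annotate_variant(list(pos = cp, ref = rb3, alt = substr(rb3, 1, 1)), loc)
  expect_identical(e$category, "inframe_indel")
  # reference mismatch is an error naming the position
  expect_error(annotate_variant(list(pos = 5, ref = "Z", alt = "A"), loc),
               "position 5")
})

test_that("annotation matches the brute-force re-splice-and-translate oracle", {
  set.seed(82)
  loc <- make_toy_locus(exon_lens = c(60, 45), intron_len = 30, flank = 40)
  for (pos in seq_len(nchar(loc$sequence))) {
    refb <- substr(loc$sequence, pos, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), refb)) {
      got <- annotate_variant(list(pos = pos, ref = refb, alt = alt),
                              loc)$category
      expect_identical(got, oracle_effect(loc, pos, alt),
                       info = sprintf("pos %d %s>%s", pos, refb, alt))
    }
  }
})

test_that("minus-strand genes are annotated on the coding-strand view", {
  set.seed(83)
  sense <- names(oracle_codon_table)[oracle_codon_table != "*"]
  cds <- paste0("ATG", paste(sample(sense, 28, replace = TRUE), collapse = ""),
                "TGA")
  exon1 <- substr(cds, 1, 45)
  exon2 <- substr(cds, 46, 90)
  intron <- paste0("GT", rand_dna(26), "AG")
  loc <- make_custom_locus(exon1, intron, exon2, rand_dna(30), rand_dna(30),
                           strand = "-")
  # reference translates cleanly through the minus-strand path
  prot <- as.character(translate_cds(cds_seq(loc)))
  expect_identical(prot, oracle_translate(cds))
  ex <- loc$gene$exons
  # genomic intron: its first two plus-strand bases are the acceptor (CT on
  # plus = AG on coding strand); its last two are the donor
  gi <- c(ex[1, "end"] + 1, ex[2, "start"] - 1)
  e <- annotate_variant(
    list(pos = gi[1] + 1, ref = substr(loc$sequence, gi[1] + 1, gi[1] + 1),
         alt = "G"), loc)
  expect_identical(e$category, "splice_acceptor")
  e <- annotate_variant(
    list(pos = gi[2], ref = substr(loc$sequence, gi[2], gi[2]), alt = "T"),
    loc)
  expect_identical(e$category, "splice_donor")
  # a plus-strand base change is complemented into the codon
  p <- ex[2, "end"] - 3                       # inside exon1 of the transcript
  refb <- substr(loc$sequence, p, p)
  alt <- setdiff(c("A", "C", "G", "T"), refb)[1]
  e <- annotate_variant(list(pos = p, ref = refb, alt = alt), loc)
  expect_true(e$category %in% c("synonymous", "nonsynonymous",
                                "premature_stop"))
})

test_that("cryptic acceptor choice follows the nearest downstream AG", {
  # exon2 begins TTTTTAG...: first AG at offsets (6,7) -> 7 bp lost
  exon1 <- paste0("ATG", strrep("GCT", 9))                  # 30 nt
  intron <- paste0("GT", strrep("TC", 10), "CAG")           # ends ..AG
  exon2 <- paste0("TTTTTAG", "GCTGCTGCTGCTGCA", "TGATT")    # 27 nt
  loc <- make_custom_locus(exon1, intron, exon2, rand_dna(25), rand_dna(25))
  accA <- loc$gene$exons[2, "start"] - 2
  expect_identical(substr(loc$sequence, accA, accA + 1), "AG")
  v <- list(pos = accA, ref = "A", alt = "C")
  out <- predict_cryptic_splice(loc, acceptor_variant = v)
  expect_identical(out$status, "ok")
  expect_identical(out$cdna_delta_bp, -7L)
  expect_true(out$frameshift)
  # 6 bp loss: in-frame
  exon2b <- paste0("TTTTAG", "GCTGCTGCTGCTGCA", "TGATTT")
  locb <- make_custom_locus(exon1, intron, exon2b, rand_dna(25), rand_dna(25))
  outb <- predict_cryptic_splice(locb, acceptor_variant = v)
  expect_identical(outb$cdna_delta_bp, -6L)
  expect_false(outb$frameshift)
  # frameshift verdict is consistent with the mod-3 arithmetic of the delta
  expect_identical(out$frameshift, abs(out$cdna_delta_bp) %% 3 != 0)
  expect_identical(outb$frameshift, abs(outb$cdna_delta_bp) %% 3 != 0)
  # no downstream AG within the scan window -> unresolved, no guess
  exon2c <- paste0(strrep("T", 30), "TAA")
  locc <- make_custom_locus(exon1, intron, exon2c, rand_dna(25), rand_dna(25))
  outc <- predict_cryptic_splice(locc, acceptor_variant = v, max_scan = 20)
  expect_identical(outc$status, "exon_skip_unresolved")
  # the reference acceptor yields delta 0 and the reference protein
  ref_out <- predict_cryptic_splice(loc, acceptor_variant = NULL)
  expect_identical(ref_out$cdna_delta_bp, 0L)
  expect_identical(ref_out$truncated_protein,
                   as.character(translate_cds(cds_seq(loc))))
  # a non-acceptor variant is rejected
  expect_error(predict_cryptic_splice(
    loc, acceptor_variant = list(pos = 3, ref = substr(loc$sequence, 3, 3),
                                 alt = "A")), "not a splice-acceptor")
})

test_that("the engineered demo locus reproduces the reported splicing mechanism", {
  d <- synthetic_ghd7_locus()
  out <- predict_cryptic_splice(d$locus, acceptor_variant = d$acceptor_variant,
                                domains = list(d$cct))
  expect_identical(out$cdna_delta_bp, -34L)
  expect_true(out$frameshift)
  expect_identical(out$domains_lost, "CCT")
  # truncation stops inside the CCT interval
  trunc_len <- nchar(sub("\\*$", "", out$truncated_protein))
  expect_lt(trunc_len, d$cct$aa_end)
  # frameshift verdict also follows from protein-length comparison
  ref_len <- nchar(sub("\\*$", "", as.character(translate_cds(cds_seq(d$locus)))))
  expect_lt(trunc_len, ref_len)
})

test_that("haplotype functional classes follow the effect hierarchy", {
  expect_identical(classify_haplotype_function(character(0), is_h0 = TRUE),
                   "deleted")
  expect_identical(classify_haplotype_function(c("nonsynonymous",
                                                 "splice_acceptor")),
                   "splice_defective")
  expect_identical(classify_haplotype_function(c("premature_stop",
                                                 "synonymous")), "truncated")
  expect_identical(classify_haplotype_function("frameshift_indel"),
                   "truncated")
  expect_identical(classify_haplotype_function(c("synonymous",
                                                 "nonsynonymous")),
                   "functional")
})
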