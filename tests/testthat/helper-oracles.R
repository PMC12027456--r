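# Independent oracles and toy-locus builders used across the suite. These
# deliberately avoid the package's own code paths (and Biostrings) wherever
# they serve as a cross-check.

# Standard genetic code as a literal, bases ordered T, C, A, G (the classic
# textbook layout), independent of any translation code in the package.
oracle_codon_table <- local({
  aas <- strsplit(paste0("FFLLSSSSYY**CC*W",
                         "LLLLPPPPHHQQRRRR",
                         "IIIMTTTTNNKKSSRR",
                         "VVVVAAAADDEEGGGG"), "")[[1]]
  b <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(b, b, function(x, y) paste0(x, y))))
  codons <- as.vector(t(outer(codons, b, paste0)))
  stats::setNames(aas, codons)
})

oracle_translate <- function(cds) {
  n <- nchar(cds) - nchar(cds) %% 3
  if (n < 3) return("")
  st <- seq(1, n, 3)
  aa <- unname(oracle_codon_table[substring(cds, st, st + 2)])
  aa[is.na(aa)] <- "X"
  k <- which(aa == "*")
  if (length(k)) aa <- aa[seq_len(k[1])]
  paste(aa, collapse = "")
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# plain substring splice, plus-strand only
oracle_splice <- function(seq, exons) {
  paste(substring(seq, exons[, 1], exons[, 2]), collapse = "")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# A small plus-strand toy gene: CDS covers the whole transcript, intron is
# GT..AG. Sequence drawn with the caller's RNG state.
make_toy_locus <- function(exon_lens = c(120, 90), intron_len = 40,
                           flank = 60, gene_id = "toy") {
  stopifnot(sum(exon_lens) %% 3 == 0)
  sense <- names(oracle_codon_table)[oracle_codon_table != "*"]
  cds <- paste0("ATG",
                paste(sample(sense, sum(exon_lens) / 3 - 2, replace = TRUE),
                      collapse = ""), "TGA")
  exon1 <- substr(cds, 1, exon_lens[1])
  exon2 <- substr(cds, exon_lens[1] + 1, nchar(cds))
  intron <- paste0("GT", rand_dna(intron_len - 4), "AG")
  seqfull <- paste0(rand_dna(flank), exon1, intron, exon2, rand_dna(flank))
  e1 <- c(flank + 1, flank + exon_lens[1])
  e2 <- c(e1[2] + intron_len + 1, e1[2] + intron_len + exon_lens[2])
  model <- gene_model(gene_id, "+", rbind(e1, e2), c(1, sum(exon_lens)))
  gene_locus("chrToy", seqfull, gene = model)
}

# Build a locus from explicit parts (exon1/intron/exon2 given literally).
make_custom_locus <- function(exon1, intron, exon2, flank_l, flank_r,
                              strand = "+") {
  parts_plus <- if (strand == "+") c(flank_l, exon1, intron, exon2, flank_r)
                else c(flank_l, oracle_revcomp(exon2), oracle_revcomp(intron),
                       oracle_revcomp(exon1), flank_r)
  seqfull <- paste(parts_plus, collapse = "")
  nl <- nchar(flank_l)
  len1 <- if (strand == "+") nchar(exon1) else nchar(exon2)
  len2 <- if (strand == "+") nchar(exon2) else nchar(exon1)
  e1 <- c(nl + 1, nl + len1)
  e2 <- c(e1[2] + nchar(intron) + 1, e1[2] + nchar(intron) + len2)
  model <- gene_model("custom", strand, rbind(e1, e2),
                      c(1, nchar(exon1) + nchar(exon2)))
  gene_locus("chrCustom", seqfull, gene = model)
}

# Brute-force re-splice-and-translate effect oracle for single-base
# substitutions on a plus-strand full-CDS model. Categories determined by
# sequence surgery, not by the package's codon arithmetic.
oracle_effect <- function(locus, pos, alt) {
  seq <- locus$sequence
  ex <- locus$gene$exons
  intron <- c(ex[1, "end"] + 1, ex[2, "start"] - 1)
  if (pos %in% c(intron[1], intron[1] + 1)) return("splice_donor")
  if (pos %in% c(intron[2] - 1, intron[2])) return("splice_acceptor")
  in_exon <- any(pos >= ex[, "start"] & pos <= ex[, "end"])
  if (!in_exon) {
    if (pos >= intron[1] && pos <= intron[2]) return("intronic")
    return("intergenic")
  }
  mut <- seq
  substr(mut, pos, pos) <- alt
  ref_prot <- oracle_translate(oracle_splice(seq, ex))
  alt_prot <- oracle_translate(oracle_splice(mut, ex))
  strip <- function(p) sub("\\*$", "", p)
  if (alt_prot == ref_prot) return("synonymous")
  if (nchar(strip(alt_prot)) < nchar(strip(ref_prot))) return("premature_stop")
  "nonsynonymous"
}

# Distances on an unrooted 4-taxon tree ((A:a,B:b):m,(C:c,D:d)) are additive;
# used to test that NJ recovers the generating topology.
additive_4taxon <- function(a = 2, b = 3, m = 4, c_ = 2, d = 5) {
  d4 <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d4["A", "B"] <- d4["B", "A"] <- a + b
  d4["A", "C"] <- d4["C", "A"] <- a + m + c_
  d4["A", "D"] <- d4["D", "A"] <- a + m + d
  d4["B", "C"] <- d4["C", "B"] <- b + m + c_
  d4["B", "D"] <- d4["D", "B"] <- b + m + d
  d4["C", "D"] <- d4["D", "C"] <- c_ + d
  d4
}
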