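## Gene-region haplotype typing: sample filtering (heterozygous/missing/whole-
## gene-deletion exclusion), collapsing identical allele vectors into named
## haplotypes, subpopulation frequency tables and a neighbor-joining tree.

GENO_CODES <- c(ref = 0L, alt = 1L, het = 2L, missing = 3L)

#' Construct a SNP matrix
#'
#' Genotype codes: 0 = homozygous reference, 1 = homozygous alternate,
#' 2 = heterozygous, 3 = missing. Variants must be biallelic with strictly
#' increasing positions; single InDel records are carried as ordinary binary
#' columns.
#'
#' @param variants data.frame(chrom, pos, ref, alt, ...).
#' @param samples Character vector of sample ids.
#' @param geno Integer matrix, samples x variants, values 0-3.
#' @return A `snp_matrix`.
#' @export
snp_matrix <- function(variants, samples, geno) {
  stopifnot(is.data.frame(variants), nrow(variants) == ncol(geno),
            length(samples) == nrow(geno))
  if (is.unsorted(variants$pos, strictly = TRUE))
    stop("variant positions must be strictly increasing")
  if (any(nchar(variants$alt) < 1L) || any(grepl(",", variants$alt)))
    stop("every variant must be biallelic")
  storage.mode(geno) <- "integer"
  if (any(!geno %in% 0:3)) stop("genotype codes must be 0/1/2/3")
  rownames(geno) <- samples
  structure(list(variants = variants, samples = samples, geno = geno),
            class = "snp_matrix")
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("<snp_matrix> %d sample(s) x %d variant(s)\n",
              length(x$samples), nrow(x$variants)))
  invisible(x)
}

#' Write a SNP matrix as plain-text VCF 4.2
#' @param m A `snp_matrix`.
#' @param path Output file.
#' @export
write_snp_vcf <- function(m, path) {
  gt_str <- c("0/0", "1/1", "0/1", "./.")
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", m$samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(m$variants)), function(i) {
    v <- m$variants[i, ]
    paste(c(v$chrom, v$pos, paste0("var", i), v$ref, v$alt, ".", "PASS", ".",
            "GT", gt_str[m$geno[, i] + 1L]), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into a SNP matrix
#'
#' Biallelic records only; unphased and phased diploid genotypes accepted.
#' Any genotype other than 0/0, 1/1 or a 0-1 het is treated as missing.
#'
#' @param path VCF file (plain text or gzipped).
#' @return A `snp_matrix`.
#' @export
read_snp_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(v)),
                dimnames = list(NULL, colnames(vcfR::getFIX(v))))
  keep <- !grepl(",", fix[, "ALT"])
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  code <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(3L, length(g))
    out[g %in% "0/0"] <- 0L
    out[g %in% "1/1"] <- 1L
    out[g %in% c("0/1", "1/0")] <- 2L
    out
  }
  geno <- t(apply(gt, 1L, code))        # variants x samples -> coded
  geno <- t(geno)                       # samples x variants
  variants <- data.frame(chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  o <- order(variants$pos)
  snp_matrix(variants[o, , drop = FALSE], colnames(gt),
             geno[, o, drop = FALSE])
}

#' Filter samples before haplotype collapsing
#'
#' Drops every sample with at least one heterozygous call, at least one
#' missing call, or membership in the whole-gene-deletion (H0) class; each
#' exclusion is logged with a reason (priority: h0_deletion > het > missing
#' when several apply).
#'
#' @param m A `snp_matrix`.
#' @param h0_carriers Sample ids carrying the whole-gene deletion.
#' @return List: `matrix` (filtered `snp_matrix`) and `log`
#'   (data.frame sample_id, reason).
#' @export
filter_samples <- function(m, h0_carriers = character(0)) {
  has_het <- apply(m$geno == GENO_CODES[["het"]], 1L, any)
  has_mis <- apply(m$geno == GENO_CODES[["missing"]], 1L, any)
  is_h0 <- m$samples %in% h0_carriers
  reason <- rep(NA_character_, length(m$samples))
  reason[has_mis] <- "missing"
  reason[has_het] <- "het"
  reason[is_h0] <- "h0_deletion"
  drop <- !is.na(reason)
  log <- data.frame(sample_id = m$samples[drop], reason = reason[drop],
                    stringsAsFactors = FALSE)
  keep <- which(!drop)
  fm <- snp_matrix(m$variants, m$samples[keep],
                   m$geno[keep, , drop = FALSE])
  list(matrix = fm, log = log)
}

#' Collapse identical allele vectors into named haplotypes
#'
#' Samples with identical vectors form one haplotype. Labels are assigned
#' H1, H2, ... by descending carrier count, ties broken by first-seen sample
#' order; H0 (the whole-gene deletion class, which has no allele vector) is
#' attached from `h0_carriers`.
#'
#' @param m A filtered `snp_matrix` (no het/missing codes).
#' @param h0_carriers Sample ids of the deletion class.
#' @return A `haplotype_set`: list(table = data.frame(label, n_carriers),
#'   alleles = matrix (haplotypes x variants, H0 absent), carriers = named
#'   list, variants = the variant table).
#' @export
collapse_haplotypes <- function(m, h0_carriers = character(0)) {
  if (any(m$geno >= 2L))
    stop("matrix still contains het/missing codes; run filter_samples() first")
  keys <- apply(m$geno, 1L, paste, collapse = "")
  first_seen <- !duplicated(keys)
  uniq <- keys[first_seen]
  counts <- as.integer(table(keys)[uniq])
  o <- order(-counts, match(uniq, keys))   # descending count, then first-seen
  uniq <- uniq[o]; counts <- counts[o]
  labels <- paste0("H", seq_along(uniq))
  carriers <- lapply(uniq, function(k) m$samples[keys == k])
  names(carriers) <- labels
  alleles <- m$geno[match(uniq, keys), , drop = FALSE]
  rownames(alleles) <- labels
  tab <- data.frame(label = labels, n_carriers = counts,
                    stringsAsFactors = FALSE)
  if (length(h0_carriers) > 0L) {
    tab <- rbind(data.frame(label = "H0", n_carriers = length(h0_carriers)),
                 tab)
    carriers <- c(list(H0 = h0_carriers), carriers)
  }
  structure(list(table = tab, alleles = alleles, carriers = carriers,
                 variants = m$variants),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("<haplotype_set> %d haplotype(s) over %d variant(s)\n",
              nrow(x$table), ncol(x$alleles)))
  print(utils::head(x$table, 10L))
  invisible(x)
}

#' Haplotype frequencies per subpopulation
#'
#' @param hs A `haplotype_set`.
#' @param metadata data.frame(sample_id, subpopulation). Carriers without a
#'   metadata row are counted under "unassigned" rather than dropped.
#' @return data.frame(haplotype, subpopulation, count, proportion) where
#'   proportions sum to 1 within each subpopulation.
#' @export
subpop_frequencies <- function(hs, metadata) {
  if (length(hs$carriers) == 0L)
    return(data.frame(haplotype = character(0), subpopulation = character(0),
                      count = integer(0), proportion = numeric(0)))
  long <- do.call(rbind, lapply(names(hs$carriers), function(lab) {
    data.frame(haplotype = lab, sample_id = hs$carriers[[lab]],
               stringsAsFactors = FALSE)
  }))
  long$subpopulation <- metadata$subpopulation[
    match(long$sample_id, metadata$sample_id)]
  long$subpopulation[is.na(long$subpopulation)] <- "unassigned"
  tab <- as.data.frame(table(haplotype = long$haplotype,
                             subpopulation = long$subpopulation),
                       responseName = "count", stringsAsFactors = FALSE)
  totals <- tapply(tab$count, tab$subpopulation, sum)
  tab$proportion <- tab$count / as.numeric(totals[tab$subpopulation])
  tab[order(tab$subpopulation,
            as.integer(sub("^H", "", tab$haplotype))), , drop = FALSE]
}

#' Hamming distances between haplotype allele vectors
#' @param hs A `haplotype_set` (H0, which has no vector, is excluded).
#' @return A symmetric distance matrix.
#' @export
hap_distance <- function(hs) {
  a <- hs$alleles
  n <- nrow(a)
  d <- matrix(0L, n, n, dimnames = list(rownames(a), rownames(a)))
  for (i in seq_len(n))
    for (j in seq_len(n))
      d[i, j] <- sum(a[i, ] != a[j, ])
  d
}

#' Neighbor-joining tree of haplotypes
#'
#' Classic NJ on the Hamming distance matrix (H0 excluded: it has no allele
#' vector). Negative branch lengths are clamped to 0 with a message. With
#' fewer than 3 haplotypes a degenerate two- or one-tip tree is emitted with
#' a warning.
#'
#' @param hs A `haplotype_set`, or a distance matrix.
#' @return An `ape` `phylo` object.
#' @export
nj_tree <- function(hs) {
  d <- if (inherits(hs, "haplotype_set")) hap_distance(hs) else as.matrix(hs)
  n <- nrow(d)
  if (n < 3L) {
    warning("fewer than 3 haplotypes: emitting a degenerate tree")
    if (n == 1L)
      return(ape::read.tree(text = paste0("(", rownames(d)[1L], ":0);")))
    return(ape::read.tree(text = sprintf("(%s:%g,%s:%g);", rownames(d)[1L],
                                         d[1L, 2L] / 2, rownames(d)[2L],
                                         d[1L, 2L] / 2)))
  }
  tr <- ape::nj(stats::as.dist(d))
  if (any(tr$edge.length < 0)) {
    message("negative NJ branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Write a tree in newick format
#' @param tree A `phylo` object.
#' @param path Output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
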