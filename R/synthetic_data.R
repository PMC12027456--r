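## Synthetic cohort generator: reference locus, SV-bearing assemblies, depth
## profiles and SNP matrices, each with a machine-readable truth table.

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Stable per-accession RNG sub-stream: adding accessions to a cohort never
# perturbs the draws of existing ones.
acc_seed <- function(seed, id) {
  h <- 0
  for (ch in utf8ToInt(id)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + (seed %% 2147483647) * 10007) %% 2147483647)
}

#' Simulation configuration
#'
#' Defaults define the study conditions used throughout the test-suite and the
#' reproduction script: a 120 kb locus holding a two-exon gene (700 + 452 bp
#' exons, 500 bp intron) at its centre; a cohort of 200 accessions of which
#' 15% carry a compound ~60 kb deletion spanning the gene; 20x short-read
#' depth with 2% off-target depth inside deleted spans; and a gene-region SNP
#' matrix of 46 SNPs plus one InDel drawn from 8 founder haplotypes with 6%
#' het-bearing and 4.5% missing-bearing samples.
#'
#' @param seed Integer master seed; every artifact is deterministic given it.
#' @param locus_length Reference segment length (bp).
#' @param exon_lengths Two exon lengths (bp); their sum must be divisible by 3
#'   (the CDS covers the whole transcript).
#' @param intron_length Intron length (bp), >= 4.
#' @param n_accessions Cohort size.
#' @param deletion_fraction Proportion of accessions carrying the homozygous
#'   gene-spanning deletion.
#' @param het_fraction Proportion carrying the deletion on one haplotype only
#'   (depth halves over the span; the assembly keeps the gene).
#' @param deletion_span_length Length (bp) of the deletion span, centred on
#'   the gene.
#' @param sv_menu Named list of flank SV size ranges, e.g.
#'   `list(inversion = c(500, 2000), substitution = c(500, 2000))`.
#' @param flank_snps SNPs planted in each non-carrier's flanks.
#' @param mean_depth Expected reads per base over present sequence.
#' @param depth_noise Off-target depth inside deleted spans, as a fraction of
#'   `mean_depth`.
#' @param snp_count,indel_count Variant sites in the gene-region SNP matrix.
#' @param haplotype_count Founder haplotypes.
#' @param het_rate,missing_rate Fractions of samples receiving injected
#'   heterozygous / missing calls (disjoint sample sets).
#' @param subpop_labels Subpopulation labels cycled over founders.
#' @param subpop_confusion Probability a sample's label deviates from its
#'   founder's subpopulation.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       locus_length = 120000L,
                       exon_lengths = c(700L, 452L),
                       intron_length = 500L,
                       n_accessions = 200L,
                       deletion_fraction = 0.15,
                       het_fraction = 0,
                       deletion_span_length = 60000L,
                       sv_menu = list(inversion = c(500L, 2000L),
                                      substitution = c(500L, 2000L)),
                       flank_snps = 30L,
                       mean_depth = 20,
                       depth_noise = 0.02,
                       snp_count = 46L,
                       indel_count = 1L,
                       haplotype_count = 8L,
                       het_rate = 0.06,
                       missing_rate = 0.045,
                       subpop_labels = c("XI", "GJ", "aus", "Or1"),
                       subpop_confusion = 0.1) {
  cfg <- list(seed = as.integer(seed), locus_length = as.integer(locus_length),
              exon_lengths = as.integer(exon_lengths),
              intron_length = as.integer(intron_length),
              n_accessions = as.integer(n_accessions),
              deletion_fraction = deletion_fraction,
              het_fraction = het_fraction,
              deletion_span_length = as.integer(deletion_span_length),
              sv_menu = sv_menu, flank_snps = as.integer(flank_snps),
              mean_depth = mean_depth, depth_noise = depth_noise,
              snp_count = as.integer(snp_count),
              indel_count = as.integer(indel_count),
              haplotype_count = as.integer(haplotype_count),
              het_rate = het_rate, missing_rate = missing_rate,
              subpop_labels = subpop_labels,
              subpop_confusion = subpop_confusion)
  if (cfg$deletion_fraction < 0 || cfg$deletion_fraction > 1)
    stop("deletion_fraction must lie in [0, 1]")
  if (cfg$mean_depth <= 0) stop("mean_depth must be > 0")
  if (cfg$haplotype_count > cfg$n_accessions)
    stop("haplotype_count may not exceed n_accessions")
  if (length(cfg$exon_lengths) != 2L)
    stop("exactly two exons are modelled")
  if (sum(cfg$exon_lengths) %% 3L != 0L)
    stop("summed exon lengths must be divisible by 3 (CDS covers transcript)")
  if (cfg$intron_length < 4L) stop("intron_length must be >= 4")
  gene_len <- sum(cfg$exon_lengths) + cfg$intron_length
  if (gene_len + 2000L > cfg$locus_length)
    stop("gene_spec does not fit inside locus_length")
  if (cfg$deletion_span_length <= gene_len ||
      cfg$deletion_span_length + 10000L > cfg$locus_length)
    stop("deletion_span_length must cover the gene and leave usable flanks")
  structure(cfg, class = "sim_config")
}

#' Simulate the reference locus
#'
#' Uniform random DNA with a two-exon gene at the segment centre. The intron
#' begins GT and ends AG; the CDS covers the whole spliced transcript, starts
#' ATG, ends with a stop codon and has no internal stop.
#'
#' @param cfg A [sim_config()].
#' @return A `gene_locus`.
#' @export
simulate_reference <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(acc_seed(cfg$seed, "__reference__"))
  n_codons <- sum(cfg$exon_lengths) / 3L
  cds <- paste0("ATG",
                paste(sample(sense_codons(), n_codons - 2L, replace = TRUE),
                      collapse = ""),
                "TGA")
  exon1 <- substr(cds, 1L, cfg$exon_lengths[1L])
  exon2 <- substr(cds, cfg$exon_lengths[1L] + 1L, nchar(cds))
  intron <- paste0("GT", random_dna(cfg$intron_length - 4L), "AG")
  gene_len <- sum(cfg$exon_lengths) + cfg$intron_length
  gstart <- (cfg$locus_length - gene_len) %/% 2L + 1L
  flank_l <- random_dna(gstart - 1L)
  flank_r <- random_dna(cfg$locus_length - gene_len - (gstart - 1L))
  seqfull <- paste0(flank_l, exon1, intron, exon2, flank_r)
  e1 <- c(gstart, gstart + cfg$exon_lengths[1L] - 1L)
  e2s <- e1[2L] + cfg$intron_length + 1L
  e2 <- c(e2s, e2s + cfg$exon_lengths[2L] - 1L)
  model <- gene_model("simGene", "+", rbind(e1, e2), c(1L, sum(cfg$exon_lengths)))
  gene_locus("chrSim", seqfull, origin_offset = 9100001L, gene = model,
             flank_size = gstart - 1L)
}

default_deletion_span <- function(cfg, locus) {
  sp <- gene_span(locus$gene)
  center <- (sp[1L] + sp[2L]) %/% 2L
  ds <- center - cfg$deletion_span_length %/% 2L
  c(ds, ds + cfg$deletion_span_length - 1L)
}

place_flank_event <- function(type, size, regions, taken) {
  for (try in 1:50) {
    reg <- regions[[sample.int(length(regions), 1L)]]
    if (reg[2L] - size < reg[1L]) next
    s <- sample(reg[1L]:(reg[2L] - size), 1L)
    e <- s + size - 1L
    clash <- any(vapply(taken, function(iv) s <= iv[2L] && e >= iv[1L], TRUE))
    if (!clash) return(c(s, e))
  }
  NULL
}

apply_events <- function(refseq, events) {
  # events: data.frame(type, ref_start, ref_end) sorted by ref_start,
  # non-overlapping. Returns list(seq, events with acc coords).
  pieces <- character(0)
  cur <- 1L
  acc_pos <- 1L
  acc_start <- integer(nrow(events))
  acc_end <- integer(nrow(events))
  for (i in seq_len(nrow(events))) {
    s <- events$ref_start[i]; e <- events$ref_end[i]
    pre <- substr(refseq, cur, s - 1L)
    acc_pos <- acc_pos + nchar(pre)
    piece <- switch(events$type[i],
      deletion = "",
      inversion = revcomp(substr(refseq, s, e)),
      substitution = random_dna(e - s + 1L),
      snp = {
        b <- substr(refseq, s, s)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      },
      stop("unknown event type: ", events$type[i]))
    acc_start[i] <- acc_pos
    acc_end[i] <- acc_pos + nchar(piece) - 1L
    acc_pos <- acc_pos + nchar(piece)
    pieces <- c(pieces, pre, piece)
    cur <- e + 1L
  }
  pieces <- c(pieces, substr(refseq, cur, nchar(refseq)))
  events$acc_start <- acc_start
  events$acc_end <- acc_end
  list(seq = paste(pieces, collapse = ""), events = events)
}

#' Simulate accession assemblies with planted SVs
#'
#' Deletion carriers receive a compound SV: one deletion spanning the gene
#' plus 1-3 nested inversion/substitution blocks in the flanks (kept >= 3 kb
#' away from the deletion edges). Non-carriers receive only flank SNPs.
#' Heterozygous carriers (see `het_fraction`) keep the gene in their assembly.
#' Every event is recorded in both reference and accession coordinate frames.
#'
#' @param cfg A [sim_config()].
#' @param locus The reference `gene_locus` from [simulate_reference()].
#' @param sequences Build assembly sequences (default TRUE). With FALSE only
#'   the truth table is produced (event draws are identical; accession-frame
#'   coordinates are NA) - useful for depth-only cohorts.
#' @return List with `assemblies` (named character vector, or NULL), `truth`
#'   (a `truth_table`: `$accessions`, `$events`, `$deletion_span`).
#' @export
simulate_accessions <- function(cfg, locus, sequences = TRUE) {
  stopifnot(inherits(cfg, "sim_config"), inherits(locus, "gene_locus"))
  L <- nchar(locus$sequence)
  sp <- gene_span(locus$gene)
  del <- default_deletion_span(cfg, locus)
  n <- cfg$n_accessions
  ids <- sprintf("ACC%03d", seq_len(n))
  set.seed(acc_seed(cfg$seed, "__cohort__"))
  n_carrier <- round(n * cfg$deletion_fraction)
  carriers <- sample(ids, n_carrier)
  n_het <- round(n * cfg$het_fraction)
  hets <- sample(setdiff(ids, carriers), n_het)

  up_region <- c(1000L, del[1L] - 3000L)
  down_region <- c(del[2L] + 3000L, L - 1000L)
  assemblies <- character(n)
  names(assemblies) <- ids
  acc_rows <- vector("list", n)
  ev_rows <- list()
  snp_ok <- setdiff(1001:(L - 1000L), (sp[1L] - 100L):(sp[2L] + 100L))
  for (i in seq_len(n)) {
    id <- ids[i]
    set.seed(acc_seed(cfg$seed, id))
    if (id %in% carriers) {
      evs <- data.frame(type = "deletion", ref_start = del[1L],
                        ref_end = del[2L], stringsAsFactors = FALSE)
      n_ev <- sample(1:3, 1L)
      taken <- list(del)
      for (j in seq_len(n_ev)) {
        type <- sample(names(cfg$sv_menu), 1L)
        rng <- cfg$sv_menu[[type]]
        size <- sample(rng[1L]:rng[2L], 1L)
        iv <- place_flank_event(type, size, list(up_region, down_region), taken)
        if (is.null(iv)) next
        taken <- c(taken, list(iv))
        evs <- rbind(evs, data.frame(type = type, ref_start = iv[1L],
                                     ref_end = iv[2L]))
      }
    } else {
      k <- cfg$flank_snps
      pos <- sort(sample(snp_ok, k))
      evs <- data.frame(type = rep("snp", k), ref_start = pos, ref_end = pos,
                        stringsAsFactors = FALSE)
    }
    evs <- evs[order(evs$ref_start), , drop = FALSE]
    if (sequences) {
      res <- apply_events(locus$sequence, evs)
      assemblies[i] <- res$seq
      evs <- res$events
    } else {
      evs$acc_start <- NA_integer_
      evs$acc_end <- NA_integer_
    }
    if (nrow(evs) > 0)
      ev_rows[[id]] <- cbind(accession_id = id, evs)
    zyg <- if (id %in% carriers) "hom" else if (id %in% hets) "het" else "none"
    acc_rows[[i]] <- data.frame(accession_id = id,
                                gene_present = !(id %in% carriers),
                                zygosity = zyg, stringsAsFactors = FALSE)
  }
  truth <- structure(list(accessions = do.call(rbind, acc_rows),
                          events = do.call(rbind, c(ev_rows,
                                                    make.row.names = FALSE)),
                          deletion_span = del),
                     class = "truth_table")
  list(assemblies = if (sequences) assemblies else NULL, truth = truth)
}

deleted_intervals <- function(truth, id) {
  ev <- truth$events
  ev <- ev[ev$accession_id == id & ev$type == "deletion", , drop = FALSE]
  if (nrow(ev) == 0) return(NULL)
  cbind(ev$ref_start, ev$ref_end)
}

#' Simulate a per-base depth profile for one accession
#'
#' Poisson depth at `mean_depth` over positions present in the accession,
#' `depth_noise * mean_depth` (off-target mapping) over deleted spans, and
#' `mean_depth / 2` over the span for heterozygous carriers.
#'
#' @param cfg A [sim_config()].
#' @param locus Reference locus.
#' @param truth Truth table from [simulate_accessions()].
#' @param id Accession id.
#' @return Integer vector of depth, one element per reference position.
#' @export
simulate_depth_one <- function(cfg, locus, truth, id) {
  L <- nchar(locus$sequence)
  set.seed(acc_seed(cfg$seed, paste0(id, ":depth")))
  acc <- truth$accessions[truth$accessions$accession_id == id, , drop = FALSE]
  if (nrow(acc) != 1L) stop("unknown accession: ", id)
  lambda <- rep(cfg$mean_depth, L)
  if (acc$zygosity == "hom") {
    ivs <- deleted_intervals(truth, id)
    for (r in seq_len(nrow(ivs)))
      lambda[ivs[r, 1L]:ivs[r, 2L]] <- cfg$depth_noise * cfg$mean_depth
  } else if (acc$zygosity == "het") {
    ds <- truth$deletion_span
    lambda[ds[1L]:ds[2L]] <- cfg$mean_depth / 2
  }
  stats::rpois(L, lambda)
}

#' Simulate depth profiles for a cohort
#'
#' @inheritParams simulate_depth_one
#' @param ids Accession ids (default: all in the truth table).
#' @param as `"table"` for per-accession `data.table(chrom, pos, depth)`,
#'   `"vector"` for bare integer vectors.
#' @return Named list, one element per accession.
#' @export
simulate_depth <- function(cfg, locus, truth, ids = NULL, as = c("table", "vector")) {
  as <- match.arg(as)
  if (is.null(ids)) ids <- truth$accessions$accession_id
  out <- lapply(ids, function(id) {
    d <- simulate_depth_one(cfg, locus, truth, id)
    if (as == "vector") d
    else data.table::data.table(chrom = locus$chrom_id,
                                pos = seq_along(d), depth = d)
  })
  names(out) <- ids
  out
}

#' Write depth tables as 3-column TSVs plus a cohort manifest
#' @param depths Named list from [simulate_depth()].
#' @param dir Output directory.
#' @return Manifest data.frame (accession_id, depth_path), also written as
#'   `manifest.tsv` in `dir`.
#' @export
write_depth_tsv <- function(depths, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(depths), function(id) {
    p <- file.path(dir, paste0(id, ".depth.tsv"))
    data.table::fwrite(depths[[id]], p, sep = "\t")
    p
  }, "")
  manifest <- data.frame(accession_id = names(depths), depth_path = unname(paths),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest
}

#' Simulate a gene-region SNP matrix with founder haplotypes
#'
#' Draws `snp_count` SNPs (plus `indel_count` single InDel columns) inside the
#' gene span, builds `haplotype_count` distinct founder allele vectors
#' (founder 1 is all-reference), assigns samples to founders with skewed
#' frequencies, then injects heterozygous calls into `round(het_rate * n)`
#' samples and missing calls into `round(missing_rate * n)` further samples
#' (sets disjoint; every founder keeps at least one clean carrier).
#' Subpopulation labels follow the founder with probability
#' `1 - subpop_confusion`.
#'
#' @param cfg A [sim_config()].
#' @param locus Reference locus.
#' @return List: `matrix` (a `snp_matrix`), `metadata` (sample_id,
#'   subpopulation), `truth` (sample_id, founder, excluded_reason).
#' @export
simulate_snp_matrix <- function(cfg, locus) {
  set.seed(acc_seed(cfg$seed, "__snp__"))
  sp <- gene_span(locus$gene)
  n <- cfg$n_accessions
  K <- cfg$haplotype_count
  pos <- sort(sample(sp[1L]:sp[2L], cfg$snp_count + cfg$indel_count))
  is_indel <- rep(FALSE, length(pos))
  if (cfg$indel_count > 0)
    is_indel[sample(seq_along(pos), cfg$indel_count)] <- TRUE
  ref <- vapply(seq_along(pos), function(i) {
    if (is_indel[i]) substr(locus$sequence, pos[i], pos[i] + 1L)
    else substr(locus$sequence, pos[i], pos[i])
  }, "")
  alt <- vapply(seq_along(pos), function(i) {
    if (is_indel[i]) substr(ref[i], 1L, 1L)
    else sample(setdiff(c("A", "C", "G", "T"), ref[i]), 1L)
  }, "")
  variants <- data.frame(chrom = locus$chrom_id, pos = pos, ref = ref,
                         alt = alt, is_indel = is_indel,
                         stringsAsFactors = FALSE)
  nv <- nrow(variants)
  repeat {
    founders <- rbind(rep(0L, nv),
                      t(vapply(seq_len(K - 1L), function(i) {
                        v <- rep(0L, nv)
                        v[sample(nv, sample(2:max(3L, nv %/% 4L), 1L))] <- 1L
                        v
                      }, integer(nv))))
    if (nrow(unique(founders)) == K) break
  }
  w <- (K:1)^1.5
  counts <- pmax(1L, round(n * w / sum(w)))
  while (sum(counts) > n) counts[which.max(counts)] <- counts[which.max(counts)] - 1L
  while (sum(counts) < n) counts[1L] <- counts[1L] + 1L
  founder_of <- sample(rep(seq_len(K), counts))
  sample_ids <- sprintf("S%03d", seq_len(n))
  geno <- founders[founder_of, , drop = FALSE]
  rownames(geno) <- sample_ids

  excluded <- rep("none", n)
  n_het <- round(n * cfg$het_rate)
  n_mis <- round(n * cfg$missing_rate)
  clean_count <- table(factor(founder_of, levels = seq_len(K)))
  pick_noisy <- function(k, already) {
    chosen <- integer(0)
    for (i in sample(setdiff(seq_len(n), already))) {
      if (length(chosen) == k) break
      f <- founder_of[i]
      if (clean_count[f] > 1L) {
        chosen <- c(chosen, i)
        clean_count[f] <<- clean_count[f] - 1L
      }
    }
    chosen
  }
  het_idx <- pick_noisy(n_het, integer(0))
  mis_idx <- pick_noisy(n_mis, het_idx)
  for (i in het_idx) geno[i, sample(nv, sample(1:2, 1L))] <- 2L
  for (i in mis_idx) geno[i, sample(nv, sample(1:2, 1L))] <- 3L
  excluded[het_idx] <- "het"
  excluded[mis_idx] <- "missing"

  founder_subpop <- rep(cfg$subpop_labels, length.out = K)
  subpop <- vapply(seq_len(n), function(i) {
    own <- founder_subpop[founder_of[i]]
    if (stats::runif(1) < cfg$subpop_confusion)
      sample(setdiff(cfg$subpop_labels, own), 1L)
    else own
  }, "")
  m <- snp_matrix(variants, sample_ids, geno)
  list(matrix = m,
       metadata = data.frame(sample_id = sample_ids, subpopulation = subpop,
                             stringsAsFactors = FALSE),
       truth = data.frame(sample_id = sample_ids, founder = founder_of,
                          excluded_reason = excluded, stringsAsFactors = FALSE))
}

## ---- deterministic demo locus ----------------------------------------------

GHD7_DEMO <- list(
  exon1 = paste0(
    "ATGAAACTTGTGGCTACAGACACACAAGCATGCGACAGGCTATACGACTGGTTCATCGCG",
    "GTTCTCGCAGCACCATGCCCTACCCTGGAAGATTCATTTCTCTCTAGGTGCGCTAGGTGC",
    "TCTACCTCTACCCGTCAGCGTGGAGACATGCGACAGTATTGTGAGAGGCAAGATTCACAT",
    "TGGAACCTTCACCTGGTGGGAGTGGTAGTC"),
  intron = paste0(
    "GTCTTTCTCCTCTTCTCTTCCTATCCTCCTATCATAAAACATATCACTCCCTCTACTAAC",
    "TCCACCACTAACCATATTCAAATCACAATACCTACACTCATCATTTCTCCAAAATCTTAG"),
  exon2 = paste0(
    "AAACCTACCACCGCGCAATATTCTCCGGGTTTAGTACATTTTGCCGGGGGCAACTGGGAG",
    "CCTGGGAACTTCGTACGCCGCCGTTGTGCTCTTTTCTACGTGCTAATTCTAGGCCTTAGA",
    "CGGCACCCACCACTTCCTGGTCCCCATGTATGA"),
  flank_l = paste0(
    "TTGCGTGCGCAACGGCCTGTTCAATCGTGGCGCACGGCACACTCACGTCCATTTTACCTG",
    "GGATTGCGATAATGGCCACTGGATGCGTTATACTCAGTATTACTCTTCAACACCTAATCT",
    "GAAGAAGTGCATATAATTCGTCGGTCTCGTAGTTACGACGCCAACATGCATGCGTTGCAC",
    "CACCCGACCTCTATGCCAGGACTGTTACCGGTGAAGGAGAGTGTTGGTCGGCAAGACCAA",
    "ATGTGACTTCGTTCGCTTGGGTCACTAATGATTCTACCCATACCGTATTCTTGATAAGAG",
    "TGCACTAATGCGGCGCAGACTTCCTACTGTGGCAAACCCCCCACTCGCTGATCTAAAGAT",
    "GTATTTGCAAGATGCGAGTATATAGGCAGGTAAGTTGTCA"),
  flank_r = paste0(
    "GACGTGGTTGCTACACTGTCACTAAACCGCTCCGGCCAAACGGGAGATGGATGACGTCGA",
    "AGGGCGGGCAGAAGCTGTCAAGTGTATTACGGGTGAAGCGGATATCATAGGTGTACCTAG",
    "ACGACAAGTGATGACTGAGTACCAACGTTTGGTCGTCCTGATCAGGAGCCAGACTACCCT",
    "CTCGAGCTTTGAGCTACTGTAGCTCTGTCTGGACAATTTCGCTTAAGAGCCCATTTGAGG",
    "CACCGGCTGGAACTACACAAACGAACACGAGGCCTGTATGTCAGTCCACTTAACTGGTCG",
    "GCCTTCACTTTCGCATAGCTTAGTATGGCACAGGTGGTAGTTACTCGAAAAACTAAACGC",
    "AGCACATTATCCGTAACACATCGGCATCGTATTAGAAATA"))

#' Synthetic Ghd7-like demonstration locus
#'
#' A fixed, fully synthetic stand-in for the rice *Ghd7* locus (the real
#' Nipponbare sequence is not redistributed here): a 1283 bp segment with a
#' two-exon gene (210 + 153 bp exons, 120 bp intron), a CCT-like domain over
#' amino acids 76-118 of its 120-aa protein, and an engineered cryptic splice
#' acceptor 34 bp into exon 2. Mutating the intron's acceptor adenine to
#' cytosine therefore reproduces the reported loss-of-function mechanism exactly: a 34 bp
#' cDNA deletion, a frameshift, and premature termination inside the CCT
#' domain. `origin_offset` is chosen so the acceptor variant maps to the
#' reported chromosome coordinate 9,152,733.
#'
#' @return List: `locus` (`gene_locus`), `cct` (`domain_annotation`),
#'   `acceptor_variant` (list pos/ref/alt in locus coordinates, the A->C
#'   acceptor mutation).
#' @export
synthetic_ghd7_locus <- function() {
  p <- GHD7_DEMO
  seqfull <- paste0(p$flank_l, p$exon1, p$intron, p$exon2, p$flank_r)
  e1 <- c(401L, 610L)
  e2 <- c(731L, 883L)
  model <- gene_model("Ghd7demo", "+", rbind(e1, e2), c(1L, 363L))
  # acceptor A of the intron-terminal AG: locus position 729
  locus <- gene_locus("chr7sim", seqfull,
                      origin_offset = 9152733L - 729L + 1L,
                      gene = model, flank_size = 400L)
  list(locus = locus,
       cct = domain_annotation("CCT", 76L, 118L),
       acceptor_variant = list(pos = 729L, ref = "A", alt = "C"))
}
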