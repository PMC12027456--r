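#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet reverseComplement GENETIC_CODE
#' @importFrom IRanges IRanges reduce start end width
#' @importFrom stats setNames
NULL

IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")

#' Reverse-complement a DNA sequence
#'
#' Involution over IUPAC DNA alphabet: `revcomp(revcomp(s)) == s`.
#'
#' @param seq Character scalar, DNA (IUPAC codes allowed, case-insensitive).
#' @return Uppercase reverse complement.
#' @export
#' @examples
#' revcomp("AAAC")  # "GTTT"
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  bad <- setdiff(unique(strsplit(s, "")[[1]]), IUPAC_DNA)
  if (length(bad) > 0)
    stop("non-IUPAC DNA character(s) in sequence: ", paste(bad, collapse = ", "))
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Translate a coding sequence
#'
#' Standard genetic code. Translation stops at (and includes) the first stop
#' codon; a trailing partial codon is ignored and flagged. Codons containing a
#' non-ACGT character translate to `X`.
#'
#' @param cds Character scalar, DNA, length >= 3.
#' @return Character scalar protein (may end in `*`), with attribute
#'   `partial_codon` (logical) when a trailing 1-2 nt remnant was dropped.
#' @export
#' @examples
#' translate_cds("ATGAAATAG")  # "MK*"
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  s <- toupper(cds)
  n <- nchar(s)
  if (n < 3L) stop("coding sequence shorter than one codon")
  partial <- (n %% 3L) != 0L
  if (partial) {
    warning("trailing partial codon ignored")
    n <- n - (n %% 3L)
  }
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(s, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  stop_at <- which(aa == "*")
  if (length(stop_at) > 0) aa <- aa[seq_len(stop_at[1L])]
  structure(paste(aa, collapse = ""), partial_codon = partial)
}

#' Construct a single-transcript gene model
#'
#' Exons are 1-based inclusive intervals in locus coordinates, sorted and
#' non-overlapping; every intron must be at least 4 bp so it can carry a donor
#' and an acceptor dinucleotide. `cds` is the coding interval in spliced
#' transcript coordinates.
#'
#' @param gene_id Gene identifier.
#' @param strand "+" or "-".
#' @param exons Two-column matrix or data.frame of (start, end).
#' @param cds Length-2 integer vector (start, end) on the spliced transcript.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, strand, exons, cds) {
  stopifnot(strand %in% c("+", "-"))
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  if (any(exons[, "end"] < exons[, "start"]))
    stop("exon end before start")
  if (is.unsorted(exons[, "start"], strictly = TRUE))
    stop("exons must be sorted by start")
  if (nrow(exons) > 1L) {
    gaps <- exons[-1L, "start"] - exons[-nrow(exons), "end"] - 1L
    if (any(gaps < 4L)) stop("every intron must be >= 4 bp")
  }
  cds <- as.integer(cds)
  tx_len <- sum(exons[, "end"] - exons[, "start"] + 1L)
  if (length(cds) != 2L || cds[1L] < 1L || cds[2L] > tx_len || cds[1L] > cds[2L])
    stop("cds interval outside spliced transcript")
  structure(list(gene_id = gene_id, strand = strand, exons = exons, cds = cds),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %d exon(s), span %d-%d, CDS %d-%d (tx)\n",
              x$gene_id, x$strand, nrow(x$exons),
              gene_span(x)[1L], gene_span(x)[2L], x$cds[1L], x$cds[2L]))
  invisible(x)
}

#' Genomic span of a gene model
#' @param model A `gene_model`.
#' @return Length-2 integer vector (start, end) in locus coordinates.
#' @export
gene_span <- function(model) {
  c(min(model$exons[, "start"]), max(model$exons[, "end"]))
}

#' Construct a gene locus
#'
#' A reference chromosome segment holding one gene model plus flanking context.
#' The segment is the coordinate frame for every downstream stage; the gene
#' span must lie fully inside it. Lowercase input is normalized to uppercase;
#' only A/C/G/T/N are allowed in the stored segment.
#'
#' @param chrom_id Source chromosome name.
#' @param sequence Segment DNA.
#' @param origin_offset 1-based position of the segment start on the source
#'   chromosome (maps locus coordinates into the chromosome frame).
#' @param gene A `gene_model` in locus coordinates.
#' @param flank_size Nominal flank width (bp) on each side of the gene.
#' @return An object of class `gene_locus`.
#' @export
gene_locus <- function(chrom_id, sequence, origin_offset = 1L, gene,
                       flank_size = NA_integer_) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(sequence)
  bad <- setdiff(unique(strsplit(s, "")[[1]]), c("A", "C", "G", "T", "N"))
  if (length(bad) > 0)
    stop("locus sequence may contain only A/C/G/T/N, found: ",
         paste(bad, collapse = ", "))
  origin_offset <- as.integer(origin_offset)
  if (origin_offset < 1L) stop("origin_offset must be >= 1")
  if (!inherits(gene, "gene_model")) stop("gene must be a gene_model")
  sp <- gene_span(gene)
  if (sp[1L] < 1L || sp[2L] > nchar(s))
    stop("gene span lies outside the locus segment")
  structure(list(chrom_id = chrom_id, sequence = s,
                 origin_offset = origin_offset, gene = gene,
                 flank_size = as.integer(flank_size)),
            class = "gene_locus")
}

#' @export
print.gene_locus <- function(x, ...) {
  cat(sprintf("<gene_locus> %s offset %d, %d bp, gene %s\n",
              x$chrom_id, x$origin_offset, nchar(x$sequence), x$gene$gene_id))
  invisible(x)
}

#' Convert locus coordinates to chromosome coordinates
#' @param locus A `gene_locus`.
#' @param pos Integer vector of 1-based locus positions.
#' @return Chromosome positions.
#' @export
locus_to_chrom <- function(locus, pos) as.integer(pos) + locus$origin_offset - 1L

#' Convert chromosome coordinates to locus coordinates
#' @rdname locus_to_chrom
#' @export
chrom_to_locus <- function(locus, pos) as.integer(pos) - locus$origin_offset + 1L

#' Spliced (mature) transcript sequence
#'
#' Concatenates exon substrings 5'->3'; for a minus-strand gene the
#' concatenation is reverse-complemented as a unit.
#'
#' @param locus A `gene_locus` (or a plain character sequence).
#' @param model A `gene_model`; defaults to the locus's own gene.
#' @return Character scalar cDNA.
#' @export
splice <- function(locus, model = NULL) {
  seq <- if (inherits(locus, "gene_locus")) locus$sequence else toupper(locus)
  if (is.null(model)) {
    if (!inherits(locus, "gene_locus")) stop("model required")
    model <- locus$gene
  }
  ex <- model$exons
  if (any(ex[, "start"] < 1L) || any(ex[, "end"] > nchar(seq)))
    stop("exon interval out of locus bounds")
  cdna <- paste(substring(seq, ex[, "start"], ex[, "end"]), collapse = "")
  if (model$strand == "-") cdna <- revcomp(cdna)
  cdna
}

#' Coding sequence of a locus's gene
#' @inheritParams splice
#' @return Character scalar CDS (subset of the spliced transcript).
#' @export
cds_seq <- function(locus, model = NULL) {
  if (is.null(model) && inherits(locus, "gene_locus")) model <- locus$gene
  tx <- splice(locus, model)
  substr(tx, model$cds[1L], model$cds[2L])
}

#' Annotate a protein domain
#'
#' @param name Domain name (e.g. "CCT").
#' @param aa_start,aa_end 1-based inclusive amino-acid interval on the
#'   reference protein.
#' @return A `domain_annotation`.
#' @export
domain_annotation <- function(name, aa_start, aa_end) {
  aa_start <- as.integer(aa_start); aa_end <- as.integer(aa_end)
  if (aa_start < 1L || aa_end < aa_start)
    stop("invalid domain interval")
  structure(list(name = name, aa_start = aa_start, aa_end = aa_end),
            class = "domain_annotation")
}

## ---- FASTA ------------------------------------------------------------------

#' Read a (multi-)FASTA file
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(ss)), names(ss))
}

#' Write sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(unlist(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

## ---- GFF3 -------------------------------------------------------------------

gff3_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attrs))[[1L]]
  if (length(m) < 2L) NA_character_ else m[2L]
}

#' Read a single-gene GFF3 file
#'
#' Restricted reader: only `gene`, `mRNA`, `exon` and `CDS` features are
#' consumed (one transcript per gene). Malformed lines raise errors that name
#' the offending line number. CDS features are converted to a spliced-
#' transcript coding interval.
#'
#' @param path GFF3 file.
#' @return A `gene_model` (attribute `chrom` holds the seqid).
#' @export
read_gene_gff3 <- function(path) {
  lines <- readLines(path)
  feats <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) != 9L)
      stop(sprintf("%s line %d: expected 9 tab-separated columns, found %d",
                   path, i, length(f)))
    type <- f[3L]
    if (!type %in% c("gene", "mRNA", "exon", "CDS")) next
    start <- suppressWarnings(as.integer(f[4L]))
    end <- suppressWarnings(as.integer(f[5L]))
    if (is.na(start) || is.na(end) || start < 1L || end < start)
      stop(sprintf("%s line %d: invalid interval %s-%s", path, i, f[4L], f[5L]))
    if (!f[7L] %in% c("+", "-"))
      stop(sprintf("%s line %d: invalid strand '%s'", path, i, f[7L]))
    feats[[length(feats) + 1L]] <- list(chrom = f[1L], type = type,
                                        start = start, end = end,
                                        strand = f[7L], attrs = f[9L])
  }
  types <- vapply(feats, `[[`, "", "type")
  if (sum(types == "gene") != 1L)
    stop(path, ": expected exactly one gene feature, found ", sum(types == "gene"))
  g <- feats[[which(types == "gene")]]
  exf <- feats[types == "exon"]
  cdf <- feats[types == "CDS"]
  if (length(exf) == 0L) stop(path, ": no exon features")
  if (length(cdf) == 0L) stop(path, ": no CDS features")
  ex <- cbind(start = vapply(exf, `[[`, 0L, "start"),
              end = vapply(exf, `[[`, 0L, "end"))
  ex <- ex[order(ex[, "start"]), , drop = FALSE]
  cd <- cbind(start = vapply(cdf, `[[`, 0L, "start"),
              end = vapply(cdf, `[[`, 0L, "end"))
  cd <- cd[order(cd[, "start"]), , drop = FALSE]
  # genomic CDS extent -> spliced-transcript interval
  tx_map <- unlist(lapply(seq_len(nrow(ex)),
                          function(i) ex[i, "start"]:ex[i, "end"]))
  if (g$strand == "-") tx_map <- rev(tx_map)
  cds_pos <- unlist(lapply(seq_len(nrow(cd)),
                           function(i) cd[i, "start"]:cd[i, "end"]))
  hit <- match(cds_pos, tx_map)
  if (anyNA(hit)) stop(path, ": CDS positions outside exons")
  gid <- gff3_attr(g$attrs, "ID")
  if (is.na(gid)) gid <- gff3_attr(g$attrs, "Name")
  if (is.na(gid)) gid <- "gene1"
  m <- gene_model(gid, g$strand, ex, c(min(hit), max(hit)))
  attr(m, "chrom") <- g$chrom
  m
}

#' Write a gene model as GFF3
#' @param model A `gene_model`.
#' @param path Output file.
#' @param chrom Seqid to write (defaults to the model's `chrom` attribute).
#' @export
write_gene_gff3 <- function(model, path, chrom = NULL) {
  if (is.null(chrom)) chrom <- attr(model, "chrom")
  if (is.null(chrom) || is.na(chrom)) chrom <- "locus"
  sp <- gene_span(model)
  ex <- model$exons
  row <- function(type, s, e, id, parent = NULL) {
    attrs <- paste0("ID=", id, if (!is.null(parent)) paste0(";Parent=", parent))
    paste(chrom, "locuspav", type, s, e, ".", model$strand, ".", attrs,
          sep = "\t")
  }
  gid <- model$gene_id
  mid <- paste0(gid, ".1")
  lines <- c("##gff-version 3",
             row("gene", sp[1L], sp[2L], gid),
             row("mRNA", sp[1L], sp[2L], mid, gid))
  for (i in seq_len(nrow(ex)))
    lines <- c(lines, row("exon", ex[i, "start"], ex[i, "end"],
                          paste0(mid, ".exon", i), mid))
  # spliced-transcript CDS interval -> genomic CDS blocks
  tx_map <- unlist(lapply(seq_len(nrow(ex)),
                          function(i) ex[i, "start"]:ex[i, "end"]))
  if (model$strand == "-") tx_map <- rev(tx_map)
  cds_genomic <- sort(tx_map[model$cds[1L]:model$cds[2L]])
  rr <- IRanges::reduce(IRanges::IRanges(cds_genomic, width = 1L))
  for (i in seq_along(rr))
    lines <- c(lines, row("CDS", IRanges::start(rr)[i], IRanges::end(rr)[i],
                          paste0(mid, ".cds", i), mid))
  writeLines(lines, path)
  invisible(path)
}
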