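## Two-primer-pair deletion assay: G1 amplifies inside the gene (present
## allele only), G2 spans the deletion (deleted allele only). Includes a
## simple in-silico PCR engine used both for design-time validation and for
## cohort genotyping from assemblies.

base_counts <- function(seq) {
  tab <- table(factor(strsplit(toupper(seq), "")[[1]],
                      levels = c("A", "C", "G", "T", "N")))
  as.integer(tab)
}

#' Wallace-rule melting temperature
#'
#' `Tm = 2 (A+T) + 4 (G+C)` degrees C; transparent, adequate for the short
#' primers used here, and documented as swappable for a nearest-neighbour
#' model.
#'
#' @param seq Primer sequence.
#' @return Tm in degrees C.
#' @export
wallace_tm <- function(seq) {
  n <- base_counts(seq)
  2 * (n[1L] + n[4L]) + 4 * (n[2L] + n[3L])
}

#' GC fraction of a sequence
#' @param seq DNA character scalar.
#' @return Fraction in [0, 1].
#' @export
gc_fraction <- function(seq) {
  n <- base_counts(seq)
  (n[2L] + n[3L]) / max(1L, sum(n))
}

#' Construct a primer
#' @param name Primer name.
#' @param sequence 5'->3' DNA, 18-27 nt, no N.
#' @return A `primer` list with fields name, sequence, tm, gc.
#' @export
primer <- function(name, sequence) {
  s <- toupper(sequence)
  if (nchar(s) < 18L || nchar(s) > 27L)
    stop("primer length must be 18-27 nt")
  if (grepl("[^ACGT]", s)) stop("primer may contain only A/C/G/T")
  structure(list(name = name, sequence = s, tm = wallace_tm(s),
                 gc = gc_fraction(s)), class = "primer")
}

count_exact <- function(seq, pat) {
  hits <- gregexpr(pat, seq, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) 0L else length(hits)
}

is_unique_site <- function(seq, pat) {
  count_exact(seq, pat) + count_exact(seq, revcomp(pat)) == 1L
}

# First window inside [region[1], region[2]] (window fully inside) meeting
# the primer constraints and unique in `locus_seq`. Returns start or NA with
# the failure reason in attr.
find_primer_window <- function(locus_seq, region, len, gc_range, tm_range) {
  if (region[2L] - len + 1L < region[1L] || region[1L] < 1L)
    return(structure(NA_integer_, reason = "region too small for primer"))
  starts <- seq.int(region[1L], region[2L] - len + 1L)
  reason <- "no candidate window in region"
  for (s in starts) {
    w <- substr(locus_seq, s, s + len - 1L)
    if (grepl("N", w, fixed = TRUE)) { reason <- "N in window"; next }
    gc <- gc_fraction(w)
    if (gc < gc_range[1L] || gc > gc_range[2L]) { reason <- "GC out of range"; next }
    tm <- wallace_tm(w)
    if (tm < tm_range[1L] || tm > tm_range[2L]) { reason <- "Tm out of range"; next }
    if (!is_unique_site(locus_seq, w)) { reason <- "not unique in locus"; next }
    return(structure(s, reason = NULL))
  }
  structure(NA_integer_, reason = reason)
}

#' Design the two-pair deletion assay
#'
#' G1 (internal): both primers within the gene span, product on the intact
#' reference. G2 (deletion-spanning): forward primer upstream of the deletion
#' start, reverse downstream of its end, so that the product exists only on
#' the deleted allele (reference-allele distance exceeds `max_product`).
#' Primers must satisfy: length `primer_len`, GC within `gc_range`, Wallace
#' Tm within `tm_range`, pair delta-Tm <= `max_dtm`, and locus-wide
#' uniqueness of the primer and its reverse complement.
#'
#' @param locus A `gene_locus`.
#' @param deletion_span c(start, end) covering the gene.
#' @param primer_len Primer length (default 20).
#' @param gc_range GC fraction bounds (default 0.40-0.60).
#' @param tm_range Wallace Tm bounds in degrees C (default 55-65).
#' @param max_dtm Maximum within-pair Tm difference (default 3).
#' @param max_product Maximum amplifiable product (default 3000 bp).
#' @param g2_window How far from the deletion edges G2 primers may sit
#'   (default 450 bp).
#' @return An `assay_design`: list(g1, g2, max_product); each pair holds fwd,
#'   rev (`primer` objects) and the expected product length on its diagnostic
#'   allele.
#' @export
design_assay <- function(locus, deletion_span, primer_len = 20L,
                         gc_range = c(0.40, 0.60), tm_range = c(55, 65),
                         max_dtm = 3, max_product = 3000L, g2_window = 450L) {
  seq <- locus$sequence
  sp <- gene_span(locus$gene)
  ds <- as.integer(deletion_span)
  if (ds[1L] > sp[1L] || ds[2L] < sp[2L])
    stop("deletion_span must cover the gene span")

  pick_pair <- function(fwd_region, rev_region, label) {
    fs <- find_primer_window(seq, fwd_region, primer_len, gc_range, tm_range)
    if (is.na(fs))
      stop(sprintf("%s forward primer design failed: %s", label,
                   attr(fs, "reason")))
    fwd_seq <- substr(seq, fs, fs + primer_len - 1L)
    if (rev_region[2L] - primer_len + 1L < rev_region[1L])
      stop(sprintf("%s reverse primer design failed: region too small", label))
    starts <- seq.int(rev_region[1L], rev_region[2L] - primer_len + 1L)
    reason <- "no candidate window in region"
    for (s in starts) {
      w <- substr(seq, s, s + primer_len - 1L)
      if (grepl("N", w, fixed = TRUE)) { reason <- "N in window"; next }
      gc <- gc_fraction(w)
      if (gc < gc_range[1L] || gc > gc_range[2L]) { reason <- "GC out of range"; next }
      tm <- wallace_tm(w)
      if (tm < tm_range[1L] || tm > tm_range[2L]) { reason <- "Tm out of range"; next }
      if (abs(tm - wallace_tm(fwd_seq)) > max_dtm) { reason <- "pair delta-Tm > max"; next }
      if (!is_unique_site(seq, w)) { reason <- "not unique in locus"; next }
      return(list(fwd = primer(paste0(label, "-F"), fwd_seq),
                  rev = primer(paste0(label, "-R"), revcomp(w)),
                  fwd_start = fs, rev_end = s + primer_len - 1L))
    }
    stop(sprintf("%s reverse primer design failed: %s", label, reason))
  }

  # G1: internal pair, product 400-1200 bp fully inside the gene
  g1_fwd_region <- c(sp[1L], sp[1L] + 400L)
  g1 <- NULL
  for (target in c(800L, 600L, 1000L)) {
    g1 <- tryCatch(pick_pair(g1_fwd_region,
                             c(min(sp[1L] + target - 200L, sp[2L] - primer_len),
                               min(sp[1L] + target + 200L, sp[2L])), "G1"),
                   error = function(e) NULL)
    if (!is.null(g1)) break
  }
  if (is.null(g1)) stop("G1 design failed: no internal pair satisfies constraints")
  g1_len <- g1$rev_end - g1$fwd_start + 1L

  # G2: spans the deletion; deleted-allele product <= max_product
  g2 <- pick_pair(c(ds[1L] - g2_window, ds[1L] - primer_len - 10L),
                  c(ds[2L] + 10L, ds[2L] + g2_window), "G2")
  g2_ref_len <- g2$rev_end - g2$fwd_start + 1L
  g2_del_len <- g2_ref_len - (ds[2L] - ds[1L] + 1L)
  if (g2_ref_len <= max_product)
    stop("G2 reference-allele distance does not exceed max_product")
  if (g2_del_len > max_product)
    stop("G2 deleted-allele product exceeds max_product")
  structure(list(g1 = list(fwd = g1$fwd, rev = g1$rev, product_len = g1_len),
                 g2 = list(fwd = g2$fwd, rev = g2$rev,
                           product_len_deleted = g2_del_len),
                 max_product = as.integer(max_product)),
            class = "assay_design")
}

match_starts <- function(template, pat, max_mismatch = 0L) {
  if (max_mismatch == 0L) {
    hits <- gregexpr(pat, template, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) integer(0) else as.integer(hits)
  } else {
    m <- Biostrings::matchPattern(pat, Biostrings::DNAString(template),
                                  max.mismatch = max_mismatch)
    as.integer(Biostrings::start(m))
  }
}

# 3'-terminal 3 bases of the primer must match the template exactly even when
# internal mismatches are tolerated (3' mismatches abolish extension).
anchored_starts <- function(template, primer_seq, sense, max_mismatch) {
  pat <- if (sense == "fwd") primer_seq else revcomp(primer_seq)
  st <- match_starts(template, pat, max_mismatch)
  if (max_mismatch == 0L || length(st) == 0L) return(st)
  lp <- nchar(pat)
  keep <- vapply(st, function(s) {
    if (sense == "fwd")
      substr(template, s + lp - 3L, s + lp - 1L) ==
        substr(pat, lp - 2L, lp)
    else
      substr(template, s, s + 2L) == substr(pat, 1L, 3L)
  }, TRUE)
  st[keep]
}

#' Simulate PCR on a template
#'
#' Every site where the forward primer matches the plus strand and the
#' reverse complement of the reverse primer matches downstream within
#' `max_product` yields an amplicon; the symmetric search with the roles of
#' the primers swapped covers the minus strand. With `max_mismatch > 0`,
#' internal mismatches are tolerated but the last 3 bases of each primer must
#' match exactly.
#'
#' @param template DNA character scalar.
#' @param fwd,rev `primer` objects (or plain sequences).
#' @param max_product Maximum product length (default 3000).
#' @param max_mismatch Internal mismatches tolerated per primer (default 0).
#' @param pair_name Name carried into the result.
#' @return data.frame of amplicons (pair, start, end, length, product),
#'   sorted by position; zero rows when nothing amplifies.
#' @export
simulate_pcr <- function(template, fwd, rev, max_product = 3000L,
                         max_mismatch = 0L, pair_name = "pair") {
  template <- toupper(template)
  fseq <- if (inherits(fwd, "primer")) fwd$sequence else toupper(fwd)
  rseq <- if (inherits(rev, "primer")) rev$sequence else toupper(rev)
  amps <- list()
  add_orientation <- function(p1, p2) {
    # p1 anneals to the minus strand (reads along plus), p2 primes leftwards
    s1 <- anchored_starts(template, p1, "fwd", max_mismatch)
    s2 <- anchored_starts(template, p2, "rev", max_mismatch)
    for (i in s1) {
      for (j in s2) {
        e <- j + nchar(p2) - 1L
        len <- e - i + 1L
        if (j >= i && len <= max_product && len >= nchar(p1) + nchar(p2)) {
          amps[[length(amps) + 1L]] <<-
            data.frame(pair = pair_name, start = i, end = e, length = len,
                       product = substr(template, i, e),
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  add_orientation(fseq, rseq)
  add_orientation(rseq, fseq)
  if (length(amps) == 0L)
    return(data.frame(pair = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      product = character(0), stringsAsFactors = FALSE))
  out <- unique(do.call(rbind, amps))
  out[order(out$start, out$end), , drop = FALSE]
}

#' Interpret the two-pair band pattern
#'
#' G1 product without G2 product means the gene is present; G2 without G1
#' means the gene-containing fragment is deleted; anything else (neither or
#' both) is uninterpretable.
#'
#' @param g1_products,g2_products Amplicon data.frames from [simulate_pcr()].
#' @return "gene_present", "gene_deleted" or "uninterpretable".
#' @export
classify_pcr <- function(g1_products, g2_products) {
  n1 <- NROW(g1_products); n2 <- NROW(g2_products)
  if (n1 >= 1L && n2 == 0L) "gene_present"
  else if (n1 == 0L && n2 >= 1L) "gene_deleted"
  else "uninterpretable"
}

#' Run a designed assay on a template and interpret it
#' @param assay An `assay_design`.
#' @param template DNA character scalar (e.g. an accession assembly).
#' @param max_mismatch Passed to [simulate_pcr()].
#' @return List: g1, g2 amplicon tables and `call`.
#' @export
run_assay <- function(assay, template, max_mismatch = 0L) {
  g1 <- simulate_pcr(template, assay$g1$fwd, assay$g1$rev, assay$max_product,
                     max_mismatch, "G1")
  g2 <- simulate_pcr(template, assay$g2$fwd, assay$g2$rev, assay$max_product,
                     max_mismatch, "G2")
  list(g1 = g1, g2 = g2, call = classify_pcr(g1, g2))
}
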