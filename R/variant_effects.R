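## Variant annotation against the single-transcript gene model, and the
## cryptic splice-acceptor consequence predictor: when the canonical acceptor
## AG is disabled, the nearest downstream AG (scanning into the exon) is used
## instead, shortening the mature transcript and - when the loss is not a
## multiple of 3 - shifting the reading frame.

# locus positions of the spliced transcript, 5'->3' on the coding strand
transcript_map <- function(model) {
  ex <- model$exons
  m <- unlist(lapply(seq_len(nrow(ex)), function(i) ex[i, "start"]:ex[i, "end"]))
  if (model$strand == "-") rev(m) else m
}

# splice-site windows (coding-strand logic): for each intron, the 2 donor and
# 2 acceptor bases in locus coordinates
splice_windows <- function(model) {
  ex <- model$exons
  n <- nrow(ex)
  if (n < 2L) return(NULL)
  out <- list()
  for (i in seq_len(n - 1L)) {
    is_ <- ex[i, "end"] + 1L
    ie_ <- ex[i + 1L, "start"] - 1L
    if (model$strand == "+") {
      out[[i]] <- list(intron = c(is_, ie_), donor = c(is_, is_ + 1L),
                       acceptor = c(ie_ - 1L, ie_), downstream_exon = i + 1L)
    } else {
      # coding-strand donor is at the genomic 3' end of the intron
      out[[i]] <- list(intron = c(is_, ie_), donor = c(ie_ - 1L, ie_),
                       acceptor = c(is_, is_ + 1L), downstream_exon = i)
    }
  }
  out
}

comp_base <- function(b) chartr("ACGTN", "TGCAN", b)

#' Annotate a variant against the gene model
#'
#' Decision order: splice site (within the 2 bp intron edge on the intron
#' side) > coding consequence > intronic > intergenic. Coding SNVs are typed
#' by codon comparison (synonymous / nonsynonymous / premature_stop); coding
#' indels by length difference (frameshift_indel / inframe_indel). Positions
#' in exons but outside the CDS fall through to intergenic (the models built
#' here have no UTRs).
#'
#' @param variant List or one-row data.frame with pos, ref, alt (locus
#'   coordinates; ref must match the locus sequence).
#' @param locus A `gene_locus`.
#' @param model A `gene_model` (default: the locus's gene).
#' @return A `variant_effect`: list(pos, ref, alt, category, protein_change).
#' @export
annotate_variant <- function(variant, locus, model = NULL) {
  if (is.null(model)) model <- locus$gene
  pos <- as.integer(variant$pos)
  ref <- toupper(variant$ref); alt <- toupper(variant$alt)
  seq <- locus$sequence
  if (pos < 1L || pos + nchar(ref) - 1L > nchar(seq))
    stop("variant position outside locus: ", pos)
  obs <- substr(seq, pos, pos + nchar(ref) - 1L)
  if (obs != ref)
    stop(sprintf("reference mismatch at position %d: locus has %s, variant says %s",
                 pos, obs, ref))
  mk <- function(category, protein_change = NA_character_) {
    structure(list(pos = pos, ref = ref, alt = alt, category = category,
                   protein_change = protein_change),
              class = "variant_effect")
  }
  sw <- splice_windows(model)
  for (w in sw) {
    if (pos >= w$donor[1L] && pos <= w$donor[2L]) return(mk("splice_donor"))
    if (pos >= w$acceptor[1L] && pos <= w$acceptor[2L])
      return(mk("splice_acceptor"))
  }
  ex <- model$exons
  in_exon <- any(pos >= ex[, "start"] & pos <= ex[, "end"])
  indel <- nchar(ref) != nchar(alt)
  if (in_exon) {
    tmap <- transcript_map(model)
    tpos <- match(pos, tmap)
    if (!is.na(tpos) && tpos >= model$cds[1L] && tpos <= model$cds[2L]) {
      if (indel) {
        shift <- abs(nchar(alt) - nchar(ref)) %% 3L
        return(mk(if (shift != 0L) "frameshift_indel" else "inframe_indel"))
      }
      cpos <- tpos - model$cds[1L] + 1L          # CDS-relative
      codon_idx <- (cpos - 1L) %/% 3L + 1L
      within <- (cpos - 1L) %% 3L + 1L
      cds <- cds_seq(locus, model)
      codon <- substr(cds, (codon_idx - 1L) * 3L + 1L, codon_idx * 3L)
      alt_tx <- if (model$strand == "-") comp_base(alt) else alt
      alt_codon <- codon
      substr(alt_codon, within, within) <- alt_tx
      aa_ref <- unname(Biostrings::GENETIC_CODE[codon])
      aa_alt <- unname(Biostrings::GENETIC_CODE[alt_codon])
      n_codons <- nchar(cds) %/% 3L
      change <- paste0(aa_ref, codon_idx, aa_alt)
      if (aa_alt == aa_ref) return(mk("synonymous", change))
      if (aa_alt == "*" && aa_ref != "*" && codon_idx < n_codons)
        return(mk("premature_stop", change))
      return(mk("nonsynonymous", change))
    }
    return(mk("intergenic"))   # exonic but outside CDS (no UTR modelled)
  }
  for (w in sw)
    if (pos >= w$intron[1L] && pos <= w$intron[2L]) return(mk("intronic"))
  mk("intergenic")
}

#' @export
print.variant_effect <- function(x, ...) {
  cat(sprintf("<variant_effect> %d %s>%s: %s%s\n", x$pos, x$ref, x$alt,
              x$category,
              if (!is.na(x$protein_change)) paste0(" (", x$protein_change, ")")
              else ""))
  invisible(x)
}

#' Annotate a table of variants
#' @param variants data.frame(pos, ref, alt).
#' @inheritParams annotate_variant
#' @return data.frame with one row per variant (pos, ref, alt, category,
#'   protein_change).
#' @export
annotate_variants <- function(variants, locus, model = NULL) {
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    e <- annotate_variant(variants[i, , drop = FALSE], locus, model)
    data.frame(pos = e$pos, ref = e$ref, alt = e$alt, category = e$category,
               protein_change = e$protein_change, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Predict the consequence of a disabled splice acceptor
#'
#' Disables the mutated canonical acceptor and selects the nearest downstream
#' AG dinucleotide - scanning into the exon on the coding strand - as the
#' cryptic acceptor. The transcript is re-spliced; the report carries the
#' signed cDNA length change (negative = deletion), whether the loss shifts
#' the reading frame, the translated truncated protein, and any annotated
#' domains lost (a domain is lost when translation stops before the domain's
#' last residue). With `acceptor_variant = NULL` the reference outcome
#' (delta 0, reference protein) is returned.
#'
#' @param locus A `gene_locus`.
#' @param model A `gene_model` (default: the locus's gene).
#' @param acceptor_variant List(pos, ref, alt) of a splice-acceptor variant,
#'   or NULL for the reference.
#' @param domains List of `domain_annotation` objects on the reference
#'   protein.
#' @param max_scan Maximum downstream distance (bp) scanned for a cryptic AG
#'   (default 200); if none is found the outcome status is
#'   "exon_skip_unresolved".
#' @return A `splice_outcome`: list(status, used_acceptor_pos, cdna_delta_bp,
#'   frameshift, truncated_protein, domains_lost).
#' @export
predict_cryptic_splice <- function(locus, model = NULL, acceptor_variant = NULL,
                                   domains = list(), max_scan = 200L) {
  if (is.null(model)) model <- locus$gene
  ref_protein <- translate_cds(cds_seq(locus, model))
  if (is.null(acceptor_variant)) {
    return(structure(list(status = "reference", used_acceptor_pos = NA_integer_,
                          cdna_delta_bp = 0L, frameshift = FALSE,
                          truncated_protein = as.character(ref_protein),
                          domains_lost = character(0)),
                     class = "splice_outcome"))
  }
  eff <- annotate_variant(acceptor_variant, locus, model)
  if (eff$category != "splice_acceptor")
    stop("variant is not a splice-acceptor variant (category: ", eff$category, ")")
  sw <- splice_windows(model)
  hit <- Filter(function(w) eff$pos >= w$acceptor[1L] && eff$pos <= w$acceptor[2L],
                sw)[[1L]]
  ex <- model$exons
  exon_idx <- hit$downstream_exon
  exon_iv <- ex[exon_idx, ]
  # coding-strand view of the downstream exon
  exon_seq <- substr(locus$sequence, exon_iv["start"], exon_iv["end"])
  if (model$strand == "-") exon_seq <- revcomp(exon_seq)
  ag <- regexpr("AG", substr(exon_seq, 1L, max_scan + 1L), fixed = TRUE)
  if (ag == -1L) {
    return(structure(list(status = "exon_skip_unresolved",
                          used_acceptor_pos = NA_integer_,
                          cdna_delta_bp = NA_integer_, frameshift = NA,
                          truncated_protein = NA_character_,
                          domains_lost = character(0)),
                     class = "splice_outcome"))
  }
  lost <- as.integer(ag) + 1L            # exon bases up to and incl. the AG's G
  delta <- -lost
  # locus coordinate of the cryptic AG's G (coding-strand position lost)
  used_acceptor_pos <- if (model$strand == "+") exon_iv["start"] + lost - 1L
                       else exon_iv["end"] - lost + 1L
  # re-splice: downstream exon loses its first `lost` coding-strand bases
  exon_seqs <- vapply(seq_len(nrow(ex)), function(i)
    substr(locus$sequence, ex[i, "start"], ex[i, "end"]), "")
  if (model$strand == "-") {
    exon_seqs <- rev(vapply(exon_seqs, revcomp, ""))
    order_idx <- nrow(ex):1L
  } else order_idx <- seq_len(nrow(ex))
  coding_idx <- match(exon_idx, order_idx)
  exon_seqs[coding_idx] <- substr(exon_seqs[coding_idx], lost + 1L,
                                  nchar(exon_seqs[coding_idx]))
  new_tx <- paste(exon_seqs, collapse = "")
  # transcript offset of the affected exon's first base
  exon_lens <- vapply(order_idx, function(i) ex[i, "end"] - ex[i, "start"] + 1L,
                      0L)
  p0 <- if (coding_idx == 1L) 1L else sum(exon_lens[seq_len(coding_idx - 1L)]) + 1L
  removed_before_cds <- max(0L, min(model$cds[1L] - 1L, p0 + lost - 1L) -
                              min(model$cds[1L] - 1L, p0 - 1L))
  new_cds_start <- model$cds[1L] - removed_before_cds
  trunc <- suppressWarnings(
    translate_cds(substr(new_tx, new_cds_start, nchar(new_tx))))
  trunc <- as.character(trunc)
  trunc_len <- nchar(sub("\\*$", "", trunc))
  lost_doms <- vapply(Filter(function(d) trunc_len < d$aa_end, domains),
                      `[[`, "", "name")
  structure(list(status = "ok",
                 used_acceptor_pos = unname(used_acceptor_pos),
                 cdna_delta_bp = delta,
                 frameshift = (lost %% 3L) != 0L,
                 truncated_protein = trunc,
                 domains_lost = lost_doms),
            class = "splice_outcome")
}

#' @export
print.splice_outcome <- function(x, ...) {
  cat(sprintf("<splice_outcome> %s: delta %s bp, frameshift=%s, domains lost: %s\n",
              x$status, x$cdna_delta_bp, x$frameshift,
              if (length(x$domains_lost)) paste(x$domains_lost, collapse = ",")
              else "none"))
  invisible(x)
}

#' Functional class of a haplotype from its variant effects
#'
#' @param categories Character vector of effect categories for the
#'   haplotype's alternate alleles (ignored when `is_h0`).
#' @param is_h0 TRUE for the whole-gene deletion class.
#' @return "deleted", "splice_defective", "truncated" or "functional".
#' @export
classify_haplotype_function <- function(categories, is_h0 = FALSE) {
  if (is_h0) return("deleted")
  if (any(categories %in% c("splice_acceptor", "splice_donor")))
    return("splice_defective")
  if (any(categories %in% c("premature_stop", "frameshift_indel")))
    return("truncated")
  "functional"
}
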