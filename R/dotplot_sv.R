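## Assembly-vs-reference comparison through exact k-mer anchors: dot-plot
## tables and inference of the gene-spanning deletion plus accompanying SV
## segments.

kmer_positions <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(data.table::data.table(kmer = character(0), pos = integer(0)))
  data.table::data.table(kmer = substring(seq, 1:(n - k + 1L), k:n),
                         pos = 1:(n - k + 1L))
}

# Merge diagonal runs of shared k-mers into anchors.
runs_to_anchors <- function(joined, k) {
  if (nrow(joined) == 0L)
    return(data.table::data.table(ref_start = integer(0), ref_end = integer(0),
                                  qs = integer(0), qe = integer(0)))
  diagid <- qpos <- rpos <- run <- NULL  # NSE columns
  joined[, diagid := rpos - qpos]
  data.table::setorder(joined, diagid, qpos)
  joined[, run := cumsum(c(1L, diff(qpos) != 1L | diff(diagid) != 0L))]
  out <- joined[, list(ref_start = min(rpos), ref_end = max(rpos) + k - 1L,
                       qs = min(qpos), qe = max(qpos) + k - 1L), by = run]
  out[, run := NULL]
  out
}

#' Exact k-mer anchors between two sequences
#'
#' Finds all maximal runs of consecutive shared k-mers between a reference and
#' an accession sequence, on the forward and the reverse-complement strand,
#' and merges each run into an anchor. K-mers occurring more than `max_occ`
#' times in either sequence are skipped (repeat masking); anchors shorter than
#' `min_len` are dropped (suppresses chance exact matches between unrelated
#' sequence, which at locus scale would otherwise speckle the dot plot).
#'
#' @param ref,acc DNA character scalars.
#' @param k K-mer size, >= 8 (default 16).
#' @param max_occ Repeat-masking occurrence cap (default 8).
#' @param min_len Minimum anchor length retained (default `k + 8`).
#' @return data.frame with columns ref_start, ref_end, acc_start, acc_end
#'   (1-based inclusive) and orientation ("forward"/"inverted"), sorted by
#'   ref_start; attribute `k` records the k-mer size.
#' @export
kmer_anchors <- function(ref, acc, k = 16L, max_occ = 8L, min_len = k + 8L) {
  if (k < 8L) stop("k must be >= 8")
  if (nchar(ref) == 0L || nchar(acc) == 0L) stop("sequences must be nonempty")
  ref <- toupper(ref); acc <- toupper(acc)
  kmer <- N <- NULL  # NSE columns
  rdt <- kmer_positions(ref, k)
  rdt <- rdt[, if (.N <= max_occ) .SD, by = kmer]
  anchors_against <- function(query, orientation) {
    qdt <- kmer_positions(query, k)
    qdt <- qdt[, if (.N <= max_occ) .SD, by = kmer]
    j <- merge(rdt[, list(kmer, rpos = pos)], qdt[, list(kmer, qpos = pos)],
               by = "kmer", allow.cartesian = TRUE)
    a <- runs_to_anchors(j, k)
    if (nrow(a) == 0L) return(NULL)
    if (orientation == "forward") {
      a[, list(ref_start, ref_end, acc_start = qs, acc_end = qe,
               orientation = "forward")]
    } else {
      n_acc <- nchar(acc)
      a[, list(ref_start, ref_end,
               acc_start = n_acc - qe + 1L, acc_end = n_acc - qs + 1L,
               orientation = "inverted")]
    }
  }
  out <- data.table::rbindlist(list(anchors_against(acc, "forward"),
                                    anchors_against(revcomp(acc), "inverted")))
  if (nrow(out) > 0L) {
    out <- out[(ref_end - ref_start + 1L) >= min_len]
    data.table::setorder(out, ref_start, acc_start)
    out <- as.data.frame(out)
  } else {
    out <- data.frame(ref_start = integer(0), ref_end = integer(0),
                      acc_start = integer(0), acc_end = integer(0),
                      orientation = character(0), stringsAsFactors = FALSE)
  }
  attr(out, "k") <- as.integer(k)
  out
}

# Weighted longest increasing subsequence over forward anchors; weight =
# reference-side anchor length, ties broken toward the smaller reference
# coordinate (earlier anchor kept).
chain_forward <- function(fw) {
  n <- nrow(fw)
  if (n == 0L) return(fw)
  fw <- fw[order(fw$ref_start, fw$acc_start), , drop = FALSE]
  w <- fw$ref_end - fw$ref_start + 1L
  best <- w
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (fw$ref_end[j] < fw$ref_start[i] && fw$acc_end[j] < fw$acc_start[i] &&
          best[j] + w[i] > best[i]) {
        best[i] <- best[j] + w[i]
        prev[i] <- j
      }
    }
  }
  i <- which.max(best)
  keep <- integer(0)
  while (!is.na(i)) { keep <- c(i, keep); i <- prev[i] }
  fw[keep, , drop = FALSE]
}

merge_close <- function(df, gap) {
  # merge rows (sorted by ref_start) whose ref gap <= gap
  if (nrow(df) == 0L) return(df)
  df <- df[order(df$ref_start), , drop = FALSE]
  grp <- cumsum(c(1L, (df$ref_start[-1L] - df$ref_end[-nrow(df)] - 1L) > gap))
  do.call(rbind, lapply(split(df, grp), function(d) {
    data.frame(ref_start = min(d$ref_start), ref_end = max(d$ref_end),
               acc_start = min(d$acc_start), acc_end = max(d$acc_end))
  }))
}

#' Chain anchors and classify structural-variant segments
#'
#' Chains collinear forward anchors (weighted longest increasing subsequence),
#' reports the deletion span as the maximal reference interval containing the
#' gene that is covered by no anchor while flanked by chained anchors on both
#' sides, types inverted-anchor chains as inversion segments, and types
#' inter-anchor gaps with both reference and accession gaps >= `min_sub` as
#' substitutions. The gene is called present when forward anchors cover at
#' least `min_gene_cov` of its span.
#'
#' @param anchors Output of [kmer_anchors()].
#' @param locus The reference `gene_locus`.
#' @param min_gene_cov Forward-coverage fraction of the gene span required to
#'   call the gene present (default 0.9).
#' @param min_sub Minimum gap (bp) on both sides for a substitution segment
#'   (default 50).
#' @return An `sv_report`: list(deletion_span, segments, gene_present,
#'   unalignable).
#' @export
chain_and_classify <- function(anchors, locus, min_gene_cov = 0.9,
                               min_sub = 50L) {
  sp <- gene_span(locus$gene)
  empty_seg <- data.frame(type = character(0), ref_start = integer(0),
                          ref_end = integer(0), acc_start = integer(0),
                          acc_end = integer(0), stringsAsFactors = FALSE)
  if (is.null(anchors) || nrow(anchors) == 0L) {
    return(structure(list(deletion_span = NULL,
                          segments = data.frame(type = "unaligned",
                                                ref_start = 1L,
                                                ref_end = nchar(locus$sequence),
                                                acc_start = NA_integer_,
                                                acc_end = NA_integer_),
                          gene_present = FALSE, unalignable = TRUE),
                     class = "sv_report"))
  }
  fw <- anchors[anchors$orientation == "forward", , drop = FALSE]
  inv <- anchors[anchors$orientation == "inverted", , drop = FALSE]
  chained <- chain_forward(fw)

  gene_ir <- IRanges::IRanges(sp[1L], sp[2L])
  cov_fw <- if (nrow(fw)) sum(IRanges::width(IRanges::intersect(
    IRanges::reduce(IRanges::IRanges(fw$ref_start, fw$ref_end)), gene_ir)))
    else 0L
  gene_present <- cov_fw >= min_gene_cov * (sp[2L] - sp[1L] + 1L)

  # reference intervals covered by any anchor
  cov_all <- IRanges::reduce(IRanges::IRanges(anchors$ref_start,
                                              anchors$ref_end))
  deletion_span <- NULL
  if (nrow(chained) >= 2L) {
    gaps <- IRanges::gaps(cov_all)
    for (g in seq_along(gaps)) {
      gs <- IRanges::start(gaps)[g]; ge <- IRanges::end(gaps)[g]
      if (gs <= sp[1L] && ge >= sp[2L] &&
          any(chained$ref_end < gs) && any(chained$ref_start > ge)) {
        deletion_span <- c(gs, ge)
        break
      }
    }
  }

  segments <- empty_seg
  # collinear segments: chained anchor runs merged over small gaps
  if (nrow(chained) > 0L) {
    col <- merge_close(chained[, c("ref_start", "ref_end", "acc_start",
                                   "acc_end")], gap = min_sub)
    segments <- rbind(segments, cbind(type = "collinear", col))
  }
  # inversion segments: merged inverted-anchor chains
  if (nrow(inv) > 0L) {
    iv <- merge_close(inv[, c("ref_start", "ref_end", "acc_start", "acc_end")],
                      gap = 100L)
    segments <- rbind(segments, cbind(type = "inversion", iv))
  }
  # substitution segments: gaps between consecutive chained anchors that are
  # large on both sides and not explained by an inversion
  if (nrow(chained) >= 2L) {
    for (i in seq_len(nrow(chained) - 1L)) {
      rg <- c(chained$ref_end[i] + 1L, chained$ref_start[i + 1L] - 1L)
      ag <- c(chained$acc_end[i] + 1L, chained$acc_start[i + 1L] - 1L)
      rgap <- rg[2L] - rg[1L] + 1L
      agap <- ag[2L] - ag[1L] + 1L
      if (rgap >= min_sub && agap >= min_sub) {
        has_inv <- nrow(inv) > 0L &&
          any(inv$ref_start <= rg[2L] & inv$ref_end >= rg[1L])
        if (!has_inv)
          segments <- rbind(segments,
                            data.frame(type = "substitution",
                                       ref_start = rg[1L], ref_end = rg[2L],
                                       acc_start = ag[1L], acc_end = ag[2L]))
      }
    }
  }
  segments <- segments[order(segments$ref_start), , drop = FALSE]
  rownames(segments) <- NULL
  structure(list(deletion_span = deletion_span, segments = segments,
                 gene_present = gene_present, unalignable = FALSE),
            class = "sv_report")
}

#' @export
print.sv_report <- function(x, ...) {
  ds <- if (is.null(x$deletion_span)) "none"
        else sprintf("%d-%d (%d bp)", x$deletion_span[1L], x$deletion_span[2L],
                     diff(x$deletion_span) + 1L)
  cat(sprintf("<sv_report> gene_present=%s deletion_span=%s, %d segment(s)\n",
              x$gene_present, ds, nrow(x$segments)))
  invisible(x)
}

#' Plot-ready dot-plot table
#'
#' One row per anchor with a render colour following the usual dot-plot
#' convention: forward anchors black, inverted anchors red.
#'
#' @param anchors Output of [kmer_anchors()].
#' @return data.frame(ref_start, ref_end, acc_start, acc_end, orientation,
#'   color).
#' @export
dotplot_table <- function(anchors) {
  if (is.null(anchors) || nrow(anchors) == 0L)
    return(data.frame(ref_start = integer(0), ref_end = integer(0),
                      acc_start = integer(0), acc_end = integer(0),
                      orientation = character(0), color = character(0)))
  data.frame(anchors[, c("ref_start", "ref_end", "acc_start", "acc_end",
                         "orientation")],
             color = ifelse(anchors$orientation == "inverted", "red", "black"),
             stringsAsFactors = FALSE)
}
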