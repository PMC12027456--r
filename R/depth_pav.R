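## Presence/absence calling of the gene from short-read depth over three
## diagnostic 400 bp intervals: a (upstream conserved flank), b (inside the
## gene at the exon-2/intron junction), c (downstream conserved flank).

#' Place the three diagnostic depth intervals
#'
#' Interval `a` is the `interval_len` window ending `margin` bp before the
#' deletion span start, `c` the window starting `margin` bp after its end, and
#' `b` the window centred on the junction between the intron end and the last
#' exon's start (the exon-2/intron junction of a two-exon gene).
#'
#' @param locus A `gene_locus`.
#' @param deletion_span Length-2 integer vector (ref_start, ref_end) of the
#'   deletion; must cover the gene span.
#' @param interval_len Window length in bp (default 400).
#' @param margin Distance between the deletion edge and intervals a/c
#'   (default 500).
#' @return A `depth_intervals` list with elements a, b, c, each c(start, end).
#' @export
place_intervals <- function(locus, deletion_span, interval_len = 400L,
                            margin = 500L) {
  sp <- gene_span(locus$gene)
  ds <- as.integer(deletion_span)
  L <- nchar(locus$sequence)
  if (ds[1L] > sp[1L] || ds[2L] < sp[2L])
    stop("deletion_span must cover the gene span")
  a <- c(ds[1L] - margin - interval_len, ds[1L] - margin - 1L)
  cc <- c(ds[2L] + margin + 1L, ds[2L] + margin + interval_len)
  if (a[1L] < 1L)
    stop("insufficient upstream flank for interval a (needs ",
         interval_len + margin, " bp before the deletion span)")
  if (cc[2L] > L)
    stop("insufficient downstream flank for interval c (needs ",
         interval_len + margin, " bp after the deletion span)")
  ex <- locus$gene$exons
  junction <- ex[nrow(ex), "start"]  # last exon start = intron/exon boundary
  b <- c(junction - interval_len %/% 2L,
         junction + interval_len - interval_len %/% 2L - 1L)
  if (b[1L] < sp[1L] || b[2L] > sp[2L])
    stop("interval b does not fit inside the gene span")
  structure(list(a = a, b = b, c = cc, interval_len = as.integer(interval_len)),
            class = "depth_intervals")
}

#' Intervals as a BED data.frame (0-based half-open)
#' @param intervals A `depth_intervals`.
#' @param chrom Chromosome name.
#' @return data.frame(chrom, start, end, name).
#' @export
intervals_to_bed <- function(intervals, chrom = "locus") {
  data.frame(chrom = chrom,
             start = c(intervals$a[1L], intervals$b[1L], intervals$c[1L]) - 1L,
             end = c(intervals$a[2L], intervals$b[2L], intervals$c[2L]),
             name = c("a", "b", "c"), stringsAsFactors = FALSE)
}

# Accepts an integer vector indexed by position, a data.frame/data.table with
# pos/depth columns, or a TSV path (chrom, pos, depth).
resolve_depth <- function(depth) {
  if (is.character(depth) && length(depth) == 1L) {
    if (!file.exists(depth)) stop("depth file not found: ", depth)
    depth <- data.table::fread(depth)
  }
  depth
}

#' Mean depth over an interval
#'
#' Positions absent from a depth table count as depth 0.
#'
#' @param depth Integer vector (element i = depth at position i), a
#'   data.frame/data.table with `pos` and `depth` columns, or a TSV path.
#' @param interval c(start, end), 1-based inclusive.
#' @return Mean reads per base over every interval position.
#' @export
mean_depth <- function(depth, interval) {
  s <- interval[1L]; e <- interval[2L]
  len <- e - s + 1L
  depth <- resolve_depth(depth)
  if (is.numeric(depth) && is.null(dim(depth))) {
    v <- depth[s:min(e, length(depth))]
    sum(v, na.rm = TRUE) / len
  } else {
    idx <- depth$pos >= s & depth$pos <= e
    sum(depth$depth[idx]) / len
  }
}

#' Classify gene presence from the three interval depths
#'
#' The statistic is the depth ratio `r = depth_b / ((depth_a + depth_c) / 2)`:
#' near 0 for a homozygous deletion, near 0.5 for a heterozygous one, near 1
#' when the gene is present. Calls: absent if `r < tau_abs`, present if
#' `r > tau_pres`, otherwise ambiguous. The present threshold sits above the
#' heterozygous band (which fluctuates symmetrically around 0.5 under Poisson
#' counting noise) and well below the present band around 1, so ambiguous
#' captures heterozygous carriers rather than splitting them at 0.5. When the
#' flank depth is 0 the ratio is undefined and the call is ambiguous with a
#' flag; flank depth below `min_flank_depth` flags low confidence.
#'
#' @param depth_a,depth_b,depth_c Mean depths of intervals a, b, c.
#' @param tau_abs Absent threshold (default 0.15).
#' @param tau_pres Present threshold (default 0.65).
#' @param min_flank_depth Low-confidence flank threshold (default 5).
#' @param accession_id Optional id carried into the result.
#' @return One-row data.frame (class `pav_call`): accession_id, depth_a,
#'   depth_b, depth_c, ratio, call, flag.
#' @export
classify_pav <- function(depth_a, depth_b, depth_c, tau_abs = 0.15,
                         tau_pres = 0.65, min_flank_depth = 5,
                         accession_id = NA_character_) {
  if (any(c(depth_a, depth_b, depth_c) < 0)) stop("negative depth")
  if (tau_abs >= tau_pres) stop("tau_abs must be < tau_pres")
  flank <- (depth_a + depth_c) / 2
  if (flank == 0) {
    r <- NA_real_
    call <- "ambiguous"
    flag <- "no_flank_depth"
  } else {
    r <- depth_b / flank
    call <- if (r < tau_abs) "absent" else if (r > tau_pres) "present"
            else "ambiguous"
    flag <- if (flank < min_flank_depth) "low_confidence" else ""
  }
  structure(data.frame(accession_id = accession_id, depth_a = depth_a,
                       depth_b = depth_b, depth_c = depth_c, ratio = r,
                       call = call, flag = flag, stringsAsFactors = FALSE),
            class = c("pav_call", "data.frame"))
}

#' Scan a cohort of depth profiles for the gene deletion
#'
#' Applies [mean_depth()] + [classify_pav()] to every accession. A missing or
#' unreadable depth source yields a per-accession error record; the scan
#' continues. Absent accessions are labelled haplotype H0.
#'
#' @param depth_source Either a named list of depth tables/vectors or a
#'   manifest data.frame with columns accession_id and depth_path.
#' @param intervals A `depth_intervals` from [place_intervals()].
#' @inheritParams classify_pav
#' @return List: `calls` (one row per accession, with `haplotype` = "H0" for
#'   absent calls and `error` messages where reading failed) and `summary`
#'   (counts per class).
#' @export
cohort_scan <- function(depth_source, intervals, tau_abs = 0.15,
                        tau_pres = 0.65, min_flank_depth = 5) {
  if (is.data.frame(depth_source)) {
    ids <- depth_source$accession_id
    srcs <- as.list(depth_source$depth_path)
  } else {
    ids <- names(depth_source)
    srcs <- depth_source
  }
  if (length(ids) == 0L) {
    empty <- classify_pav(1, 1, 1)[0, ]
    empty$error <- character(0)
    empty$haplotype <- character(0)
    return(list(calls = empty,
                summary = list(present = 0L, absent = 0L, ambiguous = 0L,
                               error = 0L)))
  }
  rows <- lapply(seq_along(ids), function(i) {
    res <- tryCatch({
      d <- resolve_depth(srcs[[i]])
      cl <- classify_pav(mean_depth(d, intervals$a),
                         mean_depth(d, intervals$b),
                         mean_depth(d, intervals$c),
                         tau_abs, tau_pres, min_flank_depth,
                         accession_id = ids[i])
      cl$error <- NA_character_
      cl
    }, error = function(e) {
      data.frame(accession_id = ids[i], depth_a = NA_real_, depth_b = NA_real_,
                 depth_c = NA_real_, ratio = NA_real_, call = "error",
                 flag = "", error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    res
  })
  calls <- do.call(rbind, rows)
  calls$haplotype <- ifelse(calls$call == "absent", "H0", NA_character_)
  summary <- as.list(table(factor(calls$call,
                                  levels = c("present", "absent", "ambiguous",
                                             "error"))))
  list(calls = calls, summary = summary)
}
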