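## PE3 prime-editing reagent design for a single-base correction: NGG
## protospacer enumeration, pegRNA 3' extension (RT template + PBS), and the
## second-nick protospacer on the opposite strand.

#' Enumerate SpCas9 protospacers (NGG PAM) on both strands
#'
#' Every 20-mer immediately 5' of an NGG, on either strand. The nick position
#' is the locus coordinate of protospacer position 17 (the Cas9n nick falls
#' between protospacer positions 17 and 18, 3 nt 5' of the PAM).
#'
#' @param seq DNA character scalar (>= 23 nt).
#' @param offset Locus coordinate of `seq`'s first base (default 1), so
#'   reported coordinates can live in a larger frame.
#' @return data.frame(strand, spacer, pam, start, end, nick_pos); start/end
#'   are the protospacer's plus-strand coordinates.
#' @export
enumerate_protospacers <- function(seq, offset = 1L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  empty <- data.frame(strand = character(0), spacer = character(0),
                      pam = character(0), start = integer(0), end = integer(0),
                      nick_pos = integer(0), stringsAsFactors = FALSE)
  if (n < 23L) return(empty)
  out <- list()
  gg <- as.integer(gregexpr("(?=GG)", seq, perl = TRUE)[[1L]])
  gg <- gg[gg >= 22L]   # PAM N at gg-1, spacer [gg-21, gg-2]
  if (length(gg) > 0L && gg[1L] != -1L) {
    s <- gg - 21L
    out$plus <- data.frame(
      strand = "+", spacer = substring(seq, s, s + 19L),
      pam = substring(seq, gg - 1L, gg + 1L),
      start = s + offset - 1L, end = s + 19L + offset - 1L,
      nick_pos = s + 16L + offset - 1L, stringsAsFactors = FALSE)
  }
  cc <- as.integer(gregexpr("(?=CC)", seq, perl = TRUE)[[1L]])
  cc <- cc[cc >= 1L & cc + 22L <= n]   # PAM (minus strand) = CCN at [cc, cc+2]
  if (length(cc) > 0L && cc[1L] != -1L) {
    rc <- revcomp(seq)
    # minus-strand spacer [q+3, q+22] on plus = rc[n-q-21, n-q-2]
    out$minus <- data.frame(
      strand = "-", spacer = substring(rc, n - cc - 21L, n - cc - 2L),
      pam = substring(rc, n - cc - 1L, n - cc + 1L),
      start = cc + 3L + offset - 1L, end = cc + 22L + offset - 1L,
      nick_pos = cc + 6L + offset - 1L, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res[order(res$start, res$strand), , drop = FALSE]
}

#' Design a pegRNA (PE3 configuration) for a single-base edit
#'
#' Chooses the NGG protospacer whose Cas9n nick lies closest 5' of the edit on
#' its own strand (ties toward the smaller coordinate), then builds the 3'
#' extension: PBS = reverse complement of the `pbs_len` nicked-strand bases
#' ending at the nick; RT template = reverse complement of the edited strand
#' from the nick for the smallest length >= `rt_min` that covers the edit
#' plus at least 3 downstream bases (capped by `rt_max`). The extension is
#' written 5'->3' as RT template then PBS. A PE3 second-nick protospacer is
#' sought on the opposite strand with nick distance inside `pe3_window`
#' (closest to the window midpoint); if none exists the design is returned
#' with a warning and `pe3_spacer = NULL`.
#'
#' @param locus A `gene_locus` or plain DNA character scalar.
#' @param edit List(pos, ref, alt): 1-based locus position, reference base
#'   (must match), desired base.
#' @param pbs_len Primer-binding-site length (default 12).
#' @param rt_min,rt_max RT-template length bounds (defaults 10, 16).
#' @param pe3_window Allowed nick-to-nick distance for the PE3 guide
#'   (default c(40, 90)).
#' @return A `pegrna_design`: spacer, pam, strand, nick_pos, pbs,
#'   rt_template, extension, pe3_spacer, pe3_nick_pos, edit.
#' @export
design_pegrna <- function(locus, edit, pbs_len = 12L, rt_min = 10L,
                          rt_max = 16L, pe3_window = c(40L, 90L)) {
  seq <- if (inherits(locus, "gene_locus")) locus$sequence else toupper(locus)
  pos <- as.integer(edit$pos)
  ref <- toupper(edit$ref); alt <- toupper(edit$alt)
  if (substr(seq, pos, pos) != ref)
    stop("edit ref base does not match locus at position ", pos)
  if (ref == alt) stop("edit ref and alt are identical")
  win <- c(max(1L, pos - 150L), min(nchar(seq), pos + 150L))
  cand <- enumerate_protospacers(substr(seq, win[1L], win[2L]),
                                 offset = win[1L])
  if (nrow(cand) > 0L) {
    d <- ifelse(cand$strand == "+", pos - cand$nick_pos, cand$nick_pos - pos)
    rt_len <- pmax(rt_min, d + 3L)
    feas <- d >= 1L & rt_len <= rt_max
    cand <- cand[feas, , drop = FALSE]
    d <- d[feas]; rt_len <- rt_len[feas]
  } else d <- integer(0)
  if (nrow(cand) == 0L)
    stop("no protospacer places the edit within the RT window ",
         sprintf("(1-%d nt 3' of a nick)", rt_max - 3L))
  o <- order(d, cand$nick_pos)
  pick <- cand[o[1L], ]
  d <- d[o[1L]]; rt_len <- rt_len[o[1L]]

  edited <- seq
  substr(edited, pos, pos) <- alt
  if (pick$strand == "+") {
    pbs_src <- substr(seq, pick$nick_pos - pbs_len + 1L, pick$nick_pos)
    rt_src <- substr(edited, pick$nick_pos + 1L, pick$nick_pos + rt_len)
  } else {
    # minus-strand sequences read 3'<-5' in plus coordinates
    pbs_src <- revcomp(substr(seq, pick$nick_pos, pick$nick_pos + pbs_len - 1L))
    rt_src <- revcomp(substr(edited, pick$nick_pos - rt_len, pick$nick_pos - 1L))
  }
  pbs <- revcomp(pbs_src)
  rt_template <- revcomp(rt_src)

  opp <- cand_all <- enumerate_protospacers(
    substr(seq, max(1L, pick$nick_pos - 200L),
           min(nchar(seq), pick$nick_pos + 200L)),
    offset = max(1L, pick$nick_pos - 200L))
  opp <- opp[opp$strand != pick$strand, , drop = FALSE]
  pe3_spacer <- NULL; pe3_nick <- NA_integer_
  if (nrow(opp) > 0L) {
    dist <- abs(opp$nick_pos - pick$nick_pos)
    ok <- dist >= pe3_window[1L] & dist <= pe3_window[2L]
    if (any(ok)) {
      opp <- opp[ok, , drop = FALSE]
      dist <- dist[ok]
      j <- which.min(abs(dist - mean(pe3_window)))
      pe3_spacer <- opp$spacer[j]
      pe3_nick <- opp$nick_pos[j]
    }
  }
  if (is.null(pe3_spacer))
    warning("no PE3 second-nick protospacer within the window; ",
            "design emitted without one")
  structure(list(spacer = pick$spacer, pam = pick$pam, strand = pick$strand,
                 nick_pos = pick$nick_pos, nick_to_edit = d,
                 pbs = pbs, rt_template = rt_template,
                 extension = paste0(rt_template, pbs),
                 pbs_len = as.integer(pbs_len), rt_len = as.integer(rt_len),
                 pe3_spacer = pe3_spacer, pe3_nick_pos = pe3_nick,
                 edit = list(pos = pos, ref = ref, alt = alt)),
            class = "pegrna_design")
}

#' @export
print.pegrna_design <- function(x, ...) {
  cat(sprintf("<pegrna_design> %s strand, spacer %s (PAM %s), nick %d\n",
              x$strand, x$spacer, x$pam, x$nick_pos))
  cat(sprintf("  extension 5'->3' (RT+PBS): %s\n", x$extension))
  cat(sprintf("  PE3 spacer: %s\n",
              if (is.null(x$pe3_spacer)) "none" else x$pe3_spacer))
  invisible(x)
}

#' Validate a pegRNA design or externally supplied reagents
#'
#' Full mode (a `pegrna_design` plus its locus): checks that revcomp(PBS)
#' equals the nicked-strand sequence ending at the nick, that
#' revcomp(RT template) equals the edited strand from the nick and contains
#' the edited base, that the extension is RT template followed by PBS, that
#' the spacer sits at its reported site with an NGG PAM, and that the PE3
#' nick (when present) lies inside the window. Reagent mode (only `spacer`
#' and `extension` given): infers the PBS length as the longest extension
#' suffix (at least `min_pbs` nt, screening out chance dinucleotide hits)
#' whose reverse complement equals a protospacer suffix ending exactly at the
#' canonical 17/18 nick.
#'
#' @param design A `pegrna_design`, or NULL in reagent mode.
#' @param locus The locus used for the design (full mode).
#' @param spacer,extension Reagent mode: printed spacer and 3' extension.
#' @param pe3_window Window used for the PE3 check (default c(40, 90)).
#' @param min_pbs Minimum PBS length considered in reagent mode (default 8).
#' @return List with `checks` (data.frame check/pass/note), `ok` (all pass),
#'   and in reagent mode `inferred_pbs_len`.
#' @export
validate_design <- function(design = NULL, locus = NULL, spacer = NULL,
                            extension = NULL, pe3_window = c(40L, 90L),
                            min_pbs = 8L) {
  checks <- data.frame(check = character(0), pass = logical(0),
                       note = character(0), stringsAsFactors = FALSE)
  add <- function(check, pass, note = "") {
    checks[nrow(checks) + 1L, ] <<- list(check, pass, note)
  }
  if (is.null(design)) {
    stopifnot(!is.null(spacer), !is.null(extension))
    spacer <- toupper(spacer); extension <- toupper(extension)
    add("spacer_length_20", nchar(spacer) == 20L)
    inferred <- NA_integer_
    for (len in seq.int(min_pbs, min(17L, nchar(extension)))) {
      suff <- substr(extension, nchar(extension) - len + 1L, nchar(extension))
      if (revcomp(suff) == substr(spacer, 17L - len + 1L, 17L))
        inferred <- len
    }
    add("pbs_matches_protospacer_suffix_at_nick", !is.na(inferred),
        if (is.na(inferred)) "no extension suffix maps to the 17/18 nick"
        else sprintf("inferred pbs_len = %d", inferred))
    return(list(checks = checks, ok = all(checks$pass),
                inferred_pbs_len = inferred))
  }
  stopifnot(inherits(design, "pegrna_design"), !is.null(locus))
  seq <- if (inherits(locus, "gene_locus")) locus$sequence else toupper(locus)
  edited <- seq
  substr(edited, design$edit$pos, design$edit$pos) <- design$edit$alt
  nick <- design$nick_pos
  pl <- nchar(design$pbs); rl <- nchar(design$rt_template)
  if (design$strand == "+") {
    nicked_end <- substr(seq, nick - pl + 1L, nick)
    rt_target <- substr(edited, nick + 1L, nick + rl)
  } else {
    nicked_end <- revcomp(substr(seq, nick, nick + pl - 1L))
    rt_target <- revcomp(substr(edited, nick - rl, nick - 1L))
  }
  add("pbs_complements_nicked_strand", revcomp(design$pbs) == nicked_end)
  add("rt_complements_edited_strand", revcomp(design$rt_template) == rt_target)
  alt_on_strand <- if (design$strand == "+") design$edit$alt
                   else comp_base(design$edit$alt)
  d <- design$nick_to_edit
  add("rt_encodes_edit",
      !is.null(d) && d >= 1L && d <= rl &&
        substr(rt_target, d, d) == alt_on_strand,
      "edited base at nick-to-edit offset inside the RT target")
  add("extension_is_rt_then_pbs",
      design$extension == paste0(design$rt_template, design$pbs))
  spacer_plus <- if (design$strand == "+") design$spacer else revcomp(design$spacer)
  start <- if (design$strand == "+") nick - 16L else nick - 3L
  add("spacer_matches_genome",
      substr(seq, start, start + 19L) == spacer_plus)
  pam_plus <- if (design$strand == "+") substr(seq, start + 20L, start + 22L)
              else revcomp(substr(seq, start - 3L, start - 1L))
  add("pam_is_NGG", substr(pam_plus, 2L, 3L) == "GG")
  if (!is.null(design$pe3_spacer)) {
    dd <- abs(design$pe3_nick_pos - nick)
    add("pe3_nick_in_window", dd >= pe3_window[1L] && dd <= pe3_window[2L],
        sprintf("distance %d", dd))
  }
  list(checks = checks, ok = all(checks$pass))
}
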