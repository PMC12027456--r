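## End-to-end orchestration: simulate a cohort, genotype it by depth and by
## in-silico PCR, type haplotypes, and write machine-readable outputs plus a
## provenance record. Serves as the package's single-call front end.

#' Run the full locus pipeline on a synthetic cohort
#'
#' Chains the stages end to end under one seed: reference + accession
#' simulation, dot-plot SV inference on a subset of carriers, depth-based
#' presence/absence calling of the whole cohort, PCR assay design +
#' simulation on every assembly, SNP-matrix simulation and haplotype typing
#' (H0 attached from the depth calls), and a neighbor-joining haplotype
#' tree. All tables are written as TSV, the tree as newick, and a provenance
#' JSON (package version, seed, config hash) accompanies every run.
#'
#' @param out_dir Output directory (created if needed).
#' @param cfg A [sim_config()]; its seed drives every stage.
#' @param n_dotplot How many deletion carriers to push through the dot-plot
#'   stage (default 3; the stage is per-accession and independent).
#' @return Invisibly, a list with the in-memory results: locus, truth,
#'   pav (cohort scan), assay, pcr_calls, haplotypes, tree, paths.
#' @export
run_pipeline <- function(out_dir, cfg = sim_config(), n_dotplot = 3L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  locus <- simulate_reference(cfg)
  sim <- simulate_accessions(cfg, locus)
  truth <- sim$truth
  del <- truth$deletion_span

  # dot-plot SV inference on a few carriers
  carrier_ids <- truth$accessions$accession_id[!truth$accessions$gene_present]
  dp_ids <- utils::head(carrier_ids, n_dotplot)
  sv_reports <- lapply(dp_ids, function(id) {
    anc <- kmer_anchors(locus$sequence, sim$assemblies[[id]])
    chain_and_classify(anc, locus)
  })
  names(sv_reports) <- dp_ids

  # depth-based presence/absence over the cohort
  intervals <- place_intervals(locus, del)
  depths <- simulate_depth(cfg, locus, truth, as = "vector")
  pav <- cohort_scan(depths, intervals)

  # PCR assay on every assembly
  assay <- design_assay(locus, del)
  pcr_calls <- data.frame(
    accession_id = names(sim$assemblies),
    call = vapply(sim$assemblies,
                  function(tpl) run_assay(assay, tpl)$call, ""),
    stringsAsFactors = FALSE)

  # haplotype typing with H0 from the depth stage
  snp <- simulate_snp_matrix(cfg, locus)
  h0 <- pav$calls$accession_id[pav$calls$call == "absent"]
  filt <- filter_samples(snp$matrix)
  haps <- collapse_haplotypes(filt$matrix, h0_carriers = h0)
  freqs <- subpop_frequencies(haps, snp$metadata)
  tree <- if (nrow(haps$alleles) >= 3L) nj_tree(haps) else NULL

  paths <- list(
    calls = file.path(out_dir, "pav_calls.tsv"),
    pcr = file.path(out_dir, "pcr_calls.tsv"),
    haplotypes = file.path(out_dir, "haplotypes.tsv"),
    frequencies = file.path(out_dir, "subpop_frequencies.tsv"),
    tree = file.path(out_dir, "haplotypes.nwk"),
    vcf = file.path(out_dir, "snp_matrix.vcf"),
    provenance = file.path(out_dir, "provenance.json"))
  utils::write.table(pav$calls, paths$calls, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(pcr_calls, paths$pcr, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(haps$table, paths$haplotypes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(freqs, paths$frequencies, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(tree)) write_newick(tree, paths$tree)
  write_snp_vcf(snp$matrix, paths$vcf)

  cfg_file <- tempfile()
  writeLines(vapply(names(unclass(cfg)), function(k)
    paste(k, paste(format(cfg[[k]]), collapse = ","), sep = "="), ""), cfg_file)
  prov <- list(package = "locuspav",
               version = as.character(utils::packageVersion("locuspav")),
               seed = cfg$seed,
               config_hash = unname(tools::md5sum(cfg_file)),
               n_accessions = cfg$n_accessions)
  unlink(cfg_file)
  jsonlite::write_json(prov, paths$provenance, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(locus = locus, truth = truth, sv_reports = sv_reports,
                 pav = pav, assay = assay, pcr_calls = pcr_calls,
                 haplotypes = haps, frequencies = freqs, tree = tree,
                 paths = paths))
}
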