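#' Simulate a dataset and record provenance
#'
#' Wraps [generate_dataset]: writes the dataset files plus `config.json`
#' (the effective configuration) and `provenance.json` (package version,
#' seed, a hash of the configuration, and per-file stage counts) into
#' `outdir`, so a run can be reproduced from its output directory alone.
#'
#' @param config a [sim_config].
#' @param outdir output directory.
#' @param design a [cross_design].
#' @return Invisibly, the [generate_dataset] result.
#' @export
run_simulate <- function(config, outdir, design = default_cross_design()) {
  ds <- generate_dataset(config, outdir, design)
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA)
  writeLines(cfg_json, file.path(outdir, "config.json"), useBytes = TRUE)
  write_provenance(
    file.path(outdir, "provenance.json"), config$seed, cfg_json,
    list(n_sites = nrow(ds$truth_genotypes$sites),
         n_genes = nrow(ds$truth_genotypes$truth),
         n_count_records = nrow(ds$counts)))
  invisible(ds)
}

write_provenance <- function(path, seed, cfg_json, stage_counts) {
  prov <- list(package = "crossASE",
               version = as.character(utils::packageVersion("crossASE")),
               seed = seed,
               config_hash = fnv1a32(as.character(cfg_json)),
               stage_counts = stage_counts)
  writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE, digits = NA),
             path, useBytes = TRUE)
  invisible(path)
}

default_parent_breed_map <- function()
  c(KNP_M = "KNP", KNP_F = "KNP", LR_M = "Landrace", LR_F = "Landrace")

default_joint_breed_map <- function()
  c(KNP = "KNP", Landrace = "Landrace")

#' Select informative SNPs from VCFs under one or both strategies
#'
#' Composes the selection pipeline — hard site filters, exon assignment,
#' informative-SNP selection — for the individual-mapping strategy I
#' (four-parent VCF), the joint-mapping strategy II (two per-breed samples),
#' or both, in which case the two informative sets are also compared. Per
#' stage in/out counts are logged (raw sites, post-filter, exonic,
#' informative) and written to `filter_report.tsv` when `outdir` is given,
#' together with `informative_<strategy>.tsv`.
#'
#' @param parents_vcf path to the four-parent VCF (strategy I).
#' @param joint_vcf path to the per-breed joint VCF (strategy II).
#' @param bed_path exon annotation BED.
#' @param strategy `"I"`, `"II"` or `"both"`.
#' @param filter a [filter_config].
#' @param parent_breed_map,joint_breed_map sample-to-breed maps.
#' @param require_breed_agreement see [select_informative].
#' @param design a [cross_design] (used only by relaxed selection).
#' @param outdir optional output directory for TSV results.
#' @param verbose log per-stage counts with `message()`.
#' @return A list with `informative` (per strategy), `report` (stage-count
#'   data.frame) and, when both strategies run, `overlap`
#'   (see [compare_strategies]).
#' @export
run_select <- function(parents_vcf = NULL, joint_vcf = NULL, bed_path,
                       strategy = c("both", "I", "II"),
                       filter = filter_config(),
                       parent_breed_map = default_parent_breed_map(),
                       joint_breed_map = default_joint_breed_map(),
                       require_breed_agreement = TRUE, design = NULL,
                       outdir = NULL, verbose = FALSE) {
  strategy <- match.arg(strategy)
  ann <- read_bed(bed_path)
  want <- if (strategy == "both") c("I", "II") else strategy
  informative <- list()
  report <- list()
  for (st in want) {
    vcf <- if (st == "I") parents_vcf else joint_vcf
    bm <- if (st == "I") parent_breed_map else joint_breed_map
    if (is.null(vcf)) stopf("strategy %s needs its VCF input", st)
    vt <- read_vcf(vcf, names(bm))
    filt <- filter_sites(vt, filter, strategy = st)
    exonic <- assign_exonic(filt$sites, ann)
    inf <- select_informative(
      exonic$sites, strategy = st, breed_map = bm,
      require_breed_agreement = require_breed_agreement, design = design)
    informative[[st]] <- inf
    report[[st]] <- data.frame(
      strategy = st,
      raw = n_sites(vt) + sum(vt$dropped),
      snp = n_sites(vt),
      removed_fs = filt$removed[["fs"]], removed_qd = filt$removed[["qd"]],
      removed_cluster = filt$removed[["cluster"]],
      removed_dp = filt$removed[["dp"]],
      filtered = filt$removed[["retained"]],
      exonic = n_sites(exonic$sites),
      informative = nrow(inf))
    if (verbose)
      message(sprintf(
        "strategy %s: %d raw -> %d SNP -> %d filtered -> %d exonic -> %d informative",
        st, report[[st]]$raw, report[[st]]$snp, report[[st]]$filtered,
        report[[st]]$exonic, report[[st]]$informative))
  }
  report <- do.call(rbind, report)
  out <- list(informative = informative, report = report)
  if (length(want) == 2)
    out$overlap <- compare_strategies(informative$I, informative$II)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (st in want)
      write_informative(informative[[st]],
                        file.path(outdir,
                                  paste0("informative_", st, ".tsv")))
    write_tsv(report, file.path(outdir, "filter_report.tsv"))
  }
  out
}

#' Run the ASE stage over count tables, with optional truth comparison
#'
#' Reads the per-pool count tables, runs [run_ase], and — when a simulation
#' truth table is supplied — builds a confusion matrix of called pattern
#' against true ASE mode. Results are written to `outdir` when given
#' (`ase_results.tsv`, `ase_summary.json`, `confusion.tsv`).
#'
#' @param informative informative-SNP data.frame or TSV path.
#' @param counts data.frame, or character vector of count TSV paths.
#' @param design a [cross_design].
#' @param truth truth data.frame or TSV path (optional).
#' @inheritParams run_ase
#' @param outdir optional output directory.
#' @return The [run_ase] result list, plus `confusion` when truth is given.
#' @export
run_ase_pipeline <- function(informative, counts,
                             design = default_cross_design(), truth = NULL,
                             alpha = 0.05, lo = 0.3, hi = 0.7,
                             williams = FALSE, per_snp = FALSE, bh = FALSE,
                             outdir = NULL) {
  if (is.character(informative)) informative <- read_informative(informative)
  if (is.character(counts))
    counts <- do.call(rbind, lapply(counts, read_counts))
  res <- run_ase(informative, counts, design, alpha = alpha, lo = lo,
                 hi = hi, williams = williams, per_snp = per_snp, bh = bh)
  if (!is.null(truth)) {
    if (is.character(truth)) truth <- read_truth(truth)
    res$confusion <- confusion_matrix(res$results, truth)
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_ase_results(res$results, file.path(outdir, "ase_results.tsv"))
    writeLines(jsonlite::toJSON(res$summary, auto_unbox = TRUE, digits = NA),
               file.path(outdir, "ase_summary.json"), useBytes = TRUE)
    if (!is.null(res$confusion))
      write_tsv(as.data.frame.matrix(res$confusion),
                file.path(outdir, "confusion.tsv"))
  }
  res
}

#' Confusion matrix of called pattern vs simulated truth
#'
#' Cross-tabulates the true ASE mode against the called cross-pattern for
#' the genes present in a result table. Row sums equal the per-mode truth
#' counts among evaluated genes.
#'
#' @param results result data.frame from [run_ase].
#' @param truth truth data.frame (see [read_truth]).
#' @return A contingency `table` (true mode x called pattern).
#' @export
confusion_matrix <- function(results, truth) {
  m <- merge(results[, c("gene_id", "pattern")],
             truth[, c("gene_id", "true_mode")], by = "gene_id")
  table(true_mode = factor(m$true_mode, levels = ASE_MODES),
        pattern = factor(m$pattern, levels = ASE_PATTERNS))
}

#' Simulate, select and analyze in one call
#'
#' End-to-end driver: generates a synthetic dataset, selects informative
#' SNPs under the requested strategy (or both), runs the ASE stage on the
#' strategy-I informative set (falling back to II when only II is run), and
#' compares calls with the simulation truth. All stage outputs and a
#' provenance record land in `outdir`. Deterministic for a fixed
#' configuration.
#'
#' @param config a [sim_config].
#' @param outdir output directory.
#' @param strategy `"I"`, `"II"` or `"both"`.
#' @param design a [cross_design].
#' @inheritParams run_ase
#' @return A list: `dataset`, `selection`, `ase`.
#' @export
run_pipeline <- function(config, outdir, strategy = "both",
                         design = default_cross_design(), alpha = 0.05,
                         lo = 0.3, hi = 0.7, williams = FALSE,
                         per_snp = FALSE, bh = FALSE) {
  ds <- run_simulate(config, file.path(outdir, "data"), design)
  sel <- run_select(parents_vcf = ds$paths$parents_vcf,
                    joint_vcf = ds$paths$joint_vcf,
                    bed_path = ds$paths$exons_bed, strategy = strategy,
                    design = design, outdir = outdir)
  inf <- sel$informative[["I"]] %||% sel$informative[["II"]]
  ase <- run_ase_pipeline(inf, ds$paths$counts_tsv, design,
                          truth = ds$paths$truth_tsv, alpha = alpha,
                          lo = lo, hi = hi, williams = williams,
                          per_snp = per_snp, bh = bh, outdir = outdir)
  list(dataset = ds, selection = sel, ase = ase)
}
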