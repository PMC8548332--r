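#' Run the full selection scan in memory
#'
#' The pipeline core: genotype QC filters, panel matching, case/control
#' allele frequencies, per-SNP PBS of the case cohort against reference and
#' outgroup panels, percentile outlier calling, case-control
#' frequency-difference pruning with Fisher's exact support, gene mapping
#' and multi-SNP gene summaries.
#'
#' @param genotypes a [genotype_table()] (cases and controls labeled).
#' @param ref_panel,out_panel `frequency_panel` objects.
#' @param annotation a `gene_annotation` (BED intervals).
#' @param config a [scan_config()].
#' @param min_depth,max_missing_fraction QC thresholds passed to
#'   [filter_genotypes()]; set `min_depth = 0` to skip depth masking.
#' @return list of class `scan_run` with elements `pbs` ([pbs()] result over
#'   scanned SNPs), `scan` ([scan_table()]), `genes` ([summarize_genes()]),
#'   `thresholds` and `counts` (per-stage record accounting).
#' @export
pbs_selection_scan <- function(genotypes, ref_panel, out_panel, annotation,
                               config = scan_config(), min_depth = 10,
                               max_missing_fraction = 0.5) {
  filtered <- filter_genotypes(genotypes, min_depth = min_depth,
                               max_missing_fraction = max_missing_fraction)
  matched <- match_panels(filtered, ref_panel, out_panel)
  tab <- matched$table
  case_f <- allele_frequencies(tab, "case")
  ctrl_f <- allele_frequencies(tab, "control")
  ref_f <- panel_frequencies(matched$ref_panel)
  out_f <- panel_frequencies(matched$out_panel)
  pbs_res <- pbs(case_f, ref_f, out_f)
  outliers <- top_outliers(pbs_res, config$pbs_percentile)
  diffs <- case_control_diff(case_f, ctrl_f)
  pruned <- prune_by_case_control(outliers, diffs, config$diff_percentile)
  gene_map <- map_snps_to_genes(tab$variants, annotation)
  scan <- scan_table(pbs_res, case_f, ctrl_f, outliers, pruned, gene_map)
  genes <- summarize_genes(scan, config)
  counts <- list(
    variants_in = nrow(genotypes$variants),
    genotypes_masked = filtered$log$genotypes_masked,
    variants_dropped_missing = filtered$log$variants_dropped_missing,
    variants_unmatched_panel = matched$n_unmatched,
    scanned = nrow(pbs_res),
    defined_pbs = sum(!is.na(pbs_res$pbs)),
    missing_pbs = sum(is.na(pbs_res$pbs)),
    outliers = length(outliers),
    excluded_case_control = length(pruned$excluded),
    retained = length(pruned$retained),
    intergenic_retained = attr(genes, "n_intergenic"),
    genes_single = sum(genes$classification == "single"),
    genes_multi = sum(genes$classification == "multi"))
  structure(list(pbs = pbs_res, scan = scan, genes = genes,
                 thresholds = list(
                   pbs_threshold = if (length(outliers) || counts$defined_pbs)
                     percentile_threshold(pbs_res$pbs, config$pbs_percentile)
                   else NA_real_,
                   diff_threshold = pruned$diff_threshold),
                 counts = counts, config = config),
            class = "scan_run")
}

#' @exportS3Method base::print
print.scan_run <- function(x, ...) {
  cat("PBS selection scan\n")
  cat(sprintf("  scanned %d SNPs (%d with defined PBS)\n",
              x$counts$scanned, x$counts$defined_pbs))
  cat(sprintf("  outliers %d -> retained %d / excluded %d (diff threshold %.4g)\n",
              x$counts$outliers, x$counts$retained,
              x$counts$excluded_case_control, x$thresholds$diff_threshold))
  cat(sprintf("  genes: %d multi-SNP candidates, %d single-SNP\n",
              x$counts$genes_multi, x$counts$genes_single))
  invisible(x)
}

write_manifest <- function(path, subcommand, config, seed, counts,
                           outputs = character()) {
  manifest <- list(tool = "pbscan",
                   version = as.character(utils::packageVersion("pbscan")),
                   subcommand = subcommand,
                   config_hash = config_hash(config),
                   seed = seed,
                   counts = counts,
                   outputs = as.list(outputs))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run the selection scan from files
#'
#' File-level wrapper over [pbs_selection_scan()]: reads the cohort VCF, two
#' frequency panels and the gene BED, runs the scan, and writes
#' `snp_scan.tsv`, `gene_summary.tsv` and a JSON `manifest.json` with the
#' per-stage record accounting into `out_dir`. Outputs are byte-deterministic
#' for identical inputs and configuration.
#'
#' @param vcf_path cohort genotype VCF.
#' @param cohort_labels named `sample -> "case"/"control"` vector.
#' @param ref_panel_path,out_panel_path panel files
#'   ([read_frequency_panel()]).
#' @param bed_path gene BED4 file.
#' @param out_dir output directory.
#' @param config a [scan_config()].
#' @param min_depth,max_missing_fraction QC thresholds.
#' @param ref_tag,out_tag population tags for VCF panels.
#' @return the `scan_run`, invisibly; side effect: report files + manifest.
#' @export
run_scan <- function(vcf_path, cohort_labels, ref_panel_path, out_panel_path,
                     bed_path, out_dir, config = scan_config(),
                     min_depth = 10, max_missing_fraction = 0.5,
                     ref_tag = "sas", out_tag = "afr") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genotypes <- read_vcf(vcf_path, cohort_labels)
  ref_panel <- read_frequency_panel(ref_panel_path, ref_tag)
  out_panel <- read_frequency_panel(out_panel_path, out_tag)
  annotation <- read_gene_bed(bed_path)
  run <- pbs_selection_scan(genotypes, ref_panel, out_panel, annotation,
                            config = config, min_depth = min_depth,
                            max_missing_fraction = max_missing_fraction)
  paths <- c(snp_scan = file.path(out_dir, "snp_scan.tsv"),
             gene_summary = file.path(out_dir, "gene_summary.tsv"),
             manifest = file.path(out_dir, "manifest.json"))
  write_report(run$scan, paths[["snp_scan"]], "snp_scan")
  write_report(run$genes, paths[["gene_summary"]], "gene_summary")
  write_manifest(paths[["manifest"]], "scan",
                 list(config = run$config, min_depth = min_depth,
                      max_missing_fraction = max_missing_fraction),
                 seed = NA, counts = run$counts,
                 outputs = paths[c("snp_scan", "gene_summary")])
  invisible(run)
}

#' Simulate a cohort and export it
#'
#' @param params a [sim_params()] object.
#' @param out_dir output directory.
#' @return the `synthetic_cohort`, invisibly; side effect: VCF, panels, BED,
#'   truth TSV and manifest in `out_dir`.
#' @export
run_simulate <- function(params, out_dir) {
  cohort <- simulate_cohort(params)
  paths <- export_cohort(cohort, out_dir)
  write_manifest(file.path(out_dir, "manifest.json"), "simulate",
                 unclass(params), seed = params$seed,
                 counts = list(n_snps = params$n_snps,
                               n_selected = params$n_selected,
                               n_case_assoc = params$n_case_assoc),
                 outputs = paths)
  invisible(cohort)
}

#' Run over-representation analysis from files
#'
#' @param query_path text file with one candidate gene name per line.
#' @param gmt_path gene-set collection (GMT).
#' @param background_path text file with one background gene name per line.
#' @param out_dir output directory.
#' @param exclude passed to [run_enrichment()]; additionally the string
#'   `"HLA"` selects the HLA-prefix filter.
#' @return the `enrichment_result`, invisibly; writes `enrichment.tsv` and a
#'   manifest.
#' @export
run_enrich <- function(query_path, gmt_path, background_path, out_dir,
                       exclude = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  query <- readLines(query_path)
  query <- query[nzchar(query)]
  background <- readLines(background_path)
  background <- background[nzchar(background)]
  collection <- read_gmt(gmt_path)
  excl <- if (identical(exclude, "HLA")) exclude_prefix("HLA-") else exclude
  res <- run_enrichment(query, collection, background, exclude = excl)
  path <- file.path(out_dir, "enrichment.tsv")
  write_report(res, path, "enrichment")
  write_manifest(file.path(out_dir, "manifest.json"), "enrich",
                 list(exclude = if (is.function(excl)) "predicate" else excl),
                 seed = NA,
                 counts = list(n_sets = nrow(res),
                               n_query_dropped = attr(res, "n_query_dropped"),
                               n_significant_q05 = sum(res$q_value < 0.05)),
                 outputs = path)
  invisible(res)
}

#' Read phased haplotypes and an archaic reference into a region
#'
#' Builds a `haplotype_region` from a phased VCF (pipe-separated GT) and an
#' archaic allele TSV with columns `chrom, pos, allele`; only biallelic SNP
#' records whose position carries an archaic allele equal to the REF or ALT
#' base are used. A diploid archaic genotype must be haploidized upstream
#' (major allele) — the TSV carries one base per site.
#'
#' @param vcf_path phased VCF.
#' @param archaic_path archaic allele TSV (`chrom, pos, allele`, no header).
#' @param region optional `"chrom:start-end"` (1-based inclusive) restriction.
#' @param pop_labels optional named `sample -> population` vector for the
#'   strip color bar.
#' @return a `haplotype_region` whose haplotypes are the phased sample
#'   haplotypes (two rows per sample, suffixed `_1`/`_2`).
#' @export
read_haplotype_region <- function(vcf_path, archaic_path, region = NULL,
                                  pop_labels = NULL) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  keep <- !grepl(",", fix$ALT, fixed = TRUE) & nchar(fix$REF) == 1L &
    nchar(fix$ALT) == 1L
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4L)
      stop_pbscan("region must be chrom:start-end", class = "pbscan_config_error")
    keep <- keep & normalize_chrom(fix$CHROM) == normalize_chrom(m[2]) &
      as.integer(fix$POS) >= as.integer(m[3]) &
      as.integer(fix$POS) <= as.integer(m[4])
  }
  arch <- utils::read.table(archaic_path, header = FALSE, sep = "",
                            col.names = c("chrom", "pos", "allele"),
                            stringsAsFactors = FALSE)
  ka <- paste(normalize_chrom(arch$chrom), arch$pos)
  kv <- paste(normalize_chrom(fix$CHROM), fix$POS)
  m <- match(kv, ka)
  keep <- keep & !is.na(m)
  idx <- which(keep)
  if (!length(idx))
    stop_pbscan("no shared biallelic SNPs between VCF and archaic table",
                class = "pbscan_insufficient_data_error")
  gt <- vcfR::extract.gt(vcf, element = "GT")[idx, , drop = FALSE]
  if (!all(grepl("|", gt, fixed = TRUE) | is.na(gt)))
    stop_pbscan("genotypes must be phased (pipe-separated)",
                class = "pbscan_format_error")
  hap1 <- t(matrix(as.integer(substr(gt, 1L, 1L)), nrow = nrow(gt)))
  hap2 <- t(matrix(as.integer(substr(gt, 3L, 3L)), nrow = nrow(gt)))
  samples <- colnames(gt)
  hap <- rbind(hap1, hap2)
  rownames(hap) <- c(paste0(samples, "_1"), paste0(samples, "_2"))
  ord <- order(rep(seq_along(samples), 2L), rep(1:2, each = length(samples)))
  hap <- hap[ord, , drop = FALSE]
  allele <- arch$allele[m[idx]]
  archaic <- ifelse(allele == fix$ALT[idx], 1L,
                    ifelse(allele == fix$REF[idx], 0L, NA_integer_))
  ok_site <- !is.na(archaic)
  labels <- if (is.null(pop_labels)) rep("modern", nrow(hap)) else
    unname(pop_labels[sub("_[12]$", "", rownames(hap))])
  structure(list(positions = as.integer(fix$POS[idx])[ok_site],
                 haplotypes = hap[, ok_site, drop = FALSE],
                 hap_labels = labels,
                 archaic = archaic[ok_site],
                 truth_introgressed = integer()),
            class = "haplotype_region")
}

#' Cluster-and-sort strip view from files
#'
#' @param vcf_path,archaic_path,region,pop_labels see
#'   [read_haplotype_region()].
#' @param out_dir output directory.
#' @param linkage clustering linkage.
#' @param min_archaic_informative minimum retained sites.
#' @return list with `encoded` and `ordering`, invisibly; writes
#'   `strips.png` (+ `.order.tsv`) and a manifest.
#' @export
run_strips <- function(vcf_path, archaic_path, out_dir, region = NULL,
                       pop_labels = NULL, linkage = "average",
                       min_archaic_informative = 2L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  reg <- read_haplotype_region(vcf_path, archaic_path, region, pop_labels)
  enc <- encode_against_archaic(reg, min_archaic_informative)
  ord <- cluster_and_sort(enc, linkage)
  img <- file.path(out_dir, "strips.png")
  paths <- render_strips(enc, ord, img)
  write_manifest(file.path(out_dir, "manifest.json"), "strips",
                 list(region = region, linkage = linkage),
                 seed = NA,
                 counts = list(n_haplotypes = nrow(enc$codes),
                               n_sites_retained = ncol(enc$codes)),
                 outputs = paths)
  invisible(list(encoded = enc, ordering = ord))
}

#' Power study over a simulation grid
#'
#' For each grid row (`delta`, `assoc_shift`, `seed`), simulates a cohort,
#' runs the scan in memory, and scores recovery against truth. All other
#' generator parameters come from `base_params`.
#'
#' @param grid data.frame with columns `delta`, `assoc_shift`, `seed`.
#' @param base_params a [sim_params()] giving the fixed parameters
#'   (`n_selected`/`n_case_assoc` should be positive for the metrics to be
#'   defined).
#' @param config a [scan_config()].
#' @param out_dir optional; when given, writes `power.tsv` and a manifest.
#' @return data.frame: the grid plus `power_selected`, `fpr_null`,
#'   `pruned_assoc_fraction`.
#' @export
run_power <- function(grid, base_params = sim_params(n_selected = 25L,
                                                     n_case_assoc = 25L),
                      config = scan_config(), out_dir = NULL) {
  if (!nrow(grid))
    stop_pbscan("empty parameter grid", class = "pbscan_config_error")
  stopifnot(all(c("delta", "assoc_shift", "seed") %in% names(grid)))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- base_params
    p$selection_shift <- grid$delta[i]
    p$assoc_shift <- grid$assoc_shift[i]
    p$seed <- as.integer(grid$seed[i])
    cohort <- simulate_cohort(p)
    run <- pbs_selection_scan(cohort$genotypes, cohort$ref_panel,
                              cohort$out_panel, cohort$annotation,
                              config = config)
    met <- evaluate_recovery(run$scan, cohort$truth)
    cbind(grid[i, , drop = FALSE], as.data.frame(met))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(out_dir, "power.tsv")
    cols <- c("delta", "assoc_shift", "seed", "power_selected", "fpr_null",
              "pruned_assoc_fraction")
    out$seed <- as.integer(out$seed)
    lines <- c(paste(cols, collapse = "\t"),
               do.call(sprintf, c(list("%g\t%g\t%d\t%.6g\t%.6g\t%.6g"),
                                  lapply(cols, function(cn) out[[cn]]))))
    write_lines_binary(lines, path)
    write_manifest(file.path(out_dir, "manifest.json"), "power",
                   list(grid = grid, base = unclass(base_params)),
                   seed = NA, counts = list(n_cells = nrow(out)),
                   outputs = path)
  }
  out
}
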