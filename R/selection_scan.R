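#' Scan configuration
#'
#' @param pbs_percentile quantile of the PBS distribution above which a SNP
#'   is an outlier (default 0.999, the top 0.1 percent rule).
#' @param diff_percentile quantile of the case-control absolute
#'   frequency-difference distribution above which an outlier is pruned
#'   (default 0.999).
#' @param min_snps_per_gene minimum surviving outlier SNPs for a gene to be
#'   classified `"multi"`, i.e. a selection candidate (default 2).
#' @return validated list of class `scan_config`.
#' @export
scan_config <- function(pbs_percentile = 0.999, diff_percentile = 0.999,
                        min_snps_per_gene = 2L) {
  if (pbs_percentile <= 0 || pbs_percentile >= 1 ||
      diff_percentile <= 0 || diff_percentile >= 1)
    stop_pbscan("percentiles must lie strictly in (0, 1)", class = "pbscan_config_error")
  if (min_snps_per_gene < 1L)
    stop_pbscan("min_snps_per_gene must be >= 1", class = "pbscan_config_error")
  structure(list(pbs_percentile = pbs_percentile,
                 diff_percentile = diff_percentile,
                 min_snps_per_gene = as.integer(min_snps_per_gene)),
            class = "scan_config")
}

#' Quantile threshold with linear interpolation of order statistics
#'
#' The q-quantile at index `h = (n - 1) q` between sorted neighbours (the
#' default convention of mainstream numeric stacks; `quantile type = 7`).
#' Missing values are excluded first.
#'
#' @param values numeric vector (at least 2 defined values expected).
#' @param q quantile in (0, 1).
#' @return the threshold value.
#' @export
#' @examples
#' percentile_threshold(1:1000, 0.999)  # 999.001
percentile_threshold <- function(values, q) {
  if (q <= 0 || q >= 1)
    stop_pbscan("q must lie strictly in (0, 1)", class = "pbscan_config_error")
  v <- values[!is.na(values)]
  if (!length(v))
    stop_pbscan("all values are missing", class = "pbscan_insufficient_data_error")
  unname(stats::quantile(v, q, type = 7, names = FALSE))
}

#' Indices of percentile-outlier SNPs
#'
#' SNPs whose PBS is strictly greater than the `q`-quantile of the defined
#' PBS distribution. With a constant distribution nothing exceeds the
#' threshold and the set is empty.
#'
#' @param pbs_result a [pbs()] result (or any data.frame with a `pbs` column).
#' @param q percentile (default 0.999).
#' @return integer vector of row indices.
#' @export
top_outliers <- function(pbs_result, q = 0.999) {
  thr <- percentile_threshold(pbs_result$pbs, q)
  which(!is.na(pbs_result$pbs) & pbs_result$pbs > thr)
}

#' Absolute case-control frequency differences
#'
#' `|p_case - p_control|` per SNP over aligned frequency vectors; missing if
#' either side is missing.
#'
#' @param case,control [freq_vector()]s over identical variant lists.
#' @return numeric vector.
#' @export
case_control_diff <- function(case, control) {
  check_aligned(case, control, "case and control frequency vectors")
  abs(case$p - control$p)
}

#' Prune outliers by case-control frequency differentiation
#'
#' Removes from the outlier set every SNP whose absolute case-control
#' frequency difference is strictly above the `q`-quantile of the difference
#' distribution computed over *all* scanned SNPs (not just outliers), so the
#' PBS and difference percentile rules are commensurate. This is the guard
#' against disease-ascertainment confounding: a truly selected SNP should not
#' separate cases from controls drawn from the same population.
#'
#' @param outliers integer indices from [top_outliers()].
#' @param diffs per-SNP differences over the full scanned SNP list
#'   ([case_control_diff()]).
#' @param q percentile (default 0.999).
#' @return list with `retained`, `excluded` (disjoint index vectors whose
#'   union is `outliers`) and `diff_threshold`.
#' @export
prune_by_case_control <- function(outliers, diffs, q = 0.999) {
  thr <- percentile_threshold(diffs, q)
  d <- diffs[outliers]
  excluded <- outliers[!is.na(d) & d > thr]
  list(retained = setdiff(outliers, excluded), excluded = excluded,
       diff_threshold = thr)
}

#' Two-sided Fisher's exact test and odds ratio on allele counts
#'
#' For 2x2 allele-count tables (rows: case/control, columns: alt/ref), the
#' two-sided exact p-value is the sum of hypergeometric probabilities of all
#' tables with the same margins whose probability does not exceed the
#' observed table's (the classical two-sided rule, identical to
#' `stats::fisher.test`). The odds ratio is the sample cross-product
#' `(alt_case * ref_control) / (ref_case * alt_control)` with no continuity
#' correction: a zero denominator with non-zero numerator yields `Inf`, a
#' zero numerator yields 0, and a doubly degenerate table yields `NaN`.
#'
#' @param alt_case,ref_case,alt_control,ref_control non-negative allele
#'   counts; vectors recycle.
#' @return data.frame with columns `p_value` and `odds_ratio`. Rows whose
#'   case or control margin is zero get `p_value = NA`.
#' @export
#' @examples
#' fisher_or(2, 8, 6, 4)
fisher_or <- function(alt_case, ref_case, alt_control, ref_control) {
  k <- max(length(alt_case), length(ref_case), length(alt_control),
           length(ref_control))
  a <- rep_len(alt_case, k); b <- rep_len(ref_case, k)
  c_ <- rep_len(alt_control, k); d <- rep_len(ref_control, k)
  if (any(c(a, b, c_, d) < 0, na.rm = TRUE))
    stop_pbscan("allele counts must be non-negative", class = "pbscan_domain_error")
  or <- (a * d) / (b * c_)
  p <- vapply(seq_len(k), function(i) {
    row1 <- a[i] + b[i]; row2 <- c_[i] + d[i]; col1 <- a[i] + c_[i]
    if (anyNA(c(row1, row2, col1)) || row1 == 0 || row2 == 0) return(NA_real_)
    n <- row1 + row2
    support <- max(0, col1 - row2):min(row1, col1)
    probs <- stats::dhyper(support, row1, row2, col1)
    p_obs <- stats::dhyper(a[i], row1, row2, col1)
    # relative tolerance guards against ties broken by floating-point error
    min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }, numeric(1))
  data.frame(p_value = p, odds_ratio = or)
}

#' Assign SNPs to overlapping gene intervals
#'
#' A SNP at 1-based position `p` lands in BED interval `(start, end)` iff
#' `start < p <= end` (half-open convention). SNPs inside several overlapping
#' genes are assigned to all of them; SNPs in no interval get an empty
#' assignment (intergenic).
#'
#' @param snps data.frame with `chrom` and `pos` columns.
#' @param annotation a [read_gene_bed()] annotation.
#' @return list (one character vector of gene names per SNP).
#' @export
map_snps_to_genes <- function(snps, annotation) {
  out <- rep(list(character()), nrow(snps))
  if (!nrow(snps) || !nrow(annotation)) return(out)
  q <- GenomicRanges::GRanges(normalize_chrom(snps$chrom),
                              IRanges::IRanges(snps$pos, snps$pos))
  s <- GenomicRanges::GRanges(normalize_chrom(annotation$chrom),
                              IRanges::IRanges(annotation$start + 1L, annotation$end))
  hits <- GenomicRanges::findOverlaps(q, s)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  for (i in seq_along(qh))
    out[[qh[i]]] <- c(out[[qh[i]]], annotation$gene[sh[i]])
  lapply(out, unique)
}

#' Assemble the per-outlier scan table
#'
#' Combines PBS values, case/control frequencies and differences, Fisher's
#' exact support and gene assignments into one table covering all outlier
#' SNPs with their pruning status. Fisher's test is reported for every
#' outlier but pruning is driven by the percentile rule alone.
#'
#' @param pbs_result a [pbs()] result.
#' @param case_freq,control_freq [freq_vector()]s aligned with `pbs_result`.
#' @param outliers,pruned outputs of [top_outliers()] and
#'   [prune_by_case_control()].
#' @param gene_map output of [map_snps_to_genes()] over the scanned SNPs.
#' @return data.frame of class `scan_result`; attributes carry the
#'   thresholds and the scanned-SNP totals used by [evaluate_recovery()].
#' @export
scan_table <- function(pbs_result, case_freq, control_freq, outliers, pruned,
                       gene_map) {
  idx <- sort(unique(c(pruned$retained, pruned$excluded)))
  stopifnot(setequal(idx, outliers))
  diffs <- abs(case_freq$p - control_freq$p)
  ac <- round(case_freq$p * case_freq$n)
  acn <- round(control_freq$p * control_freq$n)
  fe <- if (length(idx)) fisher_or(ac[idx], case_freq$n[idx] - ac[idx],
                                   acn[idx], control_freq$n[idx] - acn[idx])
        else data.frame(p_value = numeric(), odds_ratio = numeric())
  out <- data.frame(chrom = pbs_result$chrom[idx], pos = pbs_result$pos[idx],
                    ref = pbs_result$ref[idx], alt = pbs_result$alt[idx],
                    pbs = pbs_result$pbs[idx],
                    case_freq = case_freq$p[idx],
                    control_freq = control_freq$p[idx],
                    abs_diff = diffs[idx],
                    fisher_p = fe$p_value, odds_ratio = fe$odds_ratio,
                    status = ifelse(idx %in% pruned$excluded,
                                    "excluded_case_control", "retained"),
                    genes = vapply(gene_map[idx], paste, "", collapse = ";"),
                    stringsAsFactors = FALSE)
  structure(out, class = c("scan_result", "data.frame"),
            diff_threshold = pruned$diff_threshold,
            scanned = data.frame(chrom = pbs_result$chrom, pos = pbs_result$pos,
                                 ref = pbs_result$ref, alt = pbs_result$alt,
                                 stringsAsFactors = FALSE),
            n_scanned = nrow(pbs_result),
            n_defined = sum(!is.na(pbs_result$pbs)))
}

#' Aggregate retained outlier SNPs into gene summaries
#'
#' Counts the retained outlier SNPs per gene (computed strictly after
#' pruning, so a pruned SNP can demote a gene from multi to single), computes
#' the arithmetic mean PBS over member SNPs, and classifies genes as
#' `"multi"` (at least `min_snps_per_gene` SNPs, the selection candidates) or
#' `"single"`. Intergenic SNPs are dropped from summaries with a count.
#'
#' @param scan a [scan_table()] result.
#' @param config a [scan_config()].
#' @return data.frame of class `gene_summary` with columns
#'   `gene, n_snps, classification, mean_pbs`, sorted by descending
#'   `mean_pbs`; attribute `n_intergenic` counts retained outliers in no gene.
#' @export
summarize_genes <- function(scan, config = scan_config()) {
  ret <- scan[scan$status == "retained", , drop = FALSE]
  genes <- strsplit(ret$genes, ";", fixed = TRUE)
  n_intergenic <- sum(!vapply(genes, function(g) any(nzchar(g)), TRUE))
  long_gene <- unlist(genes)
  long_pbs <- rep(ret$pbs, lengths(genes))
  keep <- nzchar(long_gene)
  long_gene <- long_gene[keep]; long_pbs <- long_pbs[keep]
  if (!length(long_gene)) {
    out <- data.frame(gene = character(), n_snps = integer(),
                      classification = character(), mean_pbs = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    n_snps <- tapply(long_pbs, long_gene, length)
    mean_pbs <- tapply(long_pbs, long_gene, mean)
    out <- data.frame(gene = names(n_snps), n_snps = as.integer(n_snps),
                      classification = ifelse(n_snps >= config$min_snps_per_gene,
                                              "multi", "single"),
                      mean_pbs = as.numeric(mean_pbs), stringsAsFactors = FALSE)
    out <- out[order(-out$mean_pbs, out$gene), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, class = c("gene_summary", "data.frame"),
            n_intergenic = n_intergenic)
}

#' Recovery metrics against simulation truth
#'
#' Scores a scan against the per-SNP truth labels of a synthetic cohort:
#' `power_selected` is the fraction of truth-"selected" SNPs that end up in
#' the retained outlier set, `fpr_null` the fraction of truth-"null" SNPs
#' that do, and `pruned_assoc_fraction` the fraction of truth-"case_assoc"
#' *outliers* that the case-control rule excluded (NA when no confounded SNP
#' reached the outlier set). Denominators count truth SNPs present in the
#' scanned set.
#'
#' @param scan a [scan_table()] result.
#' @param truth data.frame `chrom, pos, ref, alt, label` (from
#'   [simulate_cohort()]).
#' @return list with `power_selected`, `fpr_null`, `pruned_assoc_fraction`.
#' @export
evaluate_recovery <- function(scan, truth) {
  scanned <- attr(scan, "scanned")
  kt <- variant_key(truth$chrom, truth$pos, truth$ref, truth$alt)
  ks <- variant_key(scanned$chrom, scanned$pos, scanned$ref, scanned$alt)
  in_scan <- kt %in% ks
  if (!any(in_scan))
    stop_pbscan("truth labels share no SNP with the scan",
                class = "pbscan_alignment_error")
  ko <- variant_key(scan$chrom, scan$pos, scan$ref, scan$alt)
  retained <- ko[scan$status == "retained"]
  outlier <- ko
  lab <- truth$label
  sel <- in_scan & lab == "selected"
  nul <- in_scan & lab == "null"
  asc <- in_scan & lab == "case_assoc"
  asc_out <- asc & kt %in% outlier
  list(power_selected = if (any(sel)) mean(kt[sel] %in% retained) else NA_real_,
       fpr_null = if (any(nul)) mean(kt[nul] %in% retained) else NA_real_,
       pruned_assoc_fraction = if (any(asc_out))
         mean(!(kt[asc_out] %in% retained)) else NA_real_)
}

#' Dot plot of multi-SNP candidate genes by mean PBS
#'
#' Plots each candidate (multi-SNP) gene against its mean PBS with point
#' size proportional to the number of member SNPs; an extreme gene can be
#' dropped from the plot for readability.
#'
#' @param summary a [summarize_genes()] result.
#' @param drop_gene optional character vector of gene names to omit from the
#'   plot (e.g. a single dominating outlier gene).
#' @param multi_only plot only `"multi"`-classified genes (default TRUE).
#' @return a ggplot object.
#' @export
plot_gene_summary <- function(summary, drop_gene = NULL, multi_only = TRUE) {
  d <- as.data.frame(summary)
  if (multi_only) d <- d[d$classification == "multi", , drop = FALSE]
  if (!is.null(drop_gene)) d <- d[!(d$gene %in% drop_gene), , drop = FALSE]
  d$gene <- factor(d$gene, levels = d$gene[order(d$mean_pbs)])
  ggplot2::ggplot(d, ggplot2::aes(x = gene, y = mean_pbs, size = n_snps)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean PBS of retained outlier SNPs",
                  size = "SNPs") +
    ggplot2::theme_minimal(base_size = 9)
}
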