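#' Per-cohort allele frequencies from genotypes
#'
#' Computes, per SNP, the alternate-allele frequency
#' `p = sum(dosages) / (2 * n_called)` over the non-missing genotypes of the
#' chosen cohort, together with the allele number `n = 2 * n_called`. A SNP
#' with no called genotype gets `p = NA`, `n = 0`.
#'
#' @param table a [genotype_table()].
#' @param cohort `"case"`, `"control"` or `"all"`.
#' @return data.frame of class `freq_vector` with columns
#'   `chrom, pos, ref, alt, p, n`; attribute `population` names the cohort.
#' @export
allele_frequencies <- function(table, cohort = c("case", "control", "all")) {
  stopifnot(inherits(table, "genotype_table"))
  cohort <- match.arg(cohort)
  cols <- if (cohort == "all") seq_len(nrow(table$samples)) else
    which(table$samples$cohort == cohort)
  if (!length(cols))
    stop_pbscan("no samples labeled '%s' in the table", cohort,
                class = "pbscan_config_error")
  g <- table$geno[, cols, drop = FALSE]
  called <- rowSums(!is.na(g))
  n <- 2 * called
  p <- ifelse(n > 0, rowSums(g, na.rm = TRUE) / pmax(n, 1), NA_real_)
  freq_vector(table$variants, p, n, population = cohort)
}

#' Assemble a frequency vector
#'
#' @param variants data.frame with `chrom, pos, ref, alt` (extra columns kept
#'   out).
#' @param p alternate-allele frequencies in `[0, 1]` (`NA` allowed iff
#'   `n == 0`).
#' @param n allele numbers.
#' @param population population name.
#' @return data.frame of class `freq_vector`.
#' @export
freq_vector <- function(variants, p, n, population = "pop") {
  stopifnot(length(p) == nrow(variants), length(n) == nrow(variants))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop_pbscan("frequencies outside [0,1]", class = "pbscan_domain_error")
  if (any(is.na(p) & n > 0))
    stop_pbscan("p may be missing only where n == 0", class = "pbscan_domain_error")
  structure(data.frame(chrom = variants$chrom, pos = variants$pos,
                       ref = variants$ref, alt = variants$alt,
                       p = as.numeric(p), n = as.numeric(n),
                       stringsAsFactors = FALSE),
            class = c("freq_vector", "data.frame"), population = population)
}

#' Frequency vector from a panel
#'
#' Converts a `frequency_panel` (AF/AN records) into a [freq_vector()].
#' Panel allele counts are reconstituted as `round(af * an)` first, so the
#' finite-sample correction of [hudson_fst()] sees frequencies that are valid
#' allele-count ratios, the same code path as cohort-derived frequencies.
#'
#' @param panel a `frequency_panel` from [read_frequency_panel()] or
#'   [simulate_cohort()].
#' @return a `freq_vector`.
#' @export
panel_frequencies <- function(panel) {
  stopifnot(inherits(panel, "frequency_panel"))
  an <- panel$an
  p <- ifelse(an > 0, round(panel$af * an) / ifelse(an > 0, an, 1), NA_real_)
  freq_vector(panel, p, an, population = attr(panel, "population"))
}

#' Hudson's per-SNP Fst estimator
#'
#' The ratio form with finite-sample correction:
#' `N = (p1 - p2)^2 - p1 (1-p1)/(n1 - 1) - p2 (1-p2)/(n2 - 1)` over
#' `D = p1 (1-p2) + p2 (1-p1)`; `fst = N / D`. The estimate is missing
#' (`NA`) when either allele number is below 2 or the site is monomorphic in
#' both populations (`D = 0`). Negative estimates are legitimate sampling
#' outcomes and are not clamped; `fst <= 1` always holds.
#'
#' @param p1,p2 alternate-allele frequencies in `[0, 1]` (`NA` allowed).
#' @param n1,n2 allele numbers (haploid sample sizes).
#' @return data.frame with columns `numerator`, `denominator`, `fst`;
#'   vectors recycle to a common length.
#' @export
#' @examples
#' hudson_fst(0.3, 100, 0.6, 100)$fst  # 0.1582492
hudson_fst <- function(p1, n1, p2, n2) {
  k <- max(length(p1), length(p2), length(n1), length(n2))
  p1 <- rep_len(as.numeric(p1), k); p2 <- rep_len(as.numeric(p2), k)
  n1 <- rep_len(as.numeric(n1), k); n2 <- rep_len(as.numeric(n2), k)
  ok1 <- !is.na(p1); ok2 <- !is.na(p2)
  if (any(p1[ok1] < 0 | p1[ok1] > 1) || any(p2[ok2] < 0 | p2[ok2] > 1))
    stop_pbscan("frequencies outside [0,1]", class = "pbscan_domain_error")
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  fst <- num / den
  bad <- is.na(p1) | is.na(p2) | n1 < 2 | n2 < 2 | den <= 0
  fst[bad] <- NA_real_
  data.frame(numerator = num, denominator = den, fst = fst)
}

#' Branch length from Fst
#'
#' `T = -log(1 - fst)`, the divergence-time transform used to build the
#' Population Branch Statistic. The argument is clamped at `1 - 1e-12` so a
#' fixed difference gives a large but finite branch (about 27.63); negative
#' Fst passes through, giving a small negative branch. `NA` propagates.
#'
#' @param fst numeric vector of Fst values (`<= 1`).
#' @return numeric vector of branch lengths.
#' @export
branch_length <- function(fst) {
  -log(1 - pmin(fst, 1 - 1e-12))
}

check_aligned <- function(a, b, what = "frequency vectors") {
  ka <- variant_key(a$chrom, a$pos, a$ref, a$alt)
  kb <- variant_key(b$chrom, b$pos, b$ref, b$alt)
  if (length(ka) != length(kb) || any(ka != kb))
    stop_pbscan("%s are not aligned on identical variant lists", what,
                class = "pbscan_alignment_error")
  invisible(TRUE)
}

#' Population Branch Statistic per SNP
#'
#' For aligned target / reference / outgroup frequency vectors, computes the
#' three pairwise Hudson Fst values, transforms them to branch lengths
#' `T = -log(1 - fst)`, and returns the target branch
#' `PBS = (T_tr + T_to - T_ro) / 2` per SNP. The statistic is missing
#' wherever any pairwise Fst is missing; no imputation is performed.
#'
#' @param target,reference,outgroup [freq_vector()]s over identical variant
#'   lists (checked; misalignment is an error).
#' @return data.frame of class `pbs_result` with columns `chrom, pos, ref,
#'   alt, fst_tr, fst_to, fst_ro, t_tr, t_to, t_ro, pbs`; attributes
#'   `populations` and `n_missing`.
#' @export
pbs <- function(target, reference, outgroup) {
  check_aligned(target, reference)
  check_aligned(target, outgroup)
  fst_tr <- hudson_fst(target$p, target$n, reference$p, reference$n)$fst
  fst_to <- hudson_fst(target$p, target$n, outgroup$p, outgroup$n)$fst
  fst_ro <- hudson_fst(reference$p, reference$n, outgroup$p, outgroup$n)$fst
  t_tr <- branch_length(fst_tr)
  t_to <- branch_length(fst_to)
  t_ro <- branch_length(fst_ro)
  value <- (t_tr + t_to - t_ro) / 2
  out <- data.frame(chrom = target$chrom, pos = target$pos,
                    ref = target$ref, alt = target$alt,
                    fst_tr = fst_tr, fst_to = fst_to, fst_ro = fst_ro,
                    t_tr = t_tr, t_to = t_to, t_ro = t_ro, pbs = value,
                    stringsAsFactors = FALSE)
  structure(out, class = c("pbs_result", "data.frame"),
            populations = c(target = attr(target, "population"),
                            reference = attr(reference, "population"),
                            outgroup = attr(outgroup, "population")),
            n_missing = sum(is.na(value)))
}

#' Concordance between two PBS scans
#'
#' Ordinary least-squares R-squared between two per-SNP PBS vectors on the
#' SNPs where both are defined (matched by variant identity). Used to compare
#' scans run against alternative reference panels, e.g. a subpopulation
#' versus a superpopulation panel.
#'
#' @param pbs_a,pbs_b [pbs()] results.
#' @return list with `r_squared` and `n_shared`.
#' @export
pbs_concordance <- function(pbs_a, pbs_b) {
  ka <- variant_key(pbs_a$chrom, pbs_a$pos, pbs_a$ref, pbs_a$alt)
  kb <- variant_key(pbs_b$chrom, pbs_b$pos, pbs_b$ref, pbs_b$alt)
  m <- match(ka, kb)
  ok <- !is.na(m) & !is.na(pbs_a$pbs) & !is.na(pbs_b$pbs[m])
  if (sum(ok) < 3L)
    stop_pbscan("fewer than 3 shared defined SNPs (%d)", sum(ok),
                class = "pbscan_insufficient_data_error")
  x <- pbs_a$pbs[ok]
  y <- pbs_b$pbs[m[ok]]
  list(r_squared = stats::cor(x, y)^2, n_shared = sum(ok))
}

#' Match a genotype table against two frequency panels
#'
#' Restricts a genotype table to the SNPs present (by `chrom, pos, ref, alt`
#' identity, chromosome labels normalized) in both panels, and reorders both
#' panels to the table's variant order. SNPs without a match in either panel
#' are dropped and counted.
#'
#' @param table a [genotype_table()].
#' @param ref_panel,out_panel `frequency_panel` objects.
#' @return list with `table`, `ref_panel`, `out_panel` (aligned) and
#'   `n_unmatched` (SNPs dropped).
#' @export
match_panels <- function(table, ref_panel, out_panel) {
  kt <- variant_key(table$variants$chrom, table$variants$pos,
                    table$variants$ref, table$variants$alt)
  kr <- variant_key(ref_panel$chrom, ref_panel$pos, ref_panel$ref, ref_panel$alt)
  ko <- variant_key(out_panel$chrom, out_panel$pos, out_panel$ref, out_panel$alt)
  mr <- match(kt, kr)
  mo <- match(kt, ko)
  keep <- !is.na(mr) & !is.na(mo)
  tab <- genotype_table(table$variants[keep, , drop = FALSE], table$samples,
                        table$geno[keep, , drop = FALSE],
                        depth = if (is.null(table$depth)) NULL else
                          table$depth[keep, , drop = FALSE],
                        log = table$log)
  reindex <- function(panel, idx) {
    out <- panel[idx, , drop = FALSE]
    rownames(out) <- NULL
    structure(out, class = class(panel), population = attr(panel, "population"),
              skipped = attr(panel, "skipped"))
  }
  list(table = tab,
       ref_panel = reindex(ref_panel, mr[keep]),
       out_panel = reindex(out_panel, mo[keep]),
       n_unmatched = sum(!keep))
}
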