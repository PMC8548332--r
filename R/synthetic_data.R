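#' Simulation parameters for a synthetic case-control cohort
#'
#' Bundles and validates the parameters of the cohort generator. Population
#' structure follows the Balding-Nichols model: each SNP draws an ancestral
#' frequency `p ~ Uniform(0.05, 0.95)` and every branch (target cohort,
#' reference panel, outgroup panel) draws its own frequency from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` with a branch-specific drift coefficient
#' `F`. A minority of SNPs can carry injected signals: "selected" SNPs shift
#' the target frequency toward fixation, `p' = p + delta * (1 - p)`;
#' "case_assoc" SNPs shift the case sampling frequency by `assoc_shift`
#' (additively, capped at 1) while controls stay at the drifted frequency,
#' emulating a disease-ascertainment confound.
#'
#' Defaults mirror the study design the generator emulates: 80 diploid cases,
#' 10 diploid controls, a close reference panel (`f_target = f_ref = 0.01`,
#' the within-subcontinental scale) and a continental-scale outgroup
#' (`f_out = 0.1`), with panel allele numbers on the aggregated-exome scale.
#'
#' @param n_snps number of SNPs to simulate.
#' @param n_cases,n_controls diploid sample sizes (defaults 80 and 10).
#' @param f_target,f_ref,f_out per-branch drift coefficients in (0, 1).
#' @param n_selected number of SNPs with a target-branch selection shift.
#' @param selection_shift shift `delta` in (0, 1] toward fixation.
#' @param n_case_assoc number of SNPs with a case-control confound.
#' @param assoc_shift additive case-frequency shift in (0, 1], capped at 1.
#' @param panel_an_ref,panel_an_out allele numbers reported by the panels.
#' @param snps_per_gene SNPs per simulated gene (consecutive blocks).
#' @param n_genes number of genes; defaults to `floor(n_snps / snps_per_gene)`.
#' @param seed integer seed; all stage seeds derive from it.
#' @return validated list of class `sim_params`.
#' @export
sim_params <- function(n_snps = 10000L, n_cases = 80L, n_controls = 10L,
                       f_target = 0.01, f_ref = 0.01, f_out = 0.1,
                       n_selected = 0L, selection_shift = 0.5,
                       n_case_assoc = 0L, assoc_shift = 0.5,
                       panel_an_ref = 30000L, panel_an_out = 16000L,
                       snps_per_gene = 5L, n_genes = NULL, seed = 1L) {
  if (is.null(n_genes)) n_genes <- n_snps %/% snps_per_gene
  p <- list(n_snps = as.integer(n_snps), n_cases = as.integer(n_cases),
            n_controls = as.integer(n_controls),
            f_target = f_target, f_ref = f_ref, f_out = f_out,
            n_selected = as.integer(n_selected), selection_shift = selection_shift,
            n_case_assoc = as.integer(n_case_assoc), assoc_shift = assoc_shift,
            panel_an_ref = as.integer(panel_an_ref),
            panel_an_out = as.integer(panel_an_out),
            snps_per_gene = as.integer(snps_per_gene),
            n_genes = as.integer(n_genes), seed = as.integer(seed))
  with(p, {
    if (n_snps < 1L || n_cases < 1L || n_controls < 1L)
      stop_pbscan("n_snps, n_cases and n_controls must be positive",
                  class = "pbscan_config_error")
    drifts <- c(f_target, f_ref, f_out)
    if (any(drifts <= 0) || any(drifts >= 1))
      stop_pbscan("drift coefficients must lie in (0, 1)", class = "pbscan_config_error")
    if (selection_shift < 0 || selection_shift > 1 || assoc_shift < 0 || assoc_shift > 1)
      stop_pbscan("shifts must lie in [0, 1]", class = "pbscan_config_error")
    if (n_selected + n_case_assoc > n_snps)
      stop_pbscan("n_selected + n_case_assoc exceeds n_snps", class = "pbscan_config_error")
    if (n_genes * snps_per_gene > n_snps)
      stop_pbscan("n_genes * snps_per_gene exceeds n_snps", class = "pbscan_config_error")
  })
  structure(p, class = "sim_params")
}

# documented hierarchical seeding: each generation stage runs under its own
# seed derived deterministically from the global one, so a stage can be
# regenerated in isolation. Offsets are fixed constants; results stay < 2^31.
stage_seed <- function(seed, stage) {
  offsets <- c(frequencies = 101, labels = 211, genotypes = 307,
               depths = 401, alleles = 503, region = 601)
  # multiply in double precision to avoid 32-bit overflow, then fold
  as.integer((as.numeric(seed) * 2654435 + offsets[[stage]]) %% 2147483647)
}

balding_nichols <- function(p, f) {
  stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

#' Simulate a case-control cohort with frequency panels and gene annotation
#'
#' Generates, under the model described in [sim_params()], a diploid
#' genotype table for cases and controls (with Poisson(30) read depths), a
#' reference and an outgroup frequency panel related to the target by
#' population drift, a non-overlapping gene annotation assigning consecutive
#' blocks of `snps_per_gene` SNPs to genes, and a per-SNP truth label
#' (`"null"`, `"selected"` or `"case_assoc"`) for every injected signal.
#' Identical parameters (including the seed) reproduce identical output.
#'
#' @param params a [sim_params()] object.
#' @return object of class `synthetic_cohort`: list with elements
#'   `genotypes` ([genotype_table()]), `ref_panel`, `out_panel`
#'   (`frequency_panel`), `annotation` (`gene_annotation`), `truth`
#'   (data.frame `chrom, pos, ref, alt, label`) and `params`.
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_snps

  set.seed(stage_seed(params$seed, "frequencies"))
  p_anc <- stats::runif(n, 0.05, 0.95)
  p_target <- balding_nichols(p_anc, params$f_target)
  p_ref <- balding_nichols(p_anc, params$f_ref)
  p_out <- balding_nichols(p_anc, params$f_out)

  set.seed(stage_seed(params$seed, "labels"))
  label <- rep("null", n)
  # selected SNPs are placed as adjacent pairs inside gene blocks (emulating
  # a selected locus tagged by several SNPs, as linkage would produce in
  # real data); every SNP is generated exchangeably, so clustering the
  # labels does not change any per-SNP distribution
  sel <- integer()
  if (params$n_selected > 0) {
    run_len <- min(2L, params$snps_per_gene)
    n_blocks <- ceiling(params$n_selected / run_len)
    if (params$n_genes >= n_blocks) {
      genes_hit <- sample.int(params$n_genes, n_blocks)
      starts <- (genes_hit - 1L) * params$snps_per_gene + 1L
      sel <- as.vector(vapply(starts, function(s) s + seq_len(run_len) - 1L,
                              integer(run_len)))
      sel <- sel[seq_len(params$n_selected)]
    } else {
      sel <- sample.int(n, params$n_selected)
    }
  }
  asc <- integer()
  if (params$n_case_assoc > 0)
    asc <- sample(setdiff(seq_len(n), sel), params$n_case_assoc)
  label[sel] <- "selected"
  label[asc] <- "case_assoc"
  # selection: deterministic shift toward fixation on the target branch
  p_target[sel] <- p_target[sel] + params$selection_shift * (1 - p_target[sel])
  # ascertainment confound: cases sample from a shifted frequency, controls
  # from the unshifted drifted frequency
  p_case <- p_target
  p_case[asc] <- pmin(p_target[asc] + params$assoc_shift, 1)

  set.seed(stage_seed(params$seed, "genotypes"))
  g_case <- matrix(stats::rbinom(n * params$n_cases, 2L, p_case),
                   nrow = n, ncol = params$n_cases)
  g_ctrl <- matrix(stats::rbinom(n * params$n_controls, 2L, p_target),
                   nrow = n, ncol = params$n_controls)

  set.seed(stage_seed(params$seed, "depths"))
  n_samp <- params$n_cases + params$n_controls
  depth <- matrix(stats::rpois(n * n_samp, 30), nrow = n, ncol = n_samp)

  set.seed(stage_seed(params$seed, "alleles"))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")

  pos <- seq_len(n) * 100L
  variants <- data.frame(chrom = "1", pos = pos,
                         id = sprintf("snp%06d", seq_len(n)),
                         ref = ref, alt = unname(alt), stringsAsFactors = FALSE)
  samples <- data.frame(
    sample = c(sprintf("case%03d", seq_len(params$n_cases)),
               sprintf("ctrl%03d", seq_len(params$n_controls))),
    cohort = rep(c("case", "control"), c(params$n_cases, params$n_controls)),
    stringsAsFactors = FALSE)
  genotypes <- genotype_table(variants, samples, cbind(g_case, g_ctrl), depth)

  mk_panel <- function(freq, an, tag) {
    structure(data.frame(chrom = variants$chrom, pos = variants$pos,
                         ref = variants$ref, alt = variants$alt,
                         af = freq, an = as.numeric(an), stringsAsFactors = FALSE),
              class = c("frequency_panel", "data.frame"),
              population = tag, skipped = 0L)
  }
  ref_panel <- mk_panel(p_ref, params$panel_an_ref, "ref")
  out_panel <- mk_panel(p_out, params$panel_an_out, "out")

  gene_block <- params$snps_per_gene
  gi <- seq_len(params$n_genes)
  first <- (gi - 1L) * gene_block + 1L
  last <- gi * gene_block
  annotation <- structure(
    data.frame(chrom = "1",
               start = pos[first] - 50L - 1L,  # 0-based, half-open
               end = pos[last] + 50L,
               gene = sprintf("GENE%04d", gi), stringsAsFactors = FALSE),
    class = c("gene_annotation", "data.frame"))

  truth <- data.frame(chrom = variants$chrom, pos = variants$pos,
                      ref = variants$ref, alt = variants$alt,
                      label = label, stringsAsFactors = FALSE)
  structure(list(genotypes = genotypes, ref_panel = ref_panel,
                 out_panel = out_panel, annotation = annotation,
                 truth = truth, params = params),
            class = "synthetic_cohort")
}

#' @exportS3Method base::print
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d SNPs, %d cases + %d controls, %d genes\n",
              x$params$n_snps, x$params$n_cases, x$params$n_controls,
              x$params$n_genes))
  cat(sprintf("  truth: %d selected, %d case_assoc, %d null (seed %d)\n",
              sum(x$truth$label == "selected"), sum(x$truth$label == "case_assoc"),
              sum(x$truth$label == "null"), x$params$seed))
  invisible(x)
}

#' Simulate a phased region with an archaic-introgressed haplotype block
#'
#' Builds a haplotype matrix over `length` sites in which the archaic
#' reference haplotype carries the derived allele at
#' `ceiling(archaic_private_fraction * length)` "archaic-private" sites where
#' non-introgressed modern haplotypes carry the ancestral allele; at all
#' remaining sites moderns and the archaic share the ancestral allele.
#' A random subset of `n_introgressed` modern haplotypes copies the archaic
#' vector wholesale and then flips each site independently with probability
#' `mutation_noise`, so the Hamming distance of an introgressed copy to the
#' archaic is Binomial(`length`, `mutation_noise`).
#'
#' @param n_modern number of modern haplotypes.
#' @param n_introgressed how many of them carry the archaic copy
#'   (`<= n_modern`).
#' @param length number of sites (`>= 2`).
#' @param archaic_private_fraction fraction of sites private to the archaic,
#'   in (0, 1].
#' @param mutation_noise per-site flip probability on introgressed copies.
#' @param seed integer seed.
#' @return object of class `haplotype_region`: list with `positions`
#'   (strictly increasing 1-based coordinates), `haplotypes`
#'   (`n_modern` x `length` 0/1 matrix), `hap_labels`, `archaic` (0/1 vector)
#'   and `truth_introgressed` (row indices).
#' @export
simulate_introgression_region <- function(n_modern, n_introgressed, length,
                                          archaic_private_fraction,
                                          mutation_noise = 0, seed = 1L) {
  if (length < 2L)
    stop_pbscan("region length must be >= 2", class = "pbscan_config_error")
  if (n_introgressed > n_modern)
    stop_pbscan("n_introgressed must be <= n_modern", class = "pbscan_config_error")
  if (archaic_private_fraction <= 0 || archaic_private_fraction > 1)
    stop_pbscan("archaic_private_fraction must lie in (0, 1]",
                class = "pbscan_config_error")
  set.seed(stage_seed(seed, "region"))
  positions <- sort(sample.int(length * 100L, length))
  n_private <- ceiling(archaic_private_fraction * length)
  private <- sort(sample.int(length, n_private))
  archaic <- integer(length)
  archaic[private] <- 1L
  hap <- matrix(0L, nrow = n_modern, ncol = length)
  truth <- sort(sample.int(n_modern, n_introgressed))
  if (n_introgressed > 0) {
    for (i in truth) {
      row <- archaic
      flip <- stats::runif(length) < mutation_noise
      row[flip] <- 1L - row[flip]
      hap[i, ] <- row
    }
  }
  rownames(hap) <- sprintf("hap%03d", seq_len(n_modern))
  structure(list(positions = positions, haplotypes = hap,
                 hap_labels = rep("modern", n_modern),
                 archaic = archaic, truth_introgressed = truth),
            class = "haplotype_region")
}

#' Export a synthetic cohort to standard file formats
#'
#' Writes the genotype VCF (GT:DP), the two panel TSVs, the gene BED and a
#' truth TSV (`chrom, pos, ref, alt, label`) into `out_dir`. All files are
#' plain text and byte-deterministic; re-reading them with [read_vcf()],
#' [read_frequency_panel()] and [read_gene_bed()] reproduces the cohort.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param out_dir output directory (created if needed).
#' @return named character vector of file paths (`vcf`, `ref_panel`,
#'   `out_panel`, `bed`, `truth`), invisibly.
#' @export
export_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(out_dir, "genotypes.vcf"),
             ref_panel = file.path(out_dir, "ref_panel.tsv"),
             out_panel = file.path(out_dir, "out_panel.tsv"),
             bed = file.path(out_dir, "genes.bed"),
             truth = file.path(out_dir, "truth.tsv"))

  gt <- cohort$genotypes
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gt$geno + 1L], nrow = nrow(gt$geno))
  gt_str[is.na(gt$geno)] <- "./."
  cells <- paste(gt_str, gt$depth, sep = ":")
  body <- matrix(cells, nrow = nrow(gt$geno))
  header <- c("##fileformat=VCFv4.2",
              "##source=pbscan_simulate_cohort",
              "##contig=<ID=1>",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", gt$samples$sample), collapse = "\t"))
  v <- gt$variants
  rows <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", ".", ".", "GT:DP",
                apply(body, 1L, paste, collapse = "\t"), sep = "\t")
  write_lines_binary(c(header, rows), paths[["vcf"]])

  write_panel_tsv <- function(panel, path) {
    rows <- sprintf("%s\t%d\t%s\t%s\t%.10g\t%g", panel$chrom, panel$pos,
                    panel$ref, panel$alt, panel$af, panel$an)
    write_lines_binary(c("chrom\tpos\tref\talt\taf\tan", rows), path)
  }
  write_panel_tsv(cohort$ref_panel, paths[["ref_panel"]])
  write_panel_tsv(cohort$out_panel, paths[["out_panel"]])

  a <- cohort$annotation
  write_lines_binary(sprintf("%s\t%d\t%d\t%s", a$chrom, a$start, a$end, a$gene),
                     paths[["bed"]])
  tr <- cohort$truth
  write_lines_binary(c("chrom\tpos\tref\talt\tlabel",
                       sprintf("%s\t%d\t%s\t%s\t%s", tr$chrom, tr$pos, tr$ref,
                               tr$alt, tr$label)),
                     paths[["truth"]])
  invisible(paths)
}

write_lines_binary <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
}

#' Cohort labels for an exported synthetic cohort
#'
#' Convenience accessor returning the named `sample -> cohort` vector
#' expected by [read_vcf()].
#'
#' @param cohort a `synthetic_cohort`.
#' @return named character vector.
#' @export
cohort_labels <- function(cohort) {
  stats::setNames(cohort$genotypes$samples$cohort, cohort$genotypes$samples$sample)
}
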