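#' Construct a genotype table
#'
#' Container for a cohort's biallelic SNP genotypes: an ordered variant table,
#' sample names with case/control labels, a variant x sample allele-dosage
#' matrix (0/1/2 alternate-allele copies, `NA` = missing) and, optionally, a
#' matching read-depth matrix. Missingness is encoded as `NA`, never as
#' dosage 0.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `id`, `ref`, `alt`.
#' @param samples data.frame with columns `sample` and `cohort`
#'   (`"case"` or `"control"`).
#' @param geno integer matrix, `nrow(variants)` x `nrow(samples)`.
#' @param depth optional integer matrix of per-genotype read depths, same
#'   dimensions as `geno`.
#' @param log named list of skip/drop counters carried along from parsing.
#' @return an object of class `genotype_table`.
#' @export
genotype_table <- function(variants, samples, geno, depth = NULL, log = list()) {
  stopifnot(is.data.frame(variants), is.data.frame(samples))
  geno <- as.matrix(geno)
  if (!all(dim(geno) == c(nrow(variants), nrow(samples))))
    stop_pbscan("genotype matrix is %d x %d but %d variants and %d samples given",
                nrow(geno), ncol(geno), nrow(variants), nrow(samples),
                class = "pbscan_format_error")
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% 0:2))
    stop_pbscan("non-missing dosages must be 0, 1 or 2", class = "pbscan_format_error")
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    stopifnot(all(dim(depth) == dim(geno)))
  }
  if (nrow(variants)) {
    if (any(variants$pos < 1))
      stop_pbscan("positions must be >= 1", class = "pbscan_format_error")
    if (any(variants$ref == variants$alt) ||
        any(nchar(variants$ref) != 1L) || any(nchar(variants$alt) != 1L))
      stop_pbscan("only biallelic SNPs with distinct single-base alleles are allowed",
                  class = "pbscan_format_error")
  }
  if (!all(samples$cohort %in% c("case", "control")))
    stop_pbscan("sample cohort labels must be 'case' or 'control'",
                class = "pbscan_config_error")
  structure(list(variants = variants, samples = samples, geno = geno,
                 depth = depth, log = log),
            class = "genotype_table")
}

#' @exportS3Method base::print
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d SNPs x %d samples (%d cases, %d controls)\n",
              nrow(x$variants), nrow(x$samples),
              sum(x$samples$cohort == "case"), sum(x$samples$cohort == "control")))
  cat(sprintf("  missing genotypes: %.1f%%; depths: %s\n",
              100 * mean(is.na(x$geno)),
              if (is.null(x$depth)) "absent" else "present"))
  if (length(x$log))
    cat("  parse log:", paste(names(x$log), unlist(x$log), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# GT string ("0/1", "1|0", "./.", ...) -> dosage; any "." allele => NA
gt_to_dosage <- function(gt) {
  gt <- sub(":.*$", "", gt)
  out <- rep(NA_integer_, length(gt))
  known <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
             "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  hit <- match(gt, names(known))
  out[!is.na(hit)] <- known[hit[!is.na(hit)]]
  out
}

#' Read cohort genotypes from a VCF file
#'
#' Parses a VCF v4.x file with `GT` (and optionally `DP`) FORMAT fields into a
#' [genotype_table()]. Only biallelic SNP records are kept; indel and
#' multiallelic records are skipped and counted in the returned table's
#' `log`. Every sample in the file must be assigned to a cohort.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @param cohort_labels named character vector mapping sample name to
#'   `"case"` or `"control"`; must cover all samples in the file.
#' @return a [genotype_table()] whose `log` holds `skipped_indel` and
#'   `skipped_multiallelic` counts.
#' @export
read_vcf <- function(path, cohort_labels) {
  if (!file.exists(path))
    stop_pbscan("VCF file not found: %s", path, class = "pbscan_io_error")
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop_pbscan("malformed VCF %s: %s", path,
                                                  conditionMessage(e),
                                                  class = "pbscan_format_error"))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  file_samples <- colnames(vcf@gt)[-1]
  missing_lab <- setdiff(file_samples, names(cohort_labels))
  if (length(missing_lab))
    stop_pbscan("samples without cohort label: %s",
                paste(missing_lab, collapse = ", "), class = "pbscan_config_error")
  absent <- setdiff(names(cohort_labels), file_samples)
  if (length(absent))
    stop_pbscan("labeled samples absent from VCF: %s",
                paste(absent, collapse = ", "), class = "pbscan_config_error")

  samples <- data.frame(sample = file_samples,
                        cohort = unname(cohort_labels[file_samples]),
                        stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(genotype_table(
      data.frame(chrom = character(), pos = integer(), id = character(),
                 ref = character(), alt = character(), stringsAsFactors = FALSE),
      samples, matrix(NA_integer_, 0L, nrow(samples)),
      depth = NULL, log = list(skipped_indel = 0L, skipped_multiallelic = 0L)))
  }

  alt <- fix$ALT
  multi <- grepl(",", alt, fixed = TRUE)
  snp <- !multi & nchar(fix$REF) == 1L & nchar(alt) == 1L &
    fix$REF != alt & fix$REF %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  keep <- which(snp)
  log <- list(skipped_indel = sum(!snp & !multi),
              skipped_multiallelic = sum(multi))

  gt <- vcfR::extract.gt(vcf, element = "GT")
  geno <- apply(gt, 2L, gt_to_dosage)
  geno <- matrix(geno, nrow = nrow(gt),
                 dimnames = list(NULL, colnames(gt)))
  fmt <- vcf@gt[, "FORMAT"]
  depth <- NULL
  if (any(grepl("(^|:)DP(:|$)", fmt))) {
    dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
    depth <- matrix(as.integer(dp), nrow = nrow(dp))
  }

  variants <- data.frame(chrom = fix$CHROM[keep],
                         pos = as.integer(fix$POS[keep]),
                         id = ifelse(is.na(fix$ID[keep]) | fix$ID[keep] == ".",
                                     NA_character_, fix$ID[keep]),
                         ref = fix$REF[keep], alt = alt[keep],
                         stringsAsFactors = FALSE)
  genotype_table(variants, samples,
                 geno[keep, , drop = FALSE],
                 depth = if (is.null(depth)) NULL else depth[keep, , drop = FALSE],
                 log = log)
}

#' Read a population allele-frequency panel
#'
#' Loads per-SNP alternate-allele frequency (`AF`) and allele number (`AN`)
#' for one population, either from a gnomAD-style VCF whose INFO column
#' carries `AF_<tag>` / `AN_<tag>` keys, or from a TSV with columns
#' `chrom, pos, ref, alt, af, an` (header optional). Records missing either
#' key are skipped and counted.
#'
#' @param path panel file (VCF or TSV; VCF detected by its `##fileformat` line).
#' @param population_tag population suffix used in the VCF INFO keys, e.g.
#'   `"sas"` for `AF_sas` / `AN_sas`. Ignored for TSV input.
#' @return data.frame of class `frequency_panel` with columns
#'   `chrom, pos, ref, alt, af, an`; attribute `skipped` counts records
#'   lacking the requested keys, attribute `population` records the tag.
#' @export
read_frequency_panel <- function(path, population_tag = "panel") {
  if (!file.exists(path))
    stop_pbscan("panel file not found: %s", path, class = "pbscan_io_error")
  first <- readLines(path, n = 1L)
  if (length(first) && startsWith(first, "##fileformat=VCF")) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    if (nrow(fix) == 0L)
      return(empty_panel(population_tag))
    snp <- !grepl(",", fix$ALT, fixed = TRUE) & nchar(fix$REF) == 1L &
      nchar(fix$ALT) == 1L & fix$REF != fix$ALT
    af <- suppressWarnings(as.numeric(
      vcfR::extract.info(vcf, element = paste0("AF_", population_tag))))
    an <- suppressWarnings(as.numeric(
      vcfR::extract.info(vcf, element = paste0("AN_", population_tag))))
    if (all(is.na(af)) && all(is.na(an)))
      stop_pbscan("no record carries AF_%s/AN_%s INFO keys", population_tag,
                  population_tag, class = "pbscan_config_error")
    ok <- snp & !is.na(af) & !is.na(an)
    out <- data.frame(chrom = fix$CHROM[ok], pos = as.integer(fix$POS[ok]),
                      ref = fix$REF[ok], alt = fix$ALT[ok],
                      af = af[ok], an = an[ok], stringsAsFactors = FALSE)
    skipped <- sum(snp & !ok)
  } else {
    tab <- utils::read.table(path, header = grepl("chrom", first, fixed = TRUE),
                             sep = "", stringsAsFactors = FALSE)
    if (ncol(tab) < 6L)
      stop_pbscan("panel TSV needs columns chrom,pos,ref,alt,af,an",
                  class = "pbscan_format_error")
    names(tab)[1:6] <- c("chrom", "pos", "ref", "alt", "af", "an")
    ok <- !is.na(tab$af) & !is.na(tab$an)
    out <- data.frame(chrom = as.character(tab$chrom[ok]),
                      pos = as.integer(tab$pos[ok]),
                      ref = tab$ref[ok], alt = tab$alt[ok],
                      af = as.numeric(tab$af[ok]), an = as.numeric(tab$an[ok]),
                      stringsAsFactors = FALSE)
    skipped <- sum(!ok)
  }
  if (nrow(out) && (any(out$af < 0 | out$af > 1) || any(out$an < 0)))
    stop_pbscan("panel frequencies must lie in [0,1] and AN must be >= 0",
                class = "pbscan_format_error")
  structure(out, class = c("frequency_panel", "data.frame"),
            population = population_tag, skipped = skipped)
}

empty_panel <- function(tag) {
  structure(data.frame(chrom = character(), pos = integer(), ref = character(),
                       alt = character(), af = numeric(), an = numeric(),
                       stringsAsFactors = FALSE),
            class = c("frequency_panel", "data.frame"),
            population = tag, skipped = 0L)
}

#' Apply per-genotype depth and per-variant missingness filters
#'
#' Masks genotypes whose read depth is below `min_depth` (setting them to
#' missing), then drops variants whose missing-genotype fraction exceeds
#' `max_missing_fraction`. This mirrors the standard exome QC pair
#' `--minDP 10` / `--max-missing 0.5`.
#'
#' @param table a [genotype_table()]; must carry depths when `min_depth > 0`.
#' @param min_depth minimum per-genotype read depth (default 10); genotypes
#'   with absent depth fail the filter.
#' @param max_missing_fraction maximum tolerated fraction of missing genotypes
#'   per variant (default 0.5), strictly-greater fractions are dropped.
#' @return a new `genotype_table`; its `log` gains `genotypes_masked` and
#'   `variants_dropped_missing` counts. The input is not modified.
#' @export
filter_genotypes <- function(table, min_depth = 10, max_missing_fraction = 0.5) {
  stopifnot(inherits(table, "genotype_table"))
  geno <- table$geno
  masked <- 0L
  if (min_depth > 0) {
    if (is.null(table$depth))
      stop_pbscan("min_depth > 0 requires depth information in the table",
                  class = "pbscan_config_error")
    low <- (is.na(table$depth) | table$depth < min_depth) & !is.na(geno)
    masked <- sum(low)
    geno[low] <- NA_integer_
  }
  miss_frac <- rowMeans(is.na(geno))
  keep <- miss_frac <= max_missing_fraction
  log <- table$log
  log$genotypes_masked <- masked
  log$variants_dropped_missing <- sum(!keep)
  genotype_table(table$variants[keep, , drop = FALSE], table$samples,
                 geno[keep, , drop = FALSE],
                 depth = if (is.null(table$depth)) NULL else
                   table$depth[keep, , drop = FALSE],
                 log = log)
}

#' Read gene intervals from a BED4 file
#'
#' @param path BED file with at least 4 columns
#'   (`chrom`, `start`, `end`, `gene`), 0-based half-open coordinates.
#' @return data.frame of class `gene_annotation` with those columns.
#'   Overlapping intervals are allowed and retained.
#' @export
read_gene_bed <- function(path) {
  if (!file.exists(path))
    stop_pbscan("BED file not found: %s", path, class = "pbscan_io_error")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- structure(data.frame(chrom = character(), start = integer(),
                                end = integer(), gene = character(),
                                stringsAsFactors = FALSE),
                     class = c("gene_annotation", "data.frame"))
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "[ \t]+")
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 4L)
      stop_pbscan("BED line %d has %d fields; need chrom,start,end,gene",
                  i, length(f), class = "pbscan_format_error")
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e) || s >= e)
      stop_pbscan("BED line %d: start (%s) must be < end (%s)", i, f[2], f[3],
                  class = "pbscan_format_error")
    if (!nzchar(f[4]))
      stop_pbscan("BED line %d: empty gene name", i, class = "pbscan_format_error")
  }
  out <- data.frame(chrom = vapply(fields, `[`, "", 1L),
                    start = as.integer(vapply(fields, `[`, "", 2L)),
                    end = as.integer(vapply(fields, `[`, "", 3L)),
                    gene = vapply(fields, `[`, "", 4L),
                    stringsAsFactors = FALSE)
  structure(out, class = c("gene_annotation", "data.frame"))
}

#' Read a gene-set collection from a GMT file
#'
#' One set per tab-separated line: set name, source/description, then member
#' gene names. Duplicate members within a line are removed and counted.
#'
#' @param path GMT file.
#' @return object of class `gene_set_collection`: a list with `sets` (named
#'   list of unique member vectors), `source` (named character vector) and
#'   `n_duplicates` (total duplicates removed).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path))
    stop_pbscan("GMT file not found: %s", path, class = "pbscan_io_error")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); src <- character(); ndup <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop_pbscan("GMT line %d has %d fields; need name, source and >= 1 member",
                  i, length(f), class = "pbscan_format_error")
    members <- f[-(1:2)]
    uniq <- unique(members)
    ndup <- ndup + (length(members) - length(uniq))
    sets[[f[1]]] <- uniq
    src[f[1]] <- f[2]
  }
  structure(list(sets = sets, source = src, n_duplicates = ndup),
            class = "gene_set_collection")
}

#' @exportS3Method base::print
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, %d duplicate members removed\n",
              length(x$sets), x$n_duplicates))
  invisible(x)
}

report_spec <- function(kind) {
  switch(kind,
    snp_scan = list(
      columns = c("chrom", "pos", "ref", "alt", "pbs", "case_freq",
                  "control_freq", "abs_diff", "fisher_p", "odds_ratio",
                  "status", "genes"),
      pcols = c("fisher_p"),
      sort = function(d) order(d$chrom, d$pos)),
    gene_summary = list(
      columns = c("gene", "n_snps", "classification", "mean_pbs"),
      pcols = character(),
      sort = function(d) order(-d$mean_pbs, d$gene)),
    enrichment = list(
      columns = c("set_name", "source", "n_overlap", "overlapping_genes",
                  "n_set", "n_query", "n_background", "p_value", "q_value"),
      pcols = c("p_value", "q_value"),
      sort = function(d) order(d$p_value, d$set_name)),
    ordering = list(
      columns = c("rank", "haplotype", "population", "distance"),
      pcols = character(),
      sort = function(d) order(d$rank)),
    stop_pbscan("unknown report kind '%s'", kind, class = "pbscan_config_error"))
}

#' Write a tab-separated result report
#'
#' Serializes scan/summary/enrichment/ordering tables with a fixed header per
#' kind, 6-significant-digit floats, p-values in 3-significant-digit
#' scientific notation, and a documented deterministic row order
#' (`snp_scan`: chrom then pos; `gene_summary`: descending `mean_pbs` then
#' gene; `enrichment`: ascending `p_value` then set name; `ordering`: rank).
#' Writing the same records twice yields byte-identical files.
#'
#' @param records data.frame carrying at least the columns of the chosen kind.
#' @param path output file path.
#' @param kind one of `"snp_scan"`, `"gene_summary"`, `"enrichment"`,
#'   `"ordering"`.
#' @return the output path, invisibly.
#' @export
write_report <- function(records, path,
                         kind = c("snp_scan", "gene_summary", "enrichment", "ordering")) {
  kind <- match.arg(kind)
  if (is.null(records))
    stop_pbscan("records must not be NULL", class = "pbscan_config_error")
  spec <- report_spec(kind)
  d <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(spec$columns, names(d))
  if (length(missing_cols))
    stop_pbscan("report kind '%s' needs columns: %s", kind,
                paste(missing_cols, collapse = ", "), class = "pbscan_format_error")
  d <- d[, spec$columns, drop = FALSE]
  if (nrow(d)) d <- d[spec$sort(d), , drop = FALSE]
  fmt_cell <- function(x, scientific) {
    if (is.numeric(x) && !is.integer(x)) {
      out <- if (scientific) sprintf("%.2e", x) else sprintf("%.6g", x)
      out[is.na(x)] <- "NA"
      out
    } else {
      out <- as.character(x)
      out[is.na(out)] <- "NA"
      out
    }
  }
  cells <- lapply(spec$columns, function(cn)
    fmt_cell(d[[cn]], scientific = cn %in% spec$pcols))
  body <- if (nrow(d)) do.call(paste, c(cells, sep = "\t")) else character()
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(spec$columns, collapse = "\t"), body), con, sep = "\n")
  invisible(path)
}
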