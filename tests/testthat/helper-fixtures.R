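# Text fixtures assembled in code; all paths are per-test tempfiles.

write_cohort_vcf_fixture <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "1\t100\trs1\tA\tG\t.\t.\t.\tGT:DP\t0/1:25\t0/0:9",
    "1\t200\t.\tC\tT\t.\t.\t.\tGT:DP\t1/1:30\t./.:12",
    "1\t300\t.\tG\tGA\t.\t.\t.\tGT:DP\t0/1:30\t0/1:30",
    "1\t400\t.\tA\tG,T\t.\t.\t.\tGT:DP\t0/1:30\t0/1:30",
    "1\t500\t.\tT\tA\t.\t.\t.\tGT:DP\t0|1:18\t1|1:22"
  ), path)
  path
}

write_header_only_vcf <- function(path, samples = c("S1", "S2")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  ), path)
  path
}

write_panel_vcf_fixture <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "##INFO=<ID=AF_afr,Number=A,Type=Float,Description=\"AF\">",
    "##INFO=<ID=AN_afr,Number=1,Type=Integer,Description=\"AN\">",
    "##INFO=<ID=AF_sas,Number=A,Type=Float,Description=\"AF\">",
    "##INFO=<ID=AN_sas,Number=1,Type=Integer,Description=\"AN\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "1\t100\t.\tA\tG\t.\t.\tAF_afr=0.25;AN_afr=1000;AF_sas=0.5;AN_sas=2000",
    "1\t200\t.\tC\tT\t.\t.\tAF_afr=0.1;AN_afr=900",
    "1\t300\t.\tG\tA\t.\t.\tAF_sas=0.3;AN_sas=1500"
  ), path)
  path
}

# small hand-built genotype table: n_var x n_samp dosage matrix
toy_table <- function(geno, depth = NULL,
                      cohort = rep("case", ncol(geno))) {
  nv <- nrow(geno)
  variants <- data.frame(chrom = "1", pos = seq_len(nv) * 10L,
                         id = NA_character_,
                         ref = rep("A", nv), alt = rep("G", nv),
                         stringsAsFactors = FALSE)
  samples <- data.frame(sample = sprintf("S%d", seq_len(ncol(geno))),
                        cohort = cohort, stringsAsFactors = FALSE)
  genotype_table(variants, samples, geno, depth)
}

# frequency vector straight from numbers, sharing one variant frame
toy_freqs <- function(p, n, population = "pop") {
  nv <- length(p)
  variants <- data.frame(chrom = "1", pos = seq_len(nv) * 10L,
                         ref = rep("A", nv), alt = rep("G", nv),
                         stringsAsFactors = FALSE)
  freq_vector(variants, p, n, population)
}
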