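test_that("simulate_cohort is deterministic under a fixed seed", {
  p <- sim_params(n_snps = 500, n_selected = 5, n_case_assoc = 5, seed = 1)
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_identical(a$genotypes$geno, b$genotypes$geno)
  expect_identical(a$ref_panel$af, b$ref_panel$af)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_cohort(sim_params(n_snps = 500, n_selected = 5,
                                   n_case_assoc = 5, seed = 2))
  expect_false(identical(a$genotypes$geno, c_$genotypes$geno))
})

test_that("simulate_cohort validates its parameters", {
  expect_error(sim_params(n_snps = 10, n_genes = 3, snps_per_gene = 5),
               class = "pbscan_config_error")
  expect_error(sim_params(n_snps = 10, n_selected = 8, n_case_assoc = 8),
               class = "pbscan_config_error")
  expect_error(sim_params(f_target = 0), class = "pbscan_config_error")
})

test_that("injected shifts stay within frequency bounds and mark truth labels", {
  p <- sim_params(n_snps = 2000, n_selected = 40, n_case_assoc = 40,
                  selection_shift = 0.9, assoc_shift = 0.9, seed = 5)
  co <- simulate_cohort(p)
  expect_equal(as.vector(table(co$truth$label)[c("case_assoc", "selected")]),
               c(40L, 40L))
  expect_true(all(co$ref_panel$af >= 0 & co$ref_panel$af <= 1))
  expect_true(all(co$out_panel$af >= 0 & co$out_panel$af <= 1))
  case_f <- allele_frequencies(co$genotypes, "case")
  expect_true(all(case_f$p >= 0 & case_f$p <= 1, na.rm = TRUE))
  # selected SNPs are shifted toward fixation: their case frequencies sit
  # well above the exchangeable-null median
  sel <- co$truth$label == "selected"
  expect_gt(median(case_f$p[sel]), median(case_f$p[!sel]))
})

test_that("mean Hudson Fst between two F=0.01 branches is near (F1+F2)/2", {
  # Monte-Carlo calibration of the Balding-Nichols generator: the Hudson
  # estimator normalizes by between-population heterozygosity, so two
  # independent drifts F1 and F2 from a shared ancestor give E[Fst] close to
  # (F1 + F2) / 2
  for (s in 1:2) {
    co <- simulate_cohort(sim_params(n_snps = 20000, f_target = 0.01,
                                     f_ref = 0.01, f_out = 0.01, seed = s))
    case_f <- allele_frequencies(co$genotypes, "case")
    ref_f <- panel_frequencies(co$ref_panel)
    fst <- hudson_fst(case_f$p, case_f$n, ref_f$p, ref_f$n)$fst
    expect_gt(mean(fst, na.rm = TRUE), 0.005)
    expect_lt(mean(fst, na.rm = TRUE), 0.015)
  }
})

test_that("null cohorts give exchangeable PBS ranks across seeds", {
  # with no injected signal, the PBS rank of a designated SNP should be
  # uniform over replicates
  n_rep <- 200
  u <- vapply(seq_len(n_rep), function(s) {
    co <- simulate_cohort(sim_params(n_snps = 400, seed = 1000 + s))
    run_pbs <- pbs(allele_frequencies(co$genotypes, "case"),
                   panel_frequencies(co$ref_panel),
                   panel_frequencies(co$out_panel))
    v <- run_pbs$pbs
    ok <- !is.na(v)
    (rank(v[ok])[1] - 0.5) / sum(ok)  # rank of the first defined SNP
  }, 0)
  ks <- suppressWarnings(ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("introgression regions copy the archaic with controlled noise", {
  # noise-free copies are identical to the archaic
  r0 <- simulate_introgression_region(20, 5, 100, 0.2, mutation_noise = 0,
                                      seed = 1)
  enc <- encode_against_archaic(r0)
  d <- archaic_distance(enc)
  expect_equal(d[r0$truth_introgressed], rep(0L, 5))
  # non-introgressed moderns differ from the archaic at every private site
  n_private <- ceiling(0.2 * 100)
  expect_equal(d[setdiff(1:20, r0$truth_introgressed)],
               rep(n_private, 15))

  # no introgression: truth empty, minimum distance equals the private count
  r_none <- simulate_introgression_region(10, 0, 50, 0.3, seed = 2)
  expect_length(r_none$truth_introgressed, 0)
  enc_none <- encode_against_archaic(r_none)
  expect_equal(min(archaic_distance(enc_none)), ceiling(0.3 * 50))

  # with noise, introgressed-to-archaic distance behaves as Binomial(L, noise)
  r_noise <- simulate_introgression_region(40, 10, 100, 0.2,
                                           mutation_noise = 0.05, seed = 3)
  raw_d <- rowSums(r_noise$haplotypes[r_noise$truth_introgressed, ] !=
                     matrix(r_noise$archaic, 10, 100, byrow = TRUE))
  expect_true(all(raw_d >= 0 & raw_d <= 13))  # mean 5, sd ~2.2
  expect_gt(mean(raw_d), 1)

  expect_error(simulate_introgression_region(10, 2, 1, 0.5),
               class = "pbscan_config_error")
  expect_error(simulate_introgression_region(5, 6, 100, 0.5),
               class = "pbscan_config_error")
})

test_that("export_cohort round-trips through the readers and is byte-stable", {
  co <- simulate_cohort(sim_params(n_snps = 300, n_selected = 3, seed = 9))
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  p1 <- export_cohort(co, d1)
  p2 <- export_cohort(co, d2)
  for (k in names(p1)) {
    expect_identical(readBin(p1[[k]], "raw", file.size(p1[[k]])),
                     readBin(p2[[k]], "raw", file.size(p2[[k]])),
                     label = sprintf("bytes of %s", k))
  }
  tab <- read_vcf(p1[["vcf"]], cohort_labels(co))
  expect_equal(unname(tab$geno), unname(co$genotypes$geno))
  expect_equal(unname(tab$depth), unname(co$genotypes$depth))
  pan <- read_frequency_panel(p1[["ref_panel"]])
  expect_lt(max(abs(pan$af - co$ref_panel$af)), 1e-9)
  truth <- read.table(p1[["truth"]], header = TRUE, sep = "\t")
  expect_equal(nrow(truth), 300L)
  ann <- read_gene_bed(p1[["bed"]])
  expect_equal(nrow(ann), co$params$n_genes)
})
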