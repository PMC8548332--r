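test_that("percentile_threshold interpolates order statistics", {
  expect_equal(percentile_threshold(1:1000, 0.999), 999.001)
  expect_equal(percentile_threshold(rep(3.7, 50), 0.9), 3.7)
  expect_equal(percentile_threshold(c(0, 1), 0.5), 0.5)
  expect_equal(percentile_threshold(c(NA, 1:10, NA), 0.5), 5.5)
  expect_error(percentile_threshold(c(NA_real_, NA_real_), 0.5),
               class = "pbscan_insufficient_data_error")
  expect_error(percentile_threshold(1:10, 1), class = "pbscan_config_error")
})

test_that("top_outliers uses a strict threshold over defined values", {
  fake <- data.frame(pbs = as.numeric(1:1000))
  expect_equal(top_outliers(fake, 0.999), 1000L)
  expect_equal(sort(top_outliers(fake[1:10, , drop = FALSE], 0.5)), 6:10)
  expect_length(top_outliers(data.frame(pbs = rep(1, 100)), 0.999), 0)
  # missing values neither enter the threshold nor the outlier set
  fake$pbs[1000] <- NA
  expect_equal(top_outliers(fake, 0.999), 999L)
})

test_that("case_control_diff propagates missingness over aligned vectors", {
  case <- toy_freqs(c(0.4, 0.9, 0.5), c(160, 160, 160))
  ctrl <- toy_freqs(c(0.4, 0.2, NA), c(20, 20, 0))
  expect_equal(case_control_diff(case, ctrl), c(0, 0.7, NA))
  expect_error(case_control_diff(case, ctrl[c(2, 1, 3), ]),
               class = "pbscan_alignment_error")
})

test_that("prune_by_case_control thresholds on the full diff distribution", {
  # 1000 scanned SNPs; the single PBS outlier carries the unique maximum diff
  diffs <- rep(0.02, 1000)
  diffs[17] <- 0.9
  res <- prune_by_case_control(17L, diffs, 0.999)
  expect_equal(res$excluded, 17L)
  expect_length(res$retained, 0)
  expect_lt(res$diff_threshold, 0.9)
  # nothing strictly exceeds a degenerate distribution's threshold
  flat <- prune_by_case_control(c(3L, 9L), rep(0.1, 100), 0.999)
  expect_equal(flat$retained, c(3L, 9L))
  expect_length(flat$excluded, 0)
  # conservation: retained and excluded partition the outliers
  set.seed(1)
  d <- runif(5000); out <- sample.int(5000, 50)
  pr <- prune_by_case_control(out, d, 0.999)
  expect_setequal(c(pr$retained, pr$excluded), out)
  expect_length(intersect(pr$retained, pr$excluded), 0)
})

test_that("threshold monotonicity holds for both percentile rules", {
  set.seed(2)
  v <- data.frame(pbs = rnorm(2000))
  qs <- c(0.9, 0.99, 0.999)
  outs <- lapply(qs, function(q) top_outliers(v, q))
  expect_true(all(outs[[2]] %in% outs[[1]]))
  expect_true(all(outs[[3]] %in% outs[[2]]))
  d <- runif(2000)
  ex <- lapply(qs, function(q) prune_by_case_control(outs[[1]], d, q)$excluded)
  expect_true(all(ex[[2]] %in% ex[[1]]))
  expect_true(all(ex[[3]] %in% ex[[2]]))
})

test_that("fisher_or reports the sample odds ratio with zero-cell conventions", {
  got <- fisher_or(2, 8, 6, 4)
  expect_equal(got$odds_ratio, (2 * 4) / (8 * 6))
  expect_equal(got$p_value, enum_fisher_p(2, 8, 6, 4), tolerance = 1e-12)
  flat <- fisher_or(5, 5, 10, 10)
  expect_equal(flat$odds_ratio, 1)
  expect_equal(flat$p_value, 1)
  expect_equal(fisher_or(3, 7, 0, 10)$odds_ratio, Inf)
  expect_equal(fisher_or(0, 10, 3, 7)$odds_ratio, 0)
  expect_true(is.nan(fisher_or(0, 10, 0, 10)$odds_ratio))
  expect_error(fisher_or(-1, 2, 3, 4), class = "pbscan_domain_error")
})

test_that("fisher_or agrees with stats::fisher.test on random tables", {
  set.seed(4)
  for (i in 1:300) {
    tab <- sample(0:40, 4, TRUE)
    if (tab[1] + tab[2] == 0 || tab[3] + tab[4] == 0) next
    want <- fisher.test(matrix(tab, 2, byrow = TRUE))$p.value
    got <- fisher_or(tab[1], tab[2], tab[3], tab[4])$p_value
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("gene summaries aggregate retained outliers only, computed after pruning", {
  scan <- structure(
    data.frame(chrom = "1", pos = c(10L, 20L, 30L, 40L, 50L, 60L),
               ref = "A", alt = "G",
               pbs = c(0.4, 0.6, 0.9, 0.8, 0.7, 0.5),
               case_freq = 0.5, control_freq = 0.5, abs_diff = 0,
               fisher_p = 1, odds_ratio = 1,
               status = c("retained", "retained", "excluded_case_control",
                          "retained", "excluded_case_control",
                          "excluded_case_control"),
               genes = c("G1", "G1", "G2", "G2", "G3", "G3;G4"),
               stringsAsFactors = FALSE),
    class = c("scan_result", "data.frame"))
  gs <- summarize_genes(scan, scan_config())
  expect_equal(gs$gene, c("G2", "G1"))      # sorted by descending mean PBS
  expect_equal(gs$mean_pbs, c(0.8, 0.5))
  expect_equal(gs$n_snps, c(1L, 2L))
  # pruning demoted G2 from multi to single; G3/G4 vanish entirely
  expect_equal(gs$classification, c("single", "multi"))
  expect_false(any(c("G3", "G4") %in% gs$gene))
  # an intergenic retained SNP is counted but not summarized
  scan$genes[1] <- ""
  gs2 <- summarize_genes(scan, scan_config())
  expect_equal(attr(gs2, "n_intergenic"), 1L)
  expect_equal(gs2$n_snps[gs2$gene == "G1"], 1L)
})

test_that("injected case-control confounds are pruned and scored against truth", {
  for (s in 1:3) {
    p <- sim_params(n_snps = 6000, n_controls = 80, n_case_assoc = 3,
                    assoc_shift = 0.6, seed = s)
    co <- simulate_cohort(p)
    run <- pbs_selection_scan(co$genotypes, co$ref_panel, co$out_panel,
                              co$annotation)
    met <- evaluate_recovery(run$scan, co$truth)
    expect_equal(met$pruned_assoc_fraction, 1)
    # conservation across the pruning stage
    expect_equal(run$counts$outliers,
                 run$counts$retained + run$counts$excluded_case_control)
  }
})

test_that("selected SNPs respond to the frequency shift in the PBS tail", {
  # at delta = 0.5 the median selected PBS clears the null 95th percentile
  # with a wide margin (the median sits near 0.1-0.25 against a null 95th
  # percentile near 0.056); the 99th-percentile version of this check is
  # knife-edge because half the selected SNPs start at high frequency where
  # the shift delta * (1 - p) is small
  for (s in 1:3) {
    co <- simulate_cohort(sim_params(n_snps = 20000, n_selected = 50,
                                     selection_shift = 0.5, seed = s))
    res <- pbs(allele_frequencies(co$genotypes, "case"),
               panel_frequencies(co$ref_panel),
               panel_frequencies(co$out_panel))
    sel <- co$truth$label == "selected"
    expect_gt(median(res$pbs[sel], na.rm = TRUE),
              quantile(res$pbs[!sel], 0.95, na.rm = TRUE, names = FALSE))
  }
})

test_that("evaluate_recovery scores perfect and empty recovery correctly", {
  co <- simulate_cohort(sim_params(n_snps = 1000, n_selected = 4,
                                   selection_shift = 1, seed = 3))
  run <- pbs_selection_scan(co$genotypes, co$ref_panel, co$out_panel,
                            co$annotation)
  met <- evaluate_recovery(run$scan, co$truth)
  expect_true(met$power_selected >= 0 && met$power_selected <= 1)
  expect_true(met$fpr_null < 0.01)
  # a scan with nothing retained has zero power
  empty_scan <- run$scan[0, , drop = FALSE]
  attr(empty_scan, "scanned") <- attr(run$scan, "scanned")
  met0 <- evaluate_recovery(empty_scan, co$truth)
  expect_equal(met0$power_selected, 0)
})

test_that("the gene dot plot returns a ggplot with candidate genes only", {
  gs <- structure(data.frame(gene = c("A", "B", "C"), n_snps = c(3L, 2L, 1L),
                             classification = c("multi", "multi", "single"),
                             mean_pbs = c(0.9, 0.4, 0.2),
                             stringsAsFactors = FALSE),
                  class = c("gene_summary", "data.frame"))
  plt <- plot_gene_summary(gs, drop_gene = "A")
  expect_s3_class(plt, "ggplot")
  expect_equal(as.character(plt$data$gene), "B")
})
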