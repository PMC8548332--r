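toy_region <- function(haps, archaic, labels = rep("modern", nrow(haps))) {
  structure(list(positions = seq_len(ncol(haps)) * 10L,
                 haplotypes = haps, hap_labels = labels,
                 archaic = archaic, truth_introgressed = integer()),
            class = "haplotype_region")
}

test_that("encoding drops uninformative sites and recodes against the archaic", {
  # 3 haplotypes, archaic (1,1,0), plus a site where everyone is identical
  haps <- rbind(c(1L, 1L, 0L, 1L),
                c(0L, 0L, 0L, 1L),
                c(1L, 0L, 1L, 1L))
  reg <- toy_region(haps, c(1L, 1L, 0L, 1L))
  enc <- encode_against_archaic(reg, min_archaic_informative = 2L)
  expect_equal(sum(enc$site_mask), 3L)  # the all-identical 4th site dropped
  expect_equal(unname(enc$codes),
               rbind(c(1L, 1L, 1L), c(0L, 0L, 1L), c(1L, 0L, 0L)))
  # a haplotype equal to the archaic everywhere encodes all-1
  expect_true(all(enc$codes[1, ] == 1L))
  expect_error(encode_against_archaic(reg, min_archaic_informative = 4L),
               class = "pbscan_insufficient_data_error")
})

test_that("archaic distance counts mismatching retained sites", {
  haps <- rbind(c(1L, 1L, 0L), c(0L, 0L, 1L), c(1L, 0L, 0L))
  enc <- encode_against_archaic(toy_region(haps, c(1L, 1L, 0L)),
                                min_archaic_informative = 1L)
  expect_equal(archaic_distance(enc), c(0L, 3L, 1L))
  # distance 0 iff the code row is all 1
  expect_equal(archaic_distance(enc) == 0L,
               apply(enc$codes == 1L, 1, all))
})

test_that("cluster_and_sort follows the min-distance-first rule with documented tie-breaks", {
  # brute-force oracle: all leaf orders reachable by flipping dendrogram
  # merges, scored by the stated rule
  haps <- rbind(c(1L, 1L, 0L), c(0L, 0L, 0L), c(1L, 0L, 1L), c(1L, 1L, 0L))
  arch <- c(1L, 1L, 0L)
  enc <- encode_against_archaic(toy_region(haps, arch),
                                min_archaic_informative = 1L)
  ord <- cluster_and_sort(enc)
  d <- archaic_distance(enc)
  # the two archaic-identical rows (1 and 4) lead, in input order
  expect_equal(ord$order[1:2], c(1L, 4L))
  expect_equal(d[ord$order[1:2]], c(0L, 0L))
  # leaf sequence is a permutation and subtree minima never increase backwards
  expect_setequal(ord$order, 1:4)

  # exhaustive check on the stated rule for this dendrogram
  hc <- hclust(dist(enc$codes, method = "manhattan"), method = "average")
  lex <- apply(enc$codes, 1, paste, collapse = "")
  walk <- function(node) {
    if (node < 0) {
      i <- -node
      return(list(lv = i, d = d[i], lx = lex[i], ix = i))
    }
    a <- walk(hc$merge[node, 1]); b <- walk(hc$merge[node, 2])
    af <- if (a$d != b$d) a$d < b$d else if (a$lx != b$lx) a$lx < b$lx else a$ix < b$ix
    list(lv = if (af) c(a$lv, b$lv) else c(b$lv, a$lv),
         d = min(a$d, b$d), lx = min(a$lx, b$lx), ix = min(a$ix, b$ix))
  }
  expect_equal(ord$order, walk(nrow(hc$merge))$lv)

  # degenerate and deterministic behavior
  single <- encode_against_archaic(toy_region(rbind(c(0L, 1L)), c(1L, 1L)),
                                   min_archaic_informative = 1L)
  expect_equal(cluster_and_sort(single)$order, 1L)
  expect_identical(cluster_and_sort(enc)$order, cluster_and_sort(enc)$order)
})

test_that("noise-free introgressed haplotypes form a contiguous leading block", {
  for (s in 1:3) {
    reg <- simulate_introgression_region(50, 8, 120, 0.25,
                                         mutation_noise = 0, seed = s)
    enc <- encode_against_archaic(reg)
    ord <- cluster_and_sort(enc)
    lead <- ord$order[seq_along(reg$truth_introgressed)]
    expect_setequal(lead, reg$truth_introgressed)
  }
})

test_that("low-noise introgression is recovered by distance thresholding", {
  for (s in 1:3) {
    reg <- simulate_introgression_region(100, 10, 200, 0.25,
                                         mutation_noise = 0.02, seed = s)
    enc <- encode_against_archaic(reg)
    flagged <- which(archaic_distance(enc) <= 10L)
    expect_setequal(flagged, reg$truth_introgressed)
  }
})

test_that("render_strips writes an image and a deterministic ordering sidecar", {
  reg <- simulate_introgression_region(20, 4, 60, 0.3, mutation_noise = 0.01,
                                       seed = 7)
  enc <- encode_against_archaic(reg)
  ord <- cluster_and_sort(enc)
  img1 <- tempfile(fileext = ".png")
  img2 <- tempfile(fileext = ".png")
  p1 <- render_strips(enc, ord, img1)
  p2 <- render_strips(enc, ord, img2)
  expect_true(file.exists(img1))
  expect_gt(file.size(img1), 0)
  expect_identical(readLines(p1[["ordering"]]), readLines(p2[["ordering"]]))
  side <- read.table(p1[["ordering"]], header = TRUE, sep = "\t")
  expect_equal(side$rank, seq_len(nrow(enc$codes)))
  expect_equal(side$distance, ord$distances[ord$order])
  expect_true(all(diff(side$distance) >= 0 |
                    side$distance[-1] >= min(side$distance)))

  empty <- enc; empty$codes <- enc$codes[, 0, drop = FALSE]
  expect_error(render_strips(empty, ord, tempfile(fileext = ".png")),
               class = "pbscan_insufficient_data_error")
})

test_that("screen_candidates reports archaic-site/outlier overlap in both directions", {
  reg <- simulate_introgression_region(30, 5, 80, 0.25, mutation_noise = 0,
                                       seed = 11)
  enc <- encode_against_archaic(reg)
  private_sites <- enc$positions   # retained = archaic-private here
  off_sites <- setdiff(reg$positions, private_sites)

  # outliers disjoint from archaic-informative sites -> no overlap
  rep_no <- screen_candidates(list(reg), off_sites[1:3], threshold_distance = 5)
  expect_false(rep_no$overlap)
  expect_equal(rep_no$n_flagged, 5L)

  # an outlier on an archaic-private site carried by flagged haplotypes
  rep_yes <- screen_candidates(list(reg), private_sites[1], threshold_distance = 5)
  expect_true(rep_yes$overlap)
  expect_equal(rep_yes$overlap_positions, as.character(private_sites[1]))

  # no flagged haplotypes -> vacuously no overlap
  reg0 <- simulate_introgression_region(10, 0, 50, 0.3, seed = 12)
  rep0 <- screen_candidates(list(reg0), private_sites[1], threshold_distance = 2)
  expect_equal(rep0$n_flagged, 0L)
  expect_false(rep0$overlap)
})
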