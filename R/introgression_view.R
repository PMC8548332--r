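#' Encode haplotypes against the archaic reference
#'
#' Drops uninformative sites (where every haplotype, archaic included,
#' carries the same allele) and recodes the remainder relative to the
#' archaic allele: code 1 means "identical to the archaic at this site",
#' 0 means "different". The archaic's own encoding is all-1 by construction.
#'
#' @param region a [simulate_introgression_region()]-style `haplotype_region`.
#' @param min_archaic_informative minimum number of retained sites
#'   (default 2); fewer is an error.
#' @return object of class `encoded_haplotypes`: list with `codes`
#'   (haplotypes x retained sites 0/1 matrix), `site_mask` (logical over the
#'   region's sites), `positions` (retained coordinates), `hap_labels` and
#'   `region`.
#' @export
encode_against_archaic <- function(region, min_archaic_informative = 2L) {
  stopifnot(inherits(region, "haplotype_region"))
  hap <- region$haplotypes
  if (length(region$archaic) != ncol(hap))
    stop_pbscan("archaic vector not aligned to region sites",
                class = "pbscan_alignment_error")
  arch <- matrix(region$archaic, nrow = nrow(hap), ncol = ncol(hap), byrow = TRUE)
  same_as_arch <- hap == arch
  informative <- colSums(!same_as_arch) > 0L  # not everyone identical to archaic
  if (sum(informative) < min_archaic_informative)
    stop_pbscan("only %d archaic-informative sites retained (< %d)",
                sum(informative), min_archaic_informative,
                class = "pbscan_insufficient_data_error")
  codes <- matrix(as.integer(same_as_arch[, informative, drop = FALSE]),
                  nrow = nrow(hap))
  rownames(codes) <- rownames(hap)
  structure(list(codes = codes, site_mask = informative,
                 positions = region$positions[informative],
                 hap_labels = region$hap_labels, region = region),
            class = "encoded_haplotypes")
}

#' Hamming distance of each haplotype to the archaic reference
#'
#' The number of retained sites where a haplotype differs from the archaic
#' (code 0). Distance 0 iff the code row is all-1.
#'
#' @param encoded an [encode_against_archaic()] result.
#' @return integer vector, one distance per haplotype.
#' @export
archaic_distance <- function(encoded) {
  stopifnot(inherits(encoded, "encoded_haplotypes"))
  as.integer(rowSums(encoded$codes == 0L))
}

# lexicographic key of a 0/1 row ("0" < "1" charwise)
row_lex_key <- function(codes) {
  apply(codes, 1L, paste, collapse = "")
}

#' Cluster haplotypes and sort leaves by archaic proximity
#'
#' Agglomerative clustering (average or complete linkage) on pairwise
#' Hamming distances between haplotype code rows, with the dendrogram leaves
#' reordered so that at every merge the subtree whose minimum distance to the
#' archaic is smaller comes first; ties are broken by the lexicographically
#' smallest code row in the subtree, then by the smallest input index. The
#' result places archaic-like (putatively introgressed) haplotypes in a
#' leading block.
#'
#' @param encoded an [encode_against_archaic()] result.
#' @param linkage `"average"` (default) or `"complete"`.
#' @return object of class `haplotype_ordering`: list with `order` (leaf
#'   permutation of haplotype indices), `distances` (per-haplotype archaic
#'   distances), `merge` and `height` (the cluster tree, `stats::hclust`
#'   encoding; `NULL` for a single haplotype).
#' @export
cluster_and_sort <- function(encoded, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  d <- archaic_distance(encoded)
  h <- nrow(encoded$codes)
  if (h == 1L)
    return(structure(list(order = 1L, distances = d, merge = NULL, height = NULL),
                     class = "haplotype_ordering"))
  lex <- row_lex_key(encoded$codes)
  hc <- stats::hclust(stats::dist(encoded$codes, method = "manhattan"),
                      method = linkage)
  # recursive leaf ordering over the merge matrix; each subtree reports
  # (leaves, min archaic distance, min lexicographic row, min input index)
  walk <- function(node) {
    if (node < 0) {
      i <- -node
      return(list(leaves = i, min_d = d[i], min_lex = lex[i], min_i = i))
    }
    a <- walk(hc$merge[node, 1L])
    b <- walk(hc$merge[node, 2L])
    a_first <- if (a$min_d != b$min_d) a$min_d < b$min_d
      else if (a$min_lex != b$min_lex) a$min_lex < b$min_lex
      else a$min_i < b$min_i
    first <- if (a_first) a else b
    second <- if (a_first) b else a
    list(leaves = c(first$leaves, second$leaves),
         min_d = min(a$min_d, b$min_d),
         min_lex = min(a$min_lex, b$min_lex),
         min_i = min(a$min_i, b$min_i))
  }
  ord <- walk(nrow(hc$merge))$leaves
  structure(list(order = ord, distances = d, merge = hc$merge,
                 height = hc$height),
            class = "haplotype_ordering")
}

#' Render a haplotype strip plot
#'
#' Draws one row per haplotype (in cluster-and-sort order, archaic first row
#' on top as reference) and one column per retained site, colored by archaic
#' identity, with a left-hand population color bar. Writes a PNG or PDF
#' depending on the output extension, plus a sidecar TSV
#' (`<out_path>.order.tsv`) of `(rank, haplotype, population, distance)`
#' matching the ordering. Output is deterministic for fixed input.
#'
#' @param encoded an [encode_against_archaic()] result.
#' @param ordering the matching [cluster_and_sort()] result.
#' @param out_path image path ending in `.png` or `.pdf`.
#' @return named character vector with `image` and `ordering` paths,
#'   invisibly.
#' @export
render_strips <- function(encoded, ordering, out_path) {
  stopifnot(inherits(encoded, "encoded_haplotypes"),
            inherits(ordering, "haplotype_ordering"))
  if (!ncol(encoded$codes))
    stop_pbscan("no retained sites to draw", class = "pbscan_insufficient_data_error")
  if (length(ordering$order) != nrow(encoded$codes))
    stop_pbscan("ordering does not match encoded haplotypes",
                class = "pbscan_alignment_error")
  ord <- ordering$order
  labels <- rownames(encoded$codes)
  if (is.null(labels)) labels <- sprintf("hap%03d", seq_len(nrow(encoded$codes)))
  pops <- encoded$hap_labels
  side <- sub("\\.(png|pdf)$", ".order.tsv", out_path)
  if (identical(side, out_path)) side <- paste0(out_path, ".order.tsv")
  write_report(data.frame(rank = seq_along(ord), haplotype = labels[ord],
                          population = pops[ord],
                          distance = ordering$distances[ord],
                          stringsAsFactors = FALSE),
               side, kind = "ordering")

  if (grepl("\\.pdf$", out_path)) grDevices::pdf(out_path, width = 7, height = 5)
  else grDevices::png(out_path, width = 900, height = 600)
  on.exit(grDevices::dev.off())
  m <- encoded$codes[ord, , drop = FALSE]
  pop_levels <- unique(pops[ord])
  pop_cols <- grDevices::hcl.colors(max(2L, length(pop_levels)), "Dark 3")
  graphics::layout(matrix(1:2, 1L), widths = c(1, 12))
  graphics::par(mar = c(4, 0.5, 3, 0))
  graphics::image(z = t(matrix(match(pops[ord], pop_levels), ncol = 1)),
                  x = 1, y = seq_len(nrow(m)),
                  col = pop_cols[seq_along(pop_levels)], axes = FALSE,
                  xlab = "", ylab = "", useRaster = FALSE,
                  zlim = c(1, max(2L, length(pop_levels))))
  graphics::par(mar = c(4, 0.5, 3, 4))
  # rows drawn bottom-up; reverse so rank 1 appears at the top
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)),
                  z = t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  col = c("grey92", "firebrick"), zlim = c(0, 1),
                  xlab = "archaic-informative site", ylab = "",
                  axes = FALSE, useRaster = FALSE)
  graphics::axis(1)
  graphics::mtext("haplotypes sorted by increasing distance to archaic",
                  side = 3, line = 0.5, cex = 0.9)
  invisible(c(image = out_path, ordering = side))
}

#' Screen candidate regions for introgression/selection overlap
#'
#' For each region: flags haplotypes within `threshold_distance` of the
#' archaic as putatively introgressed, collects the archaic-informative
#' sites at which any flagged haplotype carries the archaic allele, and
#' reports whether any selection-outlier SNP position falls on one of those
#' sites. A region with no flagged haplotype vacuously reports no overlap.
#'
#' @param regions list of `haplotype_region` objects (shared coordinate
#'   system with the outlier positions).
#' @param outlier_positions numeric vector of retained selection-outlier SNP
#'   positions.
#' @param threshold_distance maximum archaic distance for flagging.
#' @return data.frame with one row per region: `region`, `n_flagged`,
#'   `overlap` (logical) and `overlap_positions` (";"-joined).
#' @export
screen_candidates <- function(regions, outlier_positions, threshold_distance) {
  rows <- lapply(seq_along(regions), function(i) {
    enc <- encode_against_archaic(regions[[i]], min_archaic_informative = 1L)
    dist <- archaic_distance(enc)
    flagged <- which(dist <= threshold_distance)
    sites <- numeric()
    if (length(flagged)) {
      carried <- colSums(enc$codes[flagged, , drop = FALSE] == 1L) > 0L
      sites <- enc$positions[carried]
    }
    hit <- intersect(sites, outlier_positions)
    data.frame(region = i, n_flagged = length(flagged),
               overlap = length(hit) > 0L,
               overlap_positions = paste(hit, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
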