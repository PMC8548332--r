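#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`: the chance that a random query of `n`
#' genes from a background of `N` overlaps a set of `K` genes in at least
#' `k` members. Computed in the log domain via `stats::phyper` for numerical
#' stability.
#'
#' @param k observed overlap.
#' @param K gene-set size (within the background).
#' @param n query size (within the background).
#' @param N background-universe size.
#' @return p-value(s); vectors recycle.
#' @export
#' @examples
#' ora_pvalue(5, 5, 5, 20)  # 1 / choose(20, 5)
ora_pvalue <- function(k, K, n, N) {
  kk <- max(length(k), length(K), length(n), length(N))
  k <- rep_len(k, kk); K <- rep_len(K, kk); n <- rep_len(n, kk); N <- rep_len(N, kk)
  if (any(k < 0 | K > N | n > N | k > pmin(K, n)))
    stop_pbscan("inconsistent hypergeometric counts", class = "pbscan_domain_error")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment `q_(i) = min_(j >= i) p_(j) m / j`, capped at 1 and
#' mapped back to input order (`stats::p.adjust`, method `"BH"`).
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop_pbscan("p-values outside [0,1]", class = "pbscan_domain_error")
  stats::p.adjust(p_values, method = "BH")
}

#' Over-representation analysis of a gene list
#'
#' Tests each set of a collection for enrichment of the query list against
#' an explicit background universe with the hypergeometric upper tail and
#' BH FDR across all tested sets. Gene names are matched exactly after
#' uppercase normalization. Query genes absent from the background are
#' dropped (with a count); set members are intersected with the background.
#' An exclusion filter (a character vector of gene names, or a predicate
#' function over names, e.g. an HLA-prefix rule) is applied to query, sets
#' and background alike before counting.
#'
#' @param query character vector of candidate gene names.
#' @param collection a [read_gmt()] collection.
#' @param background character vector: the gene universe (e.g. all genes
#'   carrying scanned SNPs).
#' @param exclude `NULL`, a character vector of gene names to drop, or a
#'   function mapping gene names to a logical "drop" vector.
#' @return data.frame of class `enrichment_result` with columns
#'   `set_name, source, n_overlap, overlapping_genes, n_set, n_query,
#'   n_background, p_value, q_value`, sorted by ascending p; attribute
#'   `n_query_dropped` counts query genes outside the background.
#' @export
#' @examples
#' coll <- structure(list(sets = list(S = paste0("G", 1:10)),
#'                        source = c(S = "demo"), n_duplicates = 0L),
#'                   class = "gene_set_collection")
#' run_enrichment(paste0("G", 1:5), coll, paste0("G", 1:100))
run_enrichment <- function(query, collection, background, exclude = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!length(background))
    stop_pbscan("background universe is empty", class = "pbscan_config_error")
  if (!length(collection$sets))
    stop_pbscan("gene-set collection is empty", class = "pbscan_config_error")
  norm <- function(x) toupper(x)
  drop_fun <- if (is.null(exclude)) function(x) rep(FALSE, length(x))
    else if (is.function(exclude)) function(x) as.logical(exclude(x))
    else function(x) x %in% norm(exclude)
  bg <- unique(norm(background))
  bg <- bg[!drop_fun(bg)]
  q <- unique(norm(query))
  q <- q[!drop_fun(q)]
  n_dropped <- sum(!(q %in% bg))
  q <- intersect(q, bg)
  N <- length(bg); n <- length(q)
  rows <- lapply(names(collection$sets), function(nm) {
    members <- intersect(unique(norm(collection$sets[[nm]])), bg)
    ov <- sort(intersect(q, members))
    data.frame(set_name = nm, source = unname(collection$source[nm]),
               n_overlap = length(ov),
               overlapping_genes = paste(ov, collapse = ";"),
               n_set = length(members), n_query = n, n_background = N,
               p_value = ora_pvalue(length(ov), length(members), n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  out <- out[order(out$p_value, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"),
            n_query_dropped = n_dropped)
}

#' HLA-prefix exclusion predicate
#'
#' Convenience filter for [run_enrichment()]'s `exclude` argument: drops
#' genes whose (uppercased) name starts with the given prefix, by default
#' `"HLA-"` — the standard device for re-running enrichment without the
#' hyperpolymorphic HLA region.
#'
#' @param prefix gene-name prefix (default `"HLA-"`).
#' @return a predicate function usable as `exclude`.
#' @export
exclude_prefix <- function(prefix = "HLA-") {
  force(prefix)
  function(genes) startsWith(toupper(genes), toupper(prefix))
}
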