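#' Over-representation analysis against a gene-set collection
#'
#' Hypergeometric upper-tail test of a query gene list against each set in
#' the collection, within an explicit gene universe. Sets are intersected
#' with the universe first and excluded when their in-universe size falls
#' outside `size_bounds`. Query genes outside the universe are dropped with
#' a warning. False-discovery control across the tested sets uses
#' Benjamini-Hochberg ([bh_adjust()]); Bonferroni is available via
#' `adjust = "bonferroni"`.
#'
#' @param query Character vector of gene ids.
#' @param sets Named list of gene-id vectors.
#' @param universe Character vector: the gene background (e.g. all genes in
#'   the expression matrix). Results are universe-sensitive, so it is a
#'   mandatory explicit input.
#' @param size_bounds In-universe set-size bounds `[min, max]`; default
#'   `c(5, 2000)`.
#' @param adjust Multiple-testing method, `"BH"` (default) or
#'   `"bonferroni"`.
#' @return Data.frame with columns `set`, `overlap`, `query_size`,
#'   `set_size`, `universe_size`, `p`, `q`, sorted by p.
#' @export
ora_test <- function(query, sets, universe, size_bounds = c(5L, 2000L),
                     adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  if (!length(query)) stop("empty query after universe filtering")
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  sizes <- vapply(sets, length, integer(1))
  sets <- sets[sizes >= size_bounds[1] & sizes <= size_bounds[2]]
  if (!length(sets)) {
    return(data.frame(set = character(), overlap = integer(),
                      query_size = integer(), set_size = integer(),
                      universe_size = integer(), p = numeric(),
                      q = numeric(), stringsAsFactors = FALSE))
  }
  N <- length(universe)
  k <- length(query)
  overlap <- vapply(sets, function(s) length(intersect(s, query)),
                    integer(1))
  m <- vapply(sets, length, integer(1))
  # P(X >= overlap), X ~ Hypergeometric(m in-set, N - m out, k drawn)
  p <- stats::phyper(overlap - 1L, m, N - m, k, lower.tail = FALSE)
  q <- if (adjust == "BH") bh_adjust(p) else pmin(1, p * length(p))
  out <- data.frame(set = names(sets), overlap = overlap, query_size = k,
                    set_size = m, universe_size = N, p = p, q = q,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p), , drop = FALSE]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' values are returned in the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, elementwise at least as large as the input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
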