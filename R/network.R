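#' Build a regulator-target edge list from an expression matrix
#'
#' Computes mutual information for every (regulator, gene) pair and keeps
#' the pairs whose independence-test p-value falls below `p_threshold`.
#' Regulator-regulator pairs are allowed (an intermediate node in the
#' data-processing-inequality step may itself be a regulator) and are listed
#' once, under the first regulator. Genes with constant expression are
#' dropped before estimation; regulators absent from the matrix are dropped
#' with a warning.
#'
#' @param expr Numeric genes x samples matrix (log scale).
#' @param regulators Character vector of regulator (TF) gene ids.
#' @param p_threshold Retain edges with p below this value; the default
#'   1e-8 refers to the Bonferroni-corrected p-value.
#' @param null An `mi_null` model from [fit_mi_null()]. If it carries no
#'   `n_pairs_tested`, the canonical count
#'   `length(regulators) * (nrow(expr) - 1)` is filled in.
#' @param corrected Threshold the Bonferroni-corrected p-value (default)
#'   rather than the uncorrected one. The reported `p` column is always the
#'   corrected value.
#' @return An `edge_list`: a data.frame with columns `tf`, `target`, `mi`
#'   (nats) and `p` (Bonferroni-corrected).
#' @seealso [apply_dpi()], [edges_to_regulons()]
#' @export
build_edge_list <- function(expr, regulators, p_threshold = 1e-8, null,
                            corrected = TRUE) {
  expr <- as_expression_matrix(expr)
  expr <- drop_constant_genes(expr)
  if (length(regulators) == 0L) stop("empty regulator list")
  missing <- setdiff(regulators, rownames(expr))
  if (length(missing)) {
    warning(length(missing), " regulator(s) absent from the expression ",
            "matrix were dropped: ",
            paste(utils::head(missing, 5), collapse = ", "))
    regulators <- intersect(regulators, rownames(expr))
  }
  if (length(regulators) == 0L) stop("no regulators left after filtering")
  stopifnot(inherits(null, "mi_null"))
  if (is.na(null$n_pairs_tested)) {
    null$n_pairs_tested <- length(regulators) * (nrow(expr) - 1)
  }

  genes <- rownames(expr)
  n <- ncol(expr)
  prep <- mi_prep(n)
  rk <- apply(expr, 1L, mi_ranks)             # samples x genes
  colnames(rk) <- genes
  reg_idx <- match(regulators, genes)

  out <- vector("list", length(regulators))
  for (i in seq_along(regulators)) {
    ri <- reg_idx[i]
    # each unordered pair once: all non-regulators, plus regulators later
    # in the list
    cand <- setdiff(seq_len(nrow(expr)), c(ri, reg_idx[seq_len(i)]))
    if (!length(cand)) next
    A <- prep$K0[rk[, ri], rk[, ri]]
    mi <- vapply(cand, function(ci) {
      B <- prep$K0[rk[, ci], rk[, ci]]
      max(mean(log(.rowSums(A * B, n, n))) - prep$log_joint_norm -
            2 * prep$mean_log_marg, 0)
    }, numeric(1))
    out[[i]] <- data.frame(tf = regulators[i], target = genes[cand],
                           mi = mi, stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, out)
  if (is.null(edges)) {
    edges <- data.frame(tf = character(), target = character(),
                        mi = numeric(), p = numeric(),
                        stringsAsFactors = FALSE)
    return(new_edge_list(edges, regulators, null$n_pairs_tested))
  }
  p_raw <- mi_pvalue(null, edges$mi, corrected = FALSE)
  edges$p <- pmin(1, p_raw * null$n_pairs_tested)
  keep <- if (corrected) edges$p < p_threshold else p_raw < p_threshold
  edges <- edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  new_edge_list(edges, regulators, null$n_pairs_tested)
}

new_edge_list <- function(df, regulators, n_pairs_tested = NA_real_) {
  stopifnot(all(c("tf", "target", "mi", "p") %in% names(df)))
  structure(df, class = c("edge_list", "data.frame"),
            regulators = regulators, n_pairs_tested = n_pairs_tested)
}

#' @export
print.edge_list <- function(x, ...) {
  cat(sprintf("Edge list: %d interactions, %d regulator(s)\n",
              nrow(x), length(unique(x$tf))))
  if (nrow(x)) {
    cat(sprintf("  MI range: %.3g - %.3g nats\n", min(x$mi), max(x$mi)))
    print.data.frame(utils::head(x, 6))
    if (nrow(x) > 6) cat("  ...\n")
  }
  invisible(x)
}

#' Trim indirect interactions with the data processing inequality
#'
#' For every edge (x, y) and every regulator z forming a path x - z - y in
#' the input list, the edge (x, y) is removed when
#' `MI(x, y) < (1 - tolerance) * min(MI(x, z), MI(z, y))`. All removal
#' decisions are evaluated against the original edge list in a single pass
#' (no cascading), and ties keep the edge. Edges are treated as undirected
#' for path lookup since MI is symmetric.
#'
#' @param edges An `edge_list` from [build_edge_list()].
#' @param tolerance DPI tolerance in `[0, 1)`; default 0.1. Larger values
#'   remove fewer edges.
#' @return The trimmed `edge_list`, a subset of the input.
#' @export
apply_dpi <- function(edges, tolerance = 0.1) {
  stopifnot(inherits(edges, "edge_list"))
  if (tolerance < 0 || tolerance >= 1) stop("tolerance must be in [0, 1)")
  if (nrow(edges) == 0L) return(edges)
  regs <- attr(edges, "regulators")
  nodes <- unique(c(edges$tf, edges$target))
  regs <- intersect(regs, nodes)
  # regulator x node MI lookup; every stored edge touches a regulator, so
  # this covers all path legs through a regulator z
  M <- matrix(NA_real_, length(regs), length(nodes),
              dimnames = list(regs, nodes))
  ti <- match(edges$tf, regs)
  M[cbind(ti, match(edges$target, nodes))] <- edges$mi
  rev_reg <- match(edges$target, regs)      # target that is itself a regulator
  has_rev <- !is.na(rev_reg)
  M[cbind(rev_reg[has_rev], match(edges$tf[has_rev], nodes))] <-
    edges$mi[has_rev]

  slack <- 1 - tolerance
  xi <- match(edges$tf, nodes)
  yi <- match(edges$target, nodes)
  drop <- logical(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    leg1 <- M[, xi[e]]
    leg2 <- M[, yi[e]]
    path_min <- pmin(leg1, leg2)
    path_min[match(c(edges$tf[e], edges$target[e]), regs, nomatch = 0L)] <- NA
    drop[e] <- any(edges$mi[e] < slack * path_min, na.rm = TRUE)
  }
  out <- edges[!drop, , drop = FALSE]
  rownames(out) <- NULL
  new_edge_list(out, attr(edges, "regulators"), attr(edges, "n_pairs_tested"))
}

#' Convert an edge list into regulons with mode and confidence
#'
#' Bridges network reconstruction to activity inference: each regulator's
#' retained targets become its regulon. The mode of action is the signed
#' Spearman correlation between regulator and target expression, and the
#' confidence weight (likelihood) is the edge MI normalized by the largest
#' MI within that regulon, so the strongest edge has likelihood exactly 1.
#' Regulators with fewer than `min_size` targets are dropped with a message.
#'
#' @param edges An `edge_list` (typically after [apply_dpi()]).
#' @param expr The expression matrix the edges were estimated from.
#' @param min_size Minimum regulon size to retain a regulator (default 25).
#' @return A `regulon_set`: a named list of data.frames with columns
#'   `target`, `mode` and `likelihood`.
#' @export
edges_to_regulons <- function(edges, expr, min_size = 25L) {
  stopifnot(inherits(edges, "edge_list"))
  if (min_size < 1L) stop("min_size must be >= 1")
  expr <- as_expression_matrix(expr)
  regulons <- list()
  for (tf in unique(edges$tf)) {
    sub <- edges[edges$tf == tf, , drop = FALSE]
    if (nrow(sub) < min_size) next
    tf_rank <- rank(expr[tf, ])
    tg_rank <- t(apply(expr[sub$target, , drop = FALSE], 1L, rank))
    mode <- as.numeric(stats::cor(tf_rank, t(tg_rank)))
    regulons[[tf]] <- data.frame(target = sub$target,
                                 mode = mode,
                                 likelihood = sub$mi / max(sub$mi),
                                 stringsAsFactors = FALSE)
  }
  n_drop <- length(unique(edges$tf)) - length(regulons)
  if (n_drop > 0) {
    message(n_drop, " regulator(s) dropped with fewer than ", min_size,
            " targets")
  }
  structure(regulons, class = "regulon_set")
}

#' @export
print.regulon_set <- function(x, ...) {
  sizes <- vapply(x, nrow, integer(1))
  cat(sprintf("Regulon set: %d regulator(s)\n", length(x)))
  if (length(x)) {
    cat(sprintf("  regulon sizes: %d - %d (median %d)\n",
                min(sizes), max(sizes), as.integer(stats::median(sizes))))
  }
  invisible(x)
}
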