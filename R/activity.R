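#' Case/control differential-expression signature
#'
#' Per-gene Welch two-sample t-statistic (case minus control) mapped to a
#' z-score through the t cumulative distribution, so the sign is positive
#' when a gene is higher in cases. Zero within-group variances are lifted
#' to a small floor (with a message) so the statistic stays defined.
#'
#' @param expr Numeric genes x samples matrix.
#' @param labels Per-sample condition, values `"case"`/`"control"`, named
#'   by sample (or in column order).
#' @param var_floor Lower bound applied to within-group variances.
#' @return Named numeric vector of z-scores over the gene universe
#'   (class `mr_signature`).
#' @export
compute_signature <- function(expr, labels, var_floor = 1e-8) {
  expr <- as_expression_matrix(expr)
  labels <- check_labels(labels, colnames(expr))
  case <- expr[, labels == "case", drop = FALSE]
  ctrl <- expr[, labels == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")
  v1 <- matrixStats_row_var(case)
  v2 <- matrixStats_row_var(ctrl)
  n_floored <- sum(v1 < var_floor) + sum(v2 < var_floor)
  if (n_floored > 0) {
    message(n_floored, " zero/near-zero within-group variance(s) lifted ",
            "to the floor")
  }
  v1 <- pmax(v1, var_floor)
  v2 <- pmax(v2, var_floor)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (rowMeans(case) - rowMeans(ctrl)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  # sign-symmetric t -> z via log-scale tail probabilities (finite for
  # arbitrarily large |t|)
  lt <- stats::pt(-abs(tstat), df, log.p = TRUE)
  z <- -sign(tstat) * stats::qnorm(lt, log.p = TRUE)
  z[tstat == 0] <- 0
  structure(stats::setNames(z, rownames(expr)), class = "mr_signature")
}

# Rank-transform a signature to standard normal quantiles over its
# universe; ties get their average rank.
signature_quantiles <- function(z) {
  n <- length(z)
  stats::setNames(stats::qnorm(rank(unclass(z)) / (n + 1)), names(z))
}

#' Weighted rank-based regulon enrichment score
#'
#' Analytic enrichment of one regulon against a signature: signature values
#' are rank-transformed to standard normal quantiles and the normalized
#' enrichment score is the confidence-weighted, mode-signed mean
#' \eqn{NES = \sum_i w_i m_i q_i / \sqrt{\sum_i w_i^2}}. Under random
#' target placement the score has mean ~0 and variance ~1, so it is
#' directly comparable across regulon sizes. Targets absent from the
#' signature universe are skipped.
#'
#' @param sig Named z-score vector from [compute_signature()].
#' @param regulon Data.frame with columns `target`, `mode` (in `[-1, 1]`)
#'   and `likelihood` (weights in (0, 1]).
#' @param min_targets Minimum number of regulon targets that must map into
#'   the signature universe (default 10).
#' @return The NES, one number.
#' @export
area_nes <- function(sig, regulon, min_targets = 10L) {
  q <- signature_quantiles(sig)
  area_nes_from_q(q, regulon, min_targets)
}

area_nes_from_q <- function(q, regulon, min_targets) {
  idx <- match(regulon$target, names(q))
  ok <- !is.na(idx)
  if (sum(ok) < min_targets) {
    stop("only ", sum(ok), " regulon target(s) map into the signature ",
         "universe (minimum ", min_targets, ")")
  }
  w <- regulon$likelihood[ok]
  sum(w * regulon$mode[ok] * q[idx[ok]]) / sqrt(sum(w * w))
}

#' Protein-activity inference with a sample-permutation null
#'
#' Computes each regulator's NES on the observed case/control signature,
#' then calibrates significance by shuffling the condition labels
#' `n_perm` times, recomputing the signature and all NES values each time.
#' Null scores are standardized per regulator and pooled across regulators,
#' and the two-sided permutation p-value uses the standard +1 pseudocount.
#' Benjamini-Hochberg adjustment is applied across regulators.
#'
#' @param expr Numeric genes x samples matrix.
#' @param labels Per-sample `"case"`/`"control"` labels.
#' @param regulons A `regulon_set` (or plain named list of data.frames with
#'   `target`, `mode`, `likelihood`).
#' @param n_perm Number of label permutations (>= 100; study default 1000).
#' @param min_targets Regulons mapping fewer targets are skipped with a
#'   message.
#' @param seed Integer seed for the permutations.
#' @return An `activity_table`: data.frame with columns `tf`, `nes`, `p`,
#'   `p_adj` and `direction` (`activated` iff `nes > 0`).
#' @export
permutation_pvalues <- function(expr, labels, regulons, n_perm = 1000L,
                                min_targets = 10L, seed = 1L) {
  expr <- as_expression_matrix(expr)
  labels <- check_labels(labels, colnames(expr))
  if (n_perm < 100L) stop("n_perm must be at least 100")
  universe <- rownames(expr)
  mapped <- vapply(regulons, function(r) sum(r$target %in% universe),
                   integer(1))
  if (any(mapped < min_targets)) {
    message(sum(mapped < min_targets), " regulon(s) skipped with fewer ",
            "than ", min_targets, " mapped targets")
    regulons <- regulons[mapped >= min_targets]
  }
  if (!length(regulons)) stop("no regulon maps enough targets")
  tfs <- names(regulons)

  # dense TF x gene weight matrix: NES for all TFs is one matrix product
  W <- matrix(0, length(tfs), length(universe),
              dimnames = list(tfs, universe))
  for (tf in tfs) {
    r <- regulons[[tf]]
    ok <- r$target %in% universe
    W[tf, r$target[ok]] <- r$likelihood[ok] * r$mode[ok]
  }
  denom <- sqrt(rowSums(W * W))
  nes_all <- function(lab) {
    q <- signature_quantiles(compute_signature(expr, lab))
    as.numeric(W %*% q[universe]) / denom
  }
  nes_obs <- suppressMessages(nes_all(labels))

  withr_seed(seed, {
    null_nes <- matrix(NA_real_, length(tfs), n_perm)
    for (b in seq_len(n_perm)) {
      perm <- stats::setNames(sample(unname(labels)), names(labels))
      while (length(unique(perm)) < 2L) {
        perm <- stats::setNames(sample(unname(labels)), names(labels))
      }
      null_nes[, b] <- suppressMessages(nes_all(perm))
    }
  })
  mu <- rowMeans(null_nes)
  sdv <- apply(null_nes, 1L, stats::sd)
  sdv[sdv == 0] <- 1
  z_obs <- (nes_obs - mu) / sdv
  pool <- abs((null_nes - mu) / sdv)
  p <- vapply(z_obs, function(z) {
    (1 + sum(pool >= abs(z))) / (length(pool) + 1)
  }, numeric(1))
  structure(data.frame(tf = tfs,
                       nes = nes_obs,
                       p = p,
                       p_adj = stats::p.adjust(p, method = "BH"),
                       direction = ifelse(nes_obs > 0, "activated",
                                          "repressed"),
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("activity_table", "data.frame"),
            n_perm = n_perm, seed = seed)
}

#' Select master regulators from an activity table
#'
#' Keeps regulators with adjusted p below `alpha`, ordered by decreasing
#' absolute NES.
#'
#' @param table An `activity_table`.
#' @param alpha Significance level on the BH-adjusted p (default 0.05).
#' @return The selected subset, still an `activity_table`.
#' @export
select_mrs <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "activity_table"))
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  out <- table[table$p_adj < alpha, , drop = FALSE]
  out <- out[order(-abs(out$nes)), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("activity_table", "data.frame"),
            n_perm = attr(table, "n_perm"), seed = attr(table, "seed"))
}

#' Consensus master regulators across cohorts
#'
#' Intersects two or more activity tables: a regulator enters the consensus
#' when it is significant (adjusted p < `alpha`) in every cohort with a
#' concordant NES sign. Significant-everywhere regulators with discordant
#' signs are excluded and reported in the `discordant` attribute.
#'
#' @param tables List of >= 2 `activity_table`s sharing a TF namespace.
#' @param alpha Per-cohort significance level (default 0.05).
#' @return A `consensus_mrs` data.frame with `tf`, `direction` and one
#'   `nes_<i>` / `p_adj_<i>` pair per cohort.
#' @export
intersect_mrs <- function(tables, alpha = 0.05) {
  if (!is.list(tables) || length(tables) < 2L) {
    stop("need at least 2 activity tables")
  }
  lapply(tables, function(t) stopifnot(inherits(t, "activity_table")))
  if (is.null(names(tables))) {
    names(tables) <- paste0("cohort", seq_along(tables))
  }
  sig_sets <- lapply(tables, function(t) t$tf[t$p_adj < alpha])
  common <- Reduce(intersect, sig_sets)
  rows <- lapply(common, function(tf) {
    nes <- vapply(tables, function(t) t$nes[match(tf, t$tf)], numeric(1))
    padj <- vapply(tables, function(t) t$p_adj[match(tf, t$tf)], numeric(1))
    list(tf = tf, nes = nes, p_adj = padj,
         concordant = length(unique(sign(nes))) == 1L)
  })
  conc <- vapply(rows, `[[`, logical(1), "concordant")
  discordant <- vapply(rows[!conc], `[[`, character(1), "tf")
  if (length(discordant)) {
    message(length(discordant), " TF(s) significant everywhere but with ",
            "discordant direction excluded: ",
            paste(discordant, collapse = ", "))
  }
  rows <- rows[conc]
  out <- data.frame(
    tf = vapply(rows, `[[`, character(1), "tf"),
    direction = vapply(rows, function(r)
      if (r$nes[1] > 0) "activated" else "repressed", character(1)),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(tables)) {
    out[[paste0("nes_", names(tables)[i])]] <-
      vapply(rows, function(r) r$nes[i], numeric(1))
    out[[paste0("p_adj_", names(tables)[i])]] <-
      vapply(rows, function(r) r$p_adj[i], numeric(1))
  }
  structure(out, class = c("consensus_mrs", "data.frame"),
            discordant = discordant, alpha = alpha,
            candidate_overlap = length(common))
}

#' @export
print.consensus_mrs <- function(x, ...) {
  cat(sprintf("Consensus master regulators: %d (%d activated, %d repressed)\n",
              nrow(x), sum(x$direction == "activated"),
              sum(x$direction == "repressed")))
  disc <- attr(x, "discordant")
  if (length(disc)) {
    cat("  discordant-direction TFs excluded:",
        paste(disc, collapse = ", "), "\n")
  }
  if (nrow(x)) print.data.frame(x)
  invisible(x)
}

#' @export
print.activity_table <- function(x, ...) {
  cat(sprintf("Activity table: %d regulator(s), %d activated / %d repressed at face value\n",
              nrow(x), sum(x$nes > 0), sum(x$nes <= 0)))
  print.data.frame(utils::head(as.data.frame(x)[order(x$p), ], 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Per-sample regulator activity
#'
#' Single-sample analog of the case/control NES used for correlating
#' activity with cell-infiltration scores: each sample gets a one-vs-rest
#' z signature (gene value minus the cohort mean, over the cohort standard
#' deviation) and every regulon is scored on it with [area_nes()].
#'
#' @param expr Numeric genes x samples matrix.
#' @param regulons A `regulon_set`.
#' @param min_targets Minimum mapped targets per regulon.
#' @return Numeric regulators x samples matrix of per-sample NES.
#' @export
sample_activity <- function(expr, regulons, min_targets = 10L) {
  expr <- as_expression_matrix(expr)
  universe <- rownames(expr)
  sdv <- sqrt(matrixStats_row_var(expr))
  if (any(sdv == 0)) stop("constant-expression gene(s) in the matrix; ",
                          "drop them before scoring")
  Z <- (expr - rowMeans(expr)) / sdv
  mapped <- vapply(regulons, function(r) sum(r$target %in% universe),
                   integer(1))
  if (any(mapped < min_targets)) {
    message(sum(mapped < min_targets), " regulon(s) skipped with fewer ",
            "than ", min_targets, " mapped targets")
    regulons <- regulons[mapped >= min_targets]
  }
  if (!length(regulons)) stop("no regulon maps enough targets")
  W <- matrix(0, length(regulons), length(universe),
              dimnames = list(names(regulons), universe))
  for (tf in names(regulons)) {
    r <- regulons[[tf]]
    ok <- r$target %in% universe
    W[tf, r$target[ok]] <- r$likelihood[ok] * r$mode[ok]
  }
  denom <- sqrt(rowSums(W * W))
  Q <- apply(Z, 2L, function(z) stats::qnorm(rank(z) / (length(z) + 1)))
  out <- (W %*% Q) / denom
  dimnames(out) <- list(names(regulons), colnames(expr))
  out
}
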