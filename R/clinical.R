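#' Pearson association between two per-sample quantities
#'
#' Product-moment correlation with the two-sided p-value from the t
#' transform with n-2 degrees of freedom. Pairs with missing values are
#' dropped (pairwise-complete); ordinal grades are treated as numeric, so
#' any affine re-coding of the grade scale leaves r unchanged.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `r`, `p` and `n` (samples used).
#' @export
pearson_assoc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (max(x) == min(x) || max(y) == min(y)) {
    stop("correlation undefined for a constant input")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Correlate regulator expression with ordinal pathology grades
#'
#' Runs [pearson_assoc()] of each regulator's expression against the
#' inflammation and fibrosis grades of the clinical table, grades treated
#' as numeric 0-3.
#'
#' @param expr Numeric genes x samples matrix.
#' @param clinical Data.frame with columns `sample`, `inflammation`,
#'   `fibrosis` (see [read_clinical()]).
#' @param tfs Regulators to test (must be rows of `expr`).
#' @return Data.frame with columns `tf`, `variable`, `r`, `p`, `n`.
#' @export
grade_associations <- function(expr, clinical, tfs) {
  expr <- as_expression_matrix(expr)
  check_clinical(clinical)
  missing <- setdiff(clinical$sample, colnames(expr))
  if (length(missing)) {
    stop("clinical sample(s) absent from expression: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  tfs <- intersect(tfs, rownames(expr))
  out <- list()
  for (v in c("inflammation", "fibrosis")) {
    for (tf in tfs) {
      a <- pearson_assoc(expr[tf, clinical$sample], clinical[[v]])
      out[[length(out) + 1L]] <- data.frame(tf = tf, variable = v,
                                            r = a$r, p = a$p, n = a$n,
                                            stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Single-covariate Cox proportional-hazards fit
#'
#' Partial-likelihood fit of survival time against one continuous
#' covariate (Breslow tie handling), reporting the log hazard ratio, the
#' hazard ratio, the Wald p-value and a convergence flag. Non-convergence
#' or monotone likelihood (perfect separation) yields a flagged result
#' rather than an error; a constant covariate is non-identifiable and is
#' rejected.
#'
#' @param time Survival times (> 0).
#' @param event Event indicators (1 = event, 0 = censored).
#' @param covariate Per-sample numeric covariate.
#' @return List with `beta`, `hr`, `se`, `p` and `converged`.
#' @export
cox_fit <- function(time, event, covariate) {
  if (any(time <= 0)) stop("survival times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  if (sum(event) < 1L) stop("need at least one event")
  if (max(covariate) == min(covariate)) {
    stop("constant covariate: hazard ratio is non-identifiable")
  }
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ covariate,
                    ties = "breslow",
                    control = survival::coxph.control(eps = 1e-8,
                                                      iter.max = 50)),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  beta <- unname(fit$coefficients)
  se <- sqrt(unname(fit$var[1, 1]))
  if (!is.finite(beta) || !is.finite(se)) converged <- FALSE
  list(beta = beta,
       hr = exp(beta),
       se = se,
       p = 2 * stats::pnorm(-abs(beta / se)),
       converged = converged)
}

#' Cox survival screen over a set of regulators
#'
#' Fits [cox_fit()] per regulator using its expression in the clinical
#' samples as the covariate.
#'
#' @inheritParams grade_associations
#' @return Data.frame with columns `tf`, `beta`, `hr`, `p`, `converged`.
#' @export
survival_associations <- function(expr, clinical, tfs) {
  expr <- as_expression_matrix(expr)
  check_clinical(clinical)
  tfs <- intersect(tfs, rownames(expr))
  rows <- lapply(tfs, function(tf) {
    f <- cox_fit(clinical$time, clinical$event,
                 expr[tf, clinical$sample])
    data.frame(tf = tf, beta = f$beta, hr = f$hr, p = f$p,
               converged = f$converged, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

check_clinical <- function(clinical) {
  need <- c("sample", "inflammation", "fibrosis", "time", "event")
  if (!all(need %in% names(clinical))) {
    stop("clinical table must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(clinical$inflammation %in% 0:3) ||
      !all(clinical$fibrosis %in% 0:3)) {
    stop("grades must be integers in 0..3")
  }
  if (any(clinical$time <= 0)) stop("survival times must be positive")
  if (!all(clinical$event %in% c(0, 1))) stop("event must be 0/1")
  invisible(clinical)
}

#' Single-sample gene-set enrichment scores
#'
#' Per-sample rank-based enrichment of each gene set: genes are ordered by
#' expression (descending) and the score is the running difference between
#' the weighted in-set empirical distribution (weight of the gene at
#' descending position j is `(n - j + 1)^alpha_weight`, so highly expressed
#' genes count more) and the unweighted out-of-set distribution, summed
#' over all positions. Raw scores are normalized by their global range
#' across the whole matrix. Sets mapping fewer than `min_genes` genes are
#' dropped with a warning.
#'
#' @param expr Numeric genes x samples matrix.
#' @param sets Named list of gene-id vectors (e.g. cell-type signatures
#'   from [read_gmt()]).
#' @param alpha_weight Rank-weighting exponent (default 0.25).
#' @param min_genes Minimum mapped genes per set (default 3).
#' @param normalize Divide by the global max - min of the raw scores.
#' @return Numeric samples x sets matrix of enrichment scores; the raw
#'   (unnormalized) scores are kept in the `"raw"` attribute.
#' @export
ssgsea_scores <- function(expr, sets, alpha_weight = 0.25, min_genes = 3L,
                          normalize = TRUE) {
  expr <- as_expression_matrix(expr)
  if (!length(sets)) stop("empty gene-set collection")
  universe <- rownames(expr)
  mapped <- lapply(sets, function(s) unique(s[s %in% universe]))
  keep <- vapply(mapped, length, integer(1)) >= min_genes
  if (!all(keep)) {
    warning(sum(!keep), " gene set(s) dropped with fewer than ", min_genes,
            " genes in the matrix")
  }
  mapped <- mapped[keep]
  if (!length(mapped)) stop("no gene set maps enough genes")
  n <- length(universe)
  scores <- matrix(NA_real_, ncol(expr), length(mapped),
                   dimnames = list(colnames(expr), names(mapped)))
  in_set <- matrix(FALSE, n, length(mapped))
  for (k in seq_along(mapped)) in_set[match(mapped[[k]], universe), k] <- TRUE
  pos_weight <- (n - seq_len(n) + 1)^alpha_weight
  for (s in seq_len(ncol(expr))) {
    ord <- order(expr[, s], decreasing = TRUE)
    w <- pos_weight
    for (k in seq_along(mapped)) {
      ins <- in_set[ord, k]
      cdf_in <- cumsum(w * ins) / sum(w * ins)
      cdf_out <- cumsum(!ins) / (n - sum(ins))
      scores[s, k] <- sum(cdf_in - cdf_out)
    }
  }
  raw <- scores
  if (normalize) scores <- scores / (max(raw) - min(raw))
  attr(scores, "raw") <- raw
  scores
}

#' Correlate per-sample regulator activity with cell-infiltration scores
#'
#' Pearson correlation of each regulator's per-sample activity (see
#' [sample_activity()]) against each cell-type score column.
#'
#' @param activity Regulators x samples activity matrix.
#' @param scores Samples x cell-types score matrix from [ssgsea_scores()].
#' @return Data.frame with columns `tf`, `cell_type`, `r`, `p`, `n`.
#' @export
activity_cell_correlation <- function(activity, scores) {
  shared <- intersect(colnames(activity), rownames(scores))
  if (length(shared) < 3L) stop("fewer than 3 shared samples")
  rows <- list()
  for (tf in rownames(activity)) {
    for (ct in colnames(scores)) {
      a <- pearson_assoc(activity[tf, shared], scores[shared, ct])
      rows[[length(rows) + 1L]] <- data.frame(tf = tf, cell_type = ct,
                                              r = a$r, p = a$p, n = a$n,
                                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
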