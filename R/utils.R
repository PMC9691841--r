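# Shared validation helpers.

# Coerce to a numeric genes x samples matrix with unique dimnames and no
# missing values. Accepts a data.frame whose columns are samples.
as_expression_matrix <- function(expr) {
  if (is.data.frame(expr)) expr <- as.matrix(expr)
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("expression must be a numeric genes x samples matrix")
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression matrix needs gene row names and sample column names")
  }
  if (anyDuplicated(rownames(expr))) stop("duplicate gene ids in expression")
  if (anyDuplicated(colnames(expr))) stop("duplicate sample ids in expression")
  if (anyNA(expr)) stop("expression matrix contains missing values")
  expr
}

# Remove zero-variance genes (MI and signatures are undefined for them),
# reporting how many were dropped.
drop_constant_genes <- function(expr, quiet = FALSE) {
  keep <- matrixStats_row_var(expr) > 0
  if (!all(keep) && !quiet) {
    message(sum(!keep), " constant-expression gene(s) dropped")
  }
  expr[keep, , drop = FALSE]
}

# Row variances without the matrixStats dependency.
matrixStats_row_var <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  (rowSums(m * m) - n * mu * mu) / (n - 1)
}

# Deterministic stage seeds derived from one top-level seed; kept below
# 2^31 so they remain valid R integers.
derive_seed <- function(seed, stage) {
  (as.numeric(seed) * 1000003 + stage * 7919) %% 2147483647
}

check_labels <- function(labels, samples) {
  if (is.null(names(labels))) {
    if (length(labels) != length(samples)) {
      stop("labels must be named by sample or match the sample count")
    }
    names(labels) <- samples
  }
  missing <- setdiff(samples, names(labels))
  if (length(missing)) {
    stop("samples without a condition label: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  labels <- labels[samples]
  bad <- setdiff(unique(labels), c("case", "control"))
  if (length(bad)) {
    stop("condition labels must be 'case' or 'control'; found: ",
         paste(bad, collapse = ", "))
  }
  labels
}
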