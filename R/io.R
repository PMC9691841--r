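# Readers and writers for the plain-text formats the pipeline exchanges:
# expression/label/clinical TSV, regulator lists, GMT gene sets, edge
# lists and regulons. All writers round-trip with their readers.

#' Read a gene-by-sample expression matrix from TSV
#'
#' First column gene id, remaining columns one per sample with a header of
#' sample ids. Duplicate gene ids are collapsed by their mean with a
#' message.
#'
#' @param path TSV file path.
#' @return Numeric genes x samples matrix.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression file needs a gene column and at ",
                          "least one sample column: ", path)
  genes <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("missing values in expression file: ", path)
  if (anyDuplicated(genes)) {
    message(sum(duplicated(genes)), " duplicate gene row(s) collapsed ",
            "by mean")
    counts <- table(genes)
    m <- rowsum(m, genes)               # sums, ordered by gene name
    m <- m / as.vector(counts[rownames(m)])
  } else {
    rownames(m) <- genes
  }
  as_expression_matrix(m)
}

#' Write an expression matrix as TSV
#' @param expr Numeric genes x samples matrix.
#' @param path Output file.
#' @export
write_expression <- function(expr, path) {
  expr <- as_expression_matrix(expr)
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write per-sample condition labels (two-column TSV)
#' @param path TSV with columns `sample`, `condition`.
#' @return Named character vector of `"case"`/`"control"`.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% names(df))) {
    stop("labels file needs columns 'sample' and 'condition': ", path)
  }
  stats::setNames(df$condition, df$sample)
}

#' @rdname read_labels
#' @param labels Named condition vector.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(sample = names(labels),
                                condition = unname(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a clinical table
#'
#' TSV with columns `sample`, `inflammation`, `fibrosis` (integer grades
#' 0-3), `time` (months, > 0) and `event` (1 = transplant/death,
#' 0 = censored). Malformed values are rejected with the offending rows
#' named.
#'
#' @param path TSV file path.
#' @return Validated data.frame.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "inflammation", "fibrosis", "time", "event")
  if (!all(need %in% names(df))) {
    stop("clinical file needs columns ", paste(need, collapse = ", "),
         ": ", path)
  }
  bad <- which(!(df$inflammation %in% 0:3) | !(df$fibrosis %in% 0:3) |
                 df$time <= 0 | !(df$event %in% c(0, 1)))
  if (length(bad)) {
    stop("malformed clinical rows (file line numbers): ",
         paste(utils::head(bad + 1L, 5), collapse = ", "))
  }
  check_clinical(df)
}

#' @rdname read_clinical
#' @param clinical Clinical data.frame.
#' @export
write_clinical <- function(clinical, path) {
  check_clinical(clinical)
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' Standard tab-separated GMT: set name, description, then one gene per
#' field. Genes are deduplicated within each set.
#'
#' @param path GMT file path.
#' @return Named list of gene-id vectors; descriptions in the
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, integer(1)) < 3L)
  if (length(short)) {
    stop("GMT lines with fewer than 3 fields: ",
         paste(utils::head(short, 5), collapse = ", "))
  }
  sets <- lapply(parts, function(f) unique(f[-c(1L, 2L)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stop("duplicate set names in ", path)
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[[`, character(1), 2L), names(sets))
  sets
}

#' @rdname read_gmt
#' @param sets Named list of gene-id vectors.
#' @param descriptions Optional per-set description strings.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("na", length(sets)), names(sets))
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a regulator list (one gene symbol per line)
#' @param path Text file path.
#' @return Character vector.
#' @export
read_regulators <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x)])
}

#' Read / write an edge list (4-column TSV: tf, target, mi, p)
#' @param path TSV file path.
#' @return An `edge_list`.
#' @export
read_edges <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("tf", "target", "mi", "p")
  if (!all(need %in% names(df))) {
    stop("edge file needs columns ", paste(need, collapse = ", "))
  }
  new_edge_list(df[, need], unique(df$tf))
}

#' @rdname read_edges
#' @param edges An `edge_list`.
#' @export
write_edges <- function(edges, path) {
  utils::write.table(as.data.frame(edges), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write regulons (TSV: tf, target, mode, likelihood)
#' @param path TSV file path.
#' @return A `regulon_set`.
#' @export
read_regulons <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("tf", "target", "mode", "likelihood")
  if (!all(need %in% names(df))) {
    stop("regulon file needs columns ", paste(need, collapse = ", "))
  }
  out <- split(df[, c("target", "mode", "likelihood")], df$tf)
  out <- lapply(out, function(d) { rownames(d) <- NULL; d })
  structure(out, class = "regulon_set")
}

#' @rdname read_regulons
#' @param regulons A `regulon_set`.
#' @export
write_regulons <- function(regulons, path) {
  df <- do.call(rbind, lapply(names(regulons), function(tf) {
    data.frame(tf = tf, regulons[[tf]], stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a whole synthetic cohort to a directory
#'
#' Emits `expression.tsv`, `labels.tsv`, `clinical.tsv`,
#' `cell_signatures.gmt` and `truth.json` (ground-truth regulons and
#' planted TF sets), all round-tripping with the package readers.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_labels(cohort$labels, file.path(dir, "labels.tsv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_gmt(cohort$cell_signatures, file.path(dir, "cell_signatures.gmt"))
  truth <- cohort$truth
  jsonlite::write_json(
    list(regulators = truth$regulators,
         activated = truth$activated,
         repressed = truth$repressed,
         driver = cohort$driver,
         linked_cell = cohort$linked_cell,
         regulons = truth$regulons,
         seed = cohort$seed),
    file.path(dir, "truth.json"))
  invisible(dir)
}
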