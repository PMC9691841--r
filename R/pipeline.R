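#' Read and validate a pipeline run configuration
#'
#' The config is a YAML file (or an equivalent R list) with a `cohorts`
#' list (each entry: `name`, `expression`, optional `labels`, optional
#' `clinical`), a `regulators` path, an optional `cell_signatures` GMT, an
#' optional `pathways` GMT for over-representation analysis, a `seed`, an
#' `output_dir` and a `thresholds` block (`p_threshold`, `dpi_tolerance`,
#' `min_regulon`, `n_perm`, `mi_null_perm`, `alpha`, `min_targets`).
#' All referenced paths must exist at validation time.
#'
#' @param config YAML path or list.
#' @return Validated config list with thresholds defaulted.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!length(config$cohorts)) stop("config needs at least one cohort")
  if (is.null(config$regulators)) stop("config needs a regulators path")
  if (is.null(config$output_dir)) stop("config needs an output_dir")
  if (is.null(config$seed)) config$seed <- 1L
  th <- config$thresholds
  defaults <- list(p_threshold = 1e-8, dpi_tolerance = 0.1,
                   min_regulon = 25L, n_perm = 1000L, mi_null_perm = 1000L,
                   alpha = 0.05, min_targets = 10L)
  for (nm in names(defaults)) if (is.null(th[[nm]])) th[[nm]] <- defaults[[nm]]
  config$thresholds <- th
  nm <- vapply(config$cohorts, function(co)
    if (is.null(co$name)) NA_character_ else co$name, character(1))
  if (anyNA(nm) || anyDuplicated(nm)) {
    stop("every cohort needs a unique 'name'")
  }
  paths <- c(config$regulators, config$cell_signatures, config$pathways,
             unlist(lapply(config$cohorts, function(co)
               c(co$expression, co$labels, co$clinical))))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("config references missing file(s): ",
         paste(missing, collapse = ", "))
  }
  n_labeled <- sum(vapply(config$cohorts,
                          function(co) !is.null(co$labels), logical(1)))
  if (isTRUE(config$consensus) && n_labeled < 2L) {
    stop("consensus requires at least 2 cohorts with case/control labels")
  }
  config
}

#' Run the full master-regulator pipeline
#'
#' Executes the study flow on every configured cohort: MI network
#' reconstruction with DPI trimming and regulon assembly, protein-activity
#' inference with the permutation null for cohorts that have both cases
#' and controls, consensus master-regulator intersection when at least two
#' such cohorts exist, then clinical grade/survival associations,
#' cell-infiltration correlations and target-set over-representation
#' analysis where the respective inputs are configured. Cohorts without
#' condition labels (or without controls) take a clinical-only role. All
#' stage outputs are plain TSV/JSON with stable names under `output_dir`,
#' and a reproducibility manifest (`manifest.json`, with per-file MD5
#' checksums and the per-stage analytic decisions) is written last, also
#' on partial failure. Every random draw derives deterministically from
#' the single top-level seed.
#'
#' @param config YAML path or config list (see [read_run_config()]).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  config <- read_run_config(config)
  th <- config$thresholds
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = as.character(utils::packageVersion("mrnet")),
    seed = config$seed,
    config = config,
    decisions = list(
      signature_statistic = "welch_t_to_z",
      mi_estimator = "gaussian_kernel_copula",
      mi_null = "permutation_with_exponential_tail_extrapolation",
      dpi = "single_pass_original_mi_multiplicative_tolerance_ties_keep",
      regulon_mode = "spearman_sign",
      selection = "bh_adjusted_p",
      per_sample_activity = "one_vs_rest_z_area_nes"
    ),
    stages = list())
  files <- character()
  note <- function(stage, status, detail = "") {
    manifest$stages[[stage]] <<- list(status = status, detail = detail)
    message(sprintf("[%s] %s %s", stage, status, detail))
  }
  finish <- function() {
    manifest$checksums <-
      as.list(tools::md5sum(files[file.exists(files)]))
    names(manifest$checksums) <- basename(names(manifest$checksums))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
  }
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <<- c(files, path)
    path
  }

  regulators <- read_regulators(config$regulators)
  cell_sets <- if (!is.null(config$cell_signatures)) {
    read_gmt(config$cell_signatures)
  }
  activity_tables <- list()
  cohort_regulons <- list()
  cohort_data <- list()

  for (i in seq_along(config$cohorts)) {
    co <- config$cohorts[[i]]
    expr <- read_expression(co$expression)
    labels <- if (!is.null(co$labels)) read_labels(co$labels)
    clinical <- if (!is.null(co$clinical)) read_clinical(co$clinical)
    if (!is.null(labels)) labels <- check_labels(labels, colnames(expr))
    if (!is.null(clinical)) {
      absent <- setdiff(clinical$sample, colnames(expr))
      if (length(absent)) {
        stop("clinical sample(s) absent from expression in cohort '",
             co$name, "': ", paste(utils::head(absent, 5), collapse = ", "))
      }
    }
    cohort_data[[co$name]] <- list(expr = expr, labels = labels,
                                   clinical = clinical)
    has_groups <- !is.null(labels) &&
      sum(labels == "case") >= 2L && sum(labels == "control") >= 2L
    if (!has_groups) {
      note(paste0("network:", co$name), "skipped",
           "clinical-only cohort (no case/control groups)")
      next
    }
    stage <- paste0("network:", co$name)
    res <- tryCatch({
      expr_nc <- drop_constant_genes(expr)
      null <- fit_mi_null(expr_nc, n_perm = th$mi_null_perm,
                          seed = derive_seed(config$seed, 10 + i))
      edges <- build_edge_list(expr_nc, regulators,
                               p_threshold = th$p_threshold, null = null)
      edges <- apply_dpi(edges, tolerance = th$dpi_tolerance)
      regulons <- edges_to_regulons(edges, expr_nc,
                                    min_size = th$min_regulon)
      emit(edges, paste0("network_", co$name, ".tsv"))
      write_regulons(regulons,
                     file.path(out_dir, paste0("regulons_", co$name,
                                               ".tsv")))
      files <- c(files, file.path(out_dir, paste0("regulons_", co$name,
                                                  ".tsv")))
      note(stage, "ok", sprintf("%d edges, %d regulons", nrow(edges),
                                length(regulons)))
      list(regulons = regulons, expr = expr_nc)
    }, error = function(e) { note(stage, "failed", conditionMessage(e)); NULL })
    if (is.null(res)) next
    cohort_regulons[[co$name]] <- res$regulons

    stage <- paste0("activity:", co$name)
    act <- tryCatch({
      at <- permutation_pvalues(res$expr, labels, res$regulons,
                                n_perm = th$n_perm,
                                min_targets = th$min_targets,
                                seed = derive_seed(config$seed, 20 + i))
      emit(at, paste0("activity_", co$name, ".tsv"))
      note(stage, "ok", sprintf("%d TFs scored", nrow(at)))
      at
    }, error = function(e) { note(stage, "failed", conditionMessage(e)); NULL })
    if (!is.null(act)) activity_tables[[co$name]] <- act
  }

  consensus <- NULL
  if (length(activity_tables) >= 2L) {
    consensus <- tryCatch({
      cm <- intersect_mrs(activity_tables, alpha = th$alpha)
      emit(cm, "consensus.tsv")
      jsonlite::write_json(as.data.frame(cm),
                           file.path(out_dir, "consensus.json"),
                           auto_unbox = TRUE, digits = NA)
      files <- c(files, file.path(out_dir, "consensus.json"))
      note("consensus", "ok", sprintf("%d common MRs", nrow(cm)))
      cm
    }, error = function(e) { note("consensus", "failed",
                                  conditionMessage(e)); NULL })
  } else {
    note("consensus", "skipped", "fewer than 2 activity cohorts")
  }
  mr_tfs <- if (!is.null(consensus) && nrow(consensus)) consensus$tf
            else regulators

  for (nm in names(cohort_data)) {
    cd <- cohort_data[[nm]]
    if (!is.null(cd$clinical)) {
      tryCatch({
        ga <- grade_associations(cd$expr, cd$clinical,
                                 intersect(mr_tfs, rownames(cd$expr)))
        emit(ga, paste0("grades_", nm, ".tsv"))
        sa <- survival_associations(cd$expr, cd$clinical,
                                    intersect(mr_tfs, rownames(cd$expr)))
        emit(sa, paste0("survival_", nm, ".tsv"))
        note(paste0("clinical:", nm), "ok",
             sprintf("%d TFs tested", length(unique(ga$tf))))
      }, error = function(e) note(paste0("clinical:", nm), "failed",
                                  conditionMessage(e)))
    }
    if (!is.null(cell_sets) && nm %in% names(cohort_regulons)) {
      tryCatch({
        regs <- cohort_regulons[[nm]]
        regs_mr <- regs[intersect(names(regs), mr_tfs)]
        if (!length(regs_mr)) stop("no consensus MR has a regulon here")
        expr_nc <- drop_constant_genes(cd$expr, quiet = TRUE)
        scores <- ssgsea_scores(expr_nc, cell_sets)
        act <- sample_activity(expr_nc, regs_mr,
                               min_targets = th$min_targets)
        cc <- activity_cell_correlation(act, scores)
        emit(cc, paste0("infiltration_", nm, ".tsv"))
        note(paste0("infiltration:", nm), "ok",
             sprintf("%d TF x cell pairs", nrow(cc)))
      }, error = function(e) note(paste0("infiltration:", nm), "failed",
                                  conditionMessage(e)))
    }
  }

  if (!is.null(config$pathways) && length(cohort_regulons)) {
    tryCatch({
      pathways <- read_gmt(config$pathways)
      universe <- unique(unlist(lapply(cohort_data, function(cd)
        rownames(cd$expr))))
      for (dir_label in c("activated", "repressed")) {
        tfs_dir <- if (!is.null(consensus)) {
          consensus$tf[consensus$direction == dir_label]
        } else character()
        if (!length(tfs_dir)) next
        targets <- unique(unlist(lapply(cohort_regulons, function(regs)
          unlist(lapply(regs[intersect(names(regs), tfs_dir)],
                        `[[`, "target")))))
        if (!length(targets)) next
        ora <- ora_test(targets, pathways, universe)
        emit(ora, paste0("ora_", dir_label, ".tsv"))
      }
      note("enrichment", "ok", "")
    }, error = function(e) note("enrichment", "failed",
                                conditionMessage(e)))
  }
  finish()
}
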