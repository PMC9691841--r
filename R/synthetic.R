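#' Generate a ground-truth transcriptional network
#'
#' Samples a planted regulatory network: `n_tf` transcription factors, each
#' with a regulon of targets drawn without replacement from the non-TF
#' genes (regulons of different TFs may overlap), a signed mode of action
#' per target and a regulatory strength. A configurable fraction of TFs is
#' planted as activated / repressed in cases; downstream recovery is judged
#' against these sets.
#'
#' @param n_tf Number of transcription factors (>= 2).
#' @param n_genes Total gene universe size, TFs included.
#' @param regulon_size Length-2 integer range of regulon sizes.
#' @param frac_activated,frac_repressed Fractions of TFs planted as
#'   activated / repressed in cases (`frac_activated + frac_repressed <= 1`);
#'   counts are the rounded fractions of `n_tf`.
#' @param strength_range Range of per-target regulatory strengths in (0, 1].
#' @param seed Integer seed; the network is deterministic given it.
#' @return A `true_network` with fields `regulators`, `genes`, `regulons`
#'   (named list of data.frames `target`/`mode`/`strength`), `activated`,
#'   `repressed`.
#' @examples
#' net <- generate_network(n_tf = 4, n_genes = 50, regulon_size = c(5, 10),
#'                         frac_activated = 0.5, frac_repressed = 0.25,
#'                         seed = 1)
#' net
#' @export
generate_network <- function(n_tf, n_genes, regulon_size = c(25L, 100L),
                             frac_activated = 0, frac_repressed = 0,
                             strength_range = c(0.5, 1), seed = 1L) {
  if (n_tf < 2L) stop("n_tf must be >= 2")
  regulon_size <- as.integer(round(regulon_size))
  if (length(regulon_size) != 2L || regulon_size[1] < 1L ||
      regulon_size[2] < regulon_size[1]) {
    stop("regulon_size must be an increasing [min, max] pair with min >= 1")
  }
  if (frac_activated < 0 || frac_repressed < 0 ||
      frac_activated + frac_repressed > 1) {
    stop("frac_activated + frac_repressed must lie in [0, 1]")
  }
  if (n_genes - n_tf < regulon_size[2]) {
    stop("n_genes - n_tf (", n_genes - n_tf,
         ") is smaller than the maximum regulon size (", regulon_size[2],
         "): cannot fill a regulon")
  }
  tfs <- sprintf("TF%02d", seq_len(n_tf))
  targets_pool <- sprintf("G%04d", seq_len(n_genes - n_tf))
  withr_seed(seed, {
    regulons <- lapply(tfs, function(tf) {
      sizes <- seq(regulon_size[1], regulon_size[2])
      size <- sizes[sample.int(length(sizes), 1L)]
      data.frame(target = sample(targets_pool, size),
                 mode = sample(c(-1, 1), size, replace = TRUE),
                 strength = stats::runif(size, strength_range[1],
                                         strength_range[2]),
                 stringsAsFactors = FALSE)
    })
    names(regulons) <- tfs
    n_act <- round(frac_activated * n_tf)
    n_rep <- round(frac_repressed * n_tf)
    planted <- sample(tfs, n_act + n_rep)
  })
  structure(list(regulators = tfs,
                 genes = c(tfs, targets_pool),
                 regulons = regulons,
                 activated = planted[seq_len(n_act)],
                 repressed = planted[n_act + seq_len(n_rep)],
                 seed = seed),
            class = "true_network")
}

#' @export
print.true_network <- function(x, ...) {
  sizes <- vapply(x$regulons, nrow, integer(1))
  cat(sprintf("Planted network: %d TFs over %d genes\n",
              length(x$regulators), length(x$genes)))
  cat(sprintf("  regulon sizes %d-%d; %d activated, %d repressed TF(s)\n",
              min(sizes), max(sizes), length(x$activated),
              length(x$repressed)))
  invisible(x)
}

#' Simulate a case/control cohort from a planted network
#'
#' Draws per-sample latent TF activities (standard normal, shifted by
#' `+effect_size` for planted-activated and `-effect_size` for
#' planted-repressed TFs in cases), then generates expression: a TF's own
#' transcript tracks its activity, and each target is the
#' strength-and-mode-weighted sum of its regulators' activities, all plus
#' independent Gaussian noise. Cases additionally receive a clinical table
#' (ordinal inflammation and fibrosis grades whose Gaussian latent scale is
#' `grade_rho`-correlated with the driver TF's activity, and exponential
#' proportional-hazards survival with log-hazard `surv_beta` per activity
#' unit, administratively censored), and all samples receive cell-type
#' signature genes tracking latent abundances, one abundance
#' `cell_rho`-linked to the driver.
#'
#' @param truth A `true_network` from [generate_network()].
#' @param n_case,n_control Sample counts (each >= 2).
#' @param effect_size Standardized case shift of planted TF activities.
#' @param noise_sd Standard deviation of the additive expression noise.
#' @param driver Regulator driving clinical variables; defaults to the
#'   first planted-activated TF (or the first regulator when none).
#' @param grade_rho Latent correlation between driver activity and the
#'   grade scales.
#' @param surv_beta Log hazard ratio per unit of driver activity.
#' @param surv_scale Baseline survival scale in months.
#' @param censor_quantile Administrative censoring horizon expressed as a
#'   quantile of the drawn event times (default 0.7, i.e. ~30% censored).
#' @param n_cell_types,sig_genes_per_type Cell-type signature layout.
#' @param cell_rho Correlation linking the first cell type's abundance to
#'   the driver activity; other abundances are independent.
#' @param count_mode If `TRUE`, expression is re-emitted as
#'   `log1p(Poisson)` counts of the exponentiated values (RNA-seq-like)
#'   instead of continuous log-scale values.
#' @param seed Integer seed; the cohort is deterministic given it.
#' @return A `synthetic_cohort` with `expression`, `labels`, `clinical`,
#'   `cell_signatures`, `true_abundances`, `latent_activity`, `driver`,
#'   `linked_cell` and the generating `truth`.
#' @export
generate_cohort <- function(truth, n_case, n_control, effect_size = 2,
                            noise_sd = 0.5, driver = NULL, grade_rho = 0.6,
                            surv_beta = 0.7, surv_scale = 36,
                            censor_quantile = 0.7, n_cell_types = 4L,
                            sig_genes_per_type = 30L, cell_rho = 0.6,
                            count_mode = FALSE, seed = 1L) {
  stopifnot(inherits(truth, "true_network"))
  if (n_case < 2L || n_control < 2L) stop("need >= 2 samples per group")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (is.null(driver)) {
    driver <- if (length(truth$activated)) truth$activated[1]
              else truth$regulators[1]
  }
  if (!driver %in% truth$regulators) {
    stop("driver TF '", driver, "' is not a regulator of the network")
  }
  n <- n_case + n_control
  samples <- c(sprintf("case_%03d", seq_len(n_case)),
               sprintf("ctrl_%03d", seq_len(n_control)))
  labels <- stats::setNames(rep(c("case", "control"), c(n_case, n_control)),
                            samples)
  tfs <- truth$regulators
  is_case <- labels == "case"

  withr_seed(seed, {
    act <- matrix(stats::rnorm(length(tfs) * n), length(tfs), n,
                  dimnames = list(tfs, samples))
    act[truth$activated, is_case] <- act[truth$activated, is_case] +
      effect_size
    act[truth$repressed, is_case] <- act[truth$repressed, is_case] -
      effect_size

    genes <- truth$genes
    expr <- matrix(0, length(genes), n, dimnames = list(genes, samples))
    expr[tfs, ] <- act
    for (tf in tfs) {
      reg <- truth$regulons[[tf]]
      expr[reg$target, ] <- expr[reg$target, , drop = FALSE] +
        outer(reg$strength * reg$mode, act[tf, ])
    }

    # latent cell-type abundances; type 1 tracks the driver
    abund <- matrix(stats::rnorm(n * n_cell_types), n, n_cell_types,
                    dimnames = list(samples,
                                    sprintf("celltype%d",
                                            seq_len(n_cell_types))))
    zdrv <- as.numeric(scale(act[driver, ]))
    abund[, 1] <- cell_rho * zdrv + sqrt(1 - cell_rho^2) * abund[, 1]
    sig_sets <- list()
    sig_expr <- matrix(0, n_cell_types * sig_genes_per_type, n)
    sig_names <- character(nrow(sig_expr))
    for (k in seq_len(n_cell_types)) {
      idx <- (k - 1L) * sig_genes_per_type + seq_len(sig_genes_per_type)
      sig_names[idx] <- sprintf("CT%d_S%03d", k, seq_len(sig_genes_per_type))
      sig_expr[idx, ] <- matrix(rep(abund[, k], each = sig_genes_per_type),
                                sig_genes_per_type, n)
      sig_sets[[colnames(abund)[k]]] <- sig_names[idx]
    }
    rownames(sig_expr) <- sig_names
    expr <- rbind(expr, sig_expr)
    expr <- expr + matrix(stats::rnorm(length(expr), sd = noise_sd),
                          nrow(expr), ncol(expr))
    if (count_mode) {
      counts <- matrix(stats::rpois(length(expr), exp(expr) * 20),
                       nrow(expr), ncol(expr), dimnames = dimnames(expr))
      expr <- log1p(counts)
    }

    # clinical table for cases only
    a_case <- act[driver, is_case]
    za <- as.numeric(scale(a_case))
    cuts <- stats::qnorm(c(0.25, 0.5, 0.75))
    latent_grade <- function(z) {
      lat <- grade_rho * z + sqrt(1 - grade_rho^2) * stats::rnorm(length(z))
      findInterval(lat, cuts)
    }
    inflammation <- latent_grade(za)
    fibrosis <- latent_grade(za)
    t_event <- stats::rexp(n_case, rate = exp(surv_beta * a_case) /
                                       surv_scale)
    horizon <- stats::quantile(t_event, censor_quantile, names = FALSE)
    clinical <- data.frame(sample = samples[is_case],
                           inflammation = inflammation,
                           fibrosis = fibrosis,
                           time = pmin(t_event, horizon),
                           event = as.integer(t_event <= horizon),
                           stringsAsFactors = FALSE)
  })

  structure(list(expression = expr,
                 labels = labels,
                 clinical = clinical,
                 cell_signatures = sig_sets,
                 true_abundances = abund,
                 latent_activity = act,
                 truth = truth,
                 driver = driver,
                 linked_cell = colnames(abund)[1],
                 seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d genes x %d samples (%d case / %d control)\n",
              nrow(x$expression), ncol(x$expression),
              sum(x$labels == "case"), sum(x$labels == "control")))
  cat(sprintf("  driver TF: %s (linked cell type: %s)\n",
              x$driver, x$linked_cell))
  cat(sprintf("  clinical rows: %d; cell-type signatures: %d\n",
              nrow(x$clinical), length(x$cell_signatures)))
  invisible(x)
}

#' True regulons in the mode/likelihood form used by activity inference
#'
#' Convenience accessor mapping a planted network's regulons (signed mode,
#' strength) to the `regulon_set` layout expected by
#' [permutation_pvalues()], with strength as the confidence weight
#' normalized to max 1 per regulon.
#'
#' @param truth A `true_network`.
#' @return A `regulon_set`.
#' @export
true_regulons <- function(truth) {
  stopifnot(inherits(truth, "true_network"))
  out <- lapply(truth$regulons, function(reg) {
    data.frame(target = reg$target, mode = reg$mode,
               likelihood = reg$strength / max(reg$strength),
               stringsAsFactors = FALSE)
  })
  structure(out, class = "regulon_set")
}
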