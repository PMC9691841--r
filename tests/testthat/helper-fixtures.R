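# Small fixtures shared across test files; everything is generated in code
# under fixed seeds.

# a compact planted network + cohort pair for fast module tests
tiny_network <- function(seed = 42) {
  generate_network(n_tf = 6, n_genes = 120, regulon_size = c(10, 20),
                   frac_activated = 0.5, frac_repressed = 1 / 6,
                   seed = seed)
}

tiny_cohort <- function(net = tiny_network(), n_case = 30, n_control = 15,
                        effect_size = 2, seed = 7, ...) {
  generate_cohort(net, n_case = n_case, n_control = n_control,
                  effect_size = effect_size, noise_sd = 0.5,
                  n_cell_types = 2, sig_genes_per_type = 8, seed = seed,
                  ...)
}

# random edge list on `n_nodes` nodes, a subset of which are regulators
random_edge_list <- function(n_nodes, n_regs, p_edge = 0.3, seed = 1) {
  withr::with_seed(seed, {
    nodes <- sprintf("n%02d", seq_len(n_nodes))
    regs <- nodes[seq_len(n_regs)]
    pairs <- expand.grid(tf = regs, target = nodes,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$tf != pairs$target, ]
    # one row per unordered pair (regulator pairs would otherwise repeat)
    key <- apply(pairs, 1L, function(r) paste(sort(r), collapse = "|"))
    pairs <- pairs[!duplicated(key), ]
    keep <- runif(nrow(pairs)) < p_edge
    df <- data.frame(tf = pairs$tf[keep], target = pairs$target[keep],
                     mi = runif(sum(keep), 0.05, 1),
                     p = rep(1e-10, sum(keep)), stringsAsFactors = FALSE)
    mrnet:::new_edge_list(df, regs)
  })
}

# brute-force DPI: enumerate every (x, z, y) triple explicitly
dpi_oracle <- function(edges, tolerance) {
  regs <- attr(edges, "regulators")
  mi_of <- function(a, b) {
    hit <- (edges$tf == a & edges$target == b) |
           (edges$tf == b & edges$target == a)
    if (any(hit)) edges$mi[which(hit)[1]] else NA_real_
  }
  drop <- logical(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    x <- edges$tf[e]; y <- edges$target[e]
    for (z in setdiff(regs, c(x, y))) {
      m1 <- mi_of(x, z); m2 <- mi_of(z, y)
      if (!is.na(m1) && !is.na(m2) &&
          edges$mi[e] < (1 - tolerance) * min(m1, m2)) {
        drop[e] <- TRUE
        break
      }
    }
  }
  out <- edges[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

edge_keys <- function(edges) paste(edges$tf, edges$target)

true_edge_keys <- function(net) {
  unlist(lapply(names(net$regulons), function(tf) {
    paste(tf, net$regulons[[tf]]$target)
  }))
}

# pipeline run fixture: two case/control cohorts + one clinical-only
# cohort from a shared planted network, with desk-scale thresholds
pipeline_fixture <- function(root, seed = 1) {
  net <- tiny_network()
  dirs <- file.path(root, c("c1", "c2", "c3"))
  co1 <- tiny_cohort(net, n_case = 40, n_control = 20, seed = seed)
  co2 <- tiny_cohort(net, n_case = 40, n_control = 20, seed = seed + 1)
  co3 <- tiny_cohort(net, n_case = 40, n_control = 20, seed = seed + 2)
  write_cohort(co1, dirs[1])
  write_cohort(co2, dirs[2])
  write_cohort(co3, dirs[3])
  file.remove(file.path(dirs[3], "labels.tsv"))   # clinical-only role
  writeLines(net$regulators, file.path(root, "regulators.txt"))
  list(
    net = net,
    config = list(
      seed = 99,
      output_dir = file.path(root, "out"),
      regulators = file.path(root, "regulators.txt"),
      cell_signatures = file.path(dirs[1], "cell_signatures.gmt"),
      cohorts = list(
        list(name = "d1", expression = file.path(dirs[1], "expression.tsv"),
             labels = file.path(dirs[1], "labels.tsv"),
             clinical = file.path(dirs[1], "clinical.tsv")),
        list(name = "d2", expression = file.path(dirs[2], "expression.tsv"),
             labels = file.path(dirs[2], "labels.tsv")),
        list(name = "d3", expression = file.path(dirs[3], "expression.tsv"),
             clinical = file.path(dirs[3], "clinical.tsv"))),
      thresholds = list(p_threshold = 1e-3, min_regulon = 5L,
                        n_perm = 100L, mi_null_perm = 200L,
                        min_targets = 5L, alpha = 0.3)))
}
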