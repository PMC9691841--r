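make_labels <- function(n_case, n_control) {
  stats::setNames(rep(c("case", "control"), c(n_case, n_control)),
                  c(sprintf("case_%02d", seq_len(n_case)),
                    sprintf("ctrl_%02d", seq_len(n_control))))
}

swap_labels <- function(labels) {
  stats::setNames(ifelse(labels == "case", "control", "case"),
                  names(labels))
}

test_that("signatures have the right sign, zeros and antisymmetry", {
  set.seed(31)
  labels <- make_labels(10, 8)
  expr <- matrix(rnorm(20 * 18), 20, 18,
                 dimnames = list(sprintf("g%02d", 1:20), names(labels)))
  expr["g01", labels == "case"] <- expr["g01", labels == "case"] + 3
  # identical group means -> z = 0 (alternating -1/+1 in both groups)
  expr["g02", ] <- rep(c(-1, 1), 9)
  sig <- suppressMessages(compute_signature(expr, labels))
  expect_gt(sig["g01"], 2)
  expect_true(all(is.finite(sig)))
  expect_equal(unname(sig["g02"]), 0)
  # swapping labels flips every z exactly
  flipped <- suppressMessages(compute_signature(expr, swap_labels(labels)))
  expect_equal(unname(flipped), -unname(sig))
  expect_error(compute_signature(expr, labels[c(1, 11:18)]),
               "without a condition")
  one_case <- stats::setNames(rep(c("case", "control"), c(1, 17)),
                              colnames(expr))
  expect_error(compute_signature(expr, one_case), "at least 2")
})

test_that("planted activated TFs get positive signature z", {
  net <- tiny_network()
  co <- generate_cohort(net, 60, 10, effect_size = 2, noise_sd = 0.5,
                        seed = 33)
  sig <- suppressMessages(compute_signature(co$expression, co$labels))
  expect_true(all(sig[net$activated] > 0))
  expect_true(all(sig[net$repressed] < 0))
})

test_that("area NES is extremal, antisymmetric in mode and standardized", {
  set.seed(34)
  z <- structure(stats::setNames(rnorm(100), sprintf("g%03d", 1:100)),
                 class = "mr_signature")
  top <- names(sort(unclass(z), decreasing = TRUE))[1:10]
  reg_top <- data.frame(target = top, mode = 1, likelihood = 1)
  nes_top <- area_nes(z, reg_top)
  # no other regulon of size 10 with unit weights can beat the top-z set
  for (i in 1:20) {
    other <- data.frame(target = sample(names(z), 10), mode = 1,
                        likelihood = 1)
    expect_lte(area_nes(z, other), nes_top)
  }
  # flipping all modes negates exactly
  reg_neg <- reg_top; reg_neg$mode <- -1
  expect_equal(area_nes(z, reg_neg), -nes_top)
  # random regulons: mean ~0, variance ~1
  set.seed(35)
  zbig <- structure(stats::setNames(rnorm(2000), sprintf("G%04d", 1:2000)),
                    class = "mr_signature")
  draws <- replicate(2000, {
    reg <- data.frame(target = sample(names(zbig), 50),
                      mode = sample(c(-1, 1), 50, replace = TRUE),
                      likelihood = runif(50, 0.2, 1))
    area_nes(zbig, reg)
  })
  expect_lt(abs(mean(draws)), 0.05)
  expect_lt(abs(var(draws) - 1), 0.1)
  # unmapped targets are skipped; too few mapped is an error
  reg_bad <- data.frame(target = c(top[1:3], sprintf("nope%d", 1:7)),
                        mode = 1, likelihood = 1)
  expect_error(area_nes(z, reg_bad, min_targets = 10), "map")
  expect_equal(area_nes(z, reg_bad, min_targets = 3),
               area_nes(z, reg_top[1:3, ], min_targets = 3))
})

test_that("NES percentile agrees with exhaustive enumeration at toy scale", {
  set.seed(36)
  z <- structure(stats::setNames(rnorm(20), sprintf("g%02d", 1:20)),
                 class = "mr_signature")
  k <- 3
  all_sets <- combn(names(z), k)
  all_nes <- apply(all_sets, 2L, function(s)
    area_nes(z, data.frame(target = s, mode = 1, likelihood = 1),
             min_targets = 1))
  # every same-size regulon: exhaustive percentile vs the analytic normal
  exhaustive_pct <- 100 * rank(all_nes) / length(all_nes)
  analytic_pct <- 100 * pnorm(all_nes)
  expect_lt(max(abs(exhaustive_pct - analytic_pct)), 5)
})

test_that("permutation p-values recover planted TFs and flip under swap", {
  net <- tiny_network()
  co <- tiny_cohort(net)
  regs <- true_regulons(net)
  at <- suppressMessages(permutation_pvalues(co$expression, co$labels, regs,
                                             n_perm = 100, seed = 37))
  expect_s3_class(at, "activity_table")
  expect_true(all(at$p > 0 & at$p <= 1))
  expect_true(all(at$p_adj >= at$p))
  expect_identical(at$direction, ifelse(at$nes > 0, "activated",
                                        "repressed"))
  # planted TFs separate cleanly from unperturbed ones: correct signs and
  # uniformly smaller permutation p
  planted <- c(net$activated, net$repressed)
  for (tf in net$activated) expect_gt(at$nes[at$tf == tf], 0)
  for (tf in net$repressed) expect_lt(at$nes[at$tf == tf], 0)
  expect_lt(max(at$p[at$tf %in% planted]),
            min(at$p[!at$tf %in% planted]))
  # label swap: every NES negated, p identical
  at_sw <- suppressMessages(permutation_pvalues(
    co$expression, swap_labels(co$labels), regs, n_perm = 100, seed = 37))
  expect_equal(at_sw$nes, -at$nes)
  expect_equal(at_sw$p, at$p)
})

test_that("NES magnitude grows with planted effect size", {
  net <- tiny_network()
  regs <- true_regulons(net)
  planted <- c(net$activated, net$repressed)
  med_nes <- vapply(c(0, 0.5, 1, 2), function(es) {
    co <- tiny_cohort(net, effect_size = es, seed = 40)
    sig <- suppressMessages(compute_signature(co$expression, co$labels))
    median(abs(vapply(planted, function(tf)
      area_nes(sig, regs[[tf]]), numeric(1))))
  }, numeric(1))
  expect_true(all(diff(med_nes) >= 0))
})

test_that("MR selection and consensus behave at the boundaries", {
  tab <- structure(
    data.frame(tf = c("a", "b", "c"), nes = c(3, -2, 1),
               p = c(0.001, 0.002, 0.5),
               p_adj = c(0.003, 0.003, 0.5),
               direction = c("activated", "repressed", "activated"),
               stringsAsFactors = FALSE),
    class = c("activity_table", "data.frame"))
  expect_equal(nrow(select_mrs(tab, alpha = 1)), 3)
  all_null <- tab; all_null$p_adj <- 1
  expect_equal(nrow(select_mrs(all_null, 0.05)), 0)
  sel <- select_mrs(tab, 0.05)
  expect_equal(sel$tf, c("a", "b"))                  # sorted by |NES|

  # duplicated table: consensus equals its significant set
  cm <- intersect_mrs(list(tab, tab), alpha = 0.05)
  expect_setequal(cm$tf, c("a", "b"))
  expect_equal(cm$direction[cm$tf == "a"], "activated")
  # disjoint significant sets: empty consensus
  other <- tab; other$p_adj <- c(0.5, 0.5, 0.01)
  expect_equal(nrow(intersect_mrs(list(tab, other), 0.05)), 0)
  # discordant signs excluded with a message
  flip <- tab; flip$nes <- c(-3, -2, 1)
  expect_message(cm2 <- intersect_mrs(list(tab, flip), 0.05), "discordant")
  expect_equal(cm2$tf, "b")
  expect_error(intersect_mrs(list(tab)), "at least 2")
})

test_that("two independent cohorts recover the planted consensus", {
  # reconstructed regulons (strong-MI targets with confidence weights) are
  # the intended input; true-strength regulons are strictly weaker here
  net <- generate_network(30, 1000, c(25, 100), 14 / 30, 8 / 30, seed = 11)
  run_cohort <- function(seed) {
    co <- generate_cohort(net, 100, 100, effect_size = 2, noise_sd = 0.5,
                          seed = seed)
    null <- fit_mi_null(co$expression, n_perm = 1000, seed = seed + 1)
    edges <- apply_dpi(build_edge_list(co$expression, net$regulators,
                                       1e-8, null, corrected = FALSE), 0.1)
    regs <- suppressMessages(edges_to_regulons(edges, co$expression,
                                               min_size = 10))
    suppressMessages(permutation_pvalues(co$expression, co$labels, regs,
                                         n_perm = 100, seed = seed + 2))
  }
  cm <- suppressMessages(intersect_mrs(list(run_cohort(51), run_cohort(58)),
                                       alpha = 0.05))
  planted <- c(net$activated, net$repressed)
  expect_gte(mean(planted %in% cm$tf), 0.9)
  hit <- intersect(planted, cm$tf)
  expect_identical(cm$direction[match(hit, cm$tf)],
                   ifelse(hit %in% net$activated, "activated", "repressed"))
  # false positives among unperturbed TFs stay controlled
  expect_lte(length(setdiff(cm$tf, planted)), 1)
})
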