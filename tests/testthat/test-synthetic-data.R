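test_that("generate_network honors sizes, fractions and determinism", {
  net <- generate_network(n_tf = 22, n_genes = 2000,
                          regulon_size = c(25, 100),
                          frac_activated = 14 / 22, frac_repressed = 8 / 22,
                          seed = 1)
  expect_length(net$activated, 14)
  expect_length(net$repressed, 8)
  expect_length(intersect(net$activated, net$repressed), 0)
  sizes <- vapply(net$regulons, nrow, integer(1))
  expect_true(all(sizes >= 25 & sizes <= 100))
  expect_true(all(unlist(lapply(net$regulons, `[[`, "target")) %in%
                    net$genes))
  # no TF targets itself and no target is drawn twice within a regulon
  for (tf in net$regulators) {
    expect_false(tf %in% net$regulons[[tf]]$target)
    expect_false(anyDuplicated(net$regulons[[tf]]$target) > 0)
  }
  expect_identical(net, generate_network(n_tf = 22, n_genes = 2000,
                                         regulon_size = c(25, 100),
                                         frac_activated = 14 / 22,
                                         frac_repressed = 8 / 22, seed = 1))

  minimal <- generate_network(n_tf = 2, n_genes = 10,
                              regulon_size = c(1, 1), seed = 7)
  expect_length(minimal$regulons, 2)
  expect_true(all(vapply(minimal$regulons, nrow, integer(1)) == 1))
  expect_length(minimal$activated, 0)

  expect_error(generate_network(n_tf = 5, n_genes = 20,
                                regulon_size = c(10, 18), seed = 1),
               "cannot fill")
  expect_error(generate_network(n_tf = 1, n_genes = 100, seed = 1))
  expect_error(generate_network(n_tf = 4, n_genes = 100,
                                frac_activated = 0.7, frac_repressed = 0.5,
                                seed = 1))
})

test_that("cohorts are deterministic and structurally valid", {
  net <- tiny_network()
  co <- tiny_cohort(net)
  co2 <- tiny_cohort(net)
  expect_identical(co, co2)
  expect_false(anyNA(co$expression))
  expect_setequal(co$clinical$sample,
                  names(co$labels)[co$labels == "case"])
  expect_true(all(co$clinical$time > 0))
  expect_true(all(co$clinical$inflammation %in% 0:3))
  expect_true(all(co$clinical$fibrosis %in% 0:3))
  expect_true(all(co$clinical$event %in% 0:1))
  # planted targets and signature genes are all in the matrix
  expect_true(all(net$genes %in% rownames(co$expression)))
  expect_true(all(unlist(co$cell_signatures) %in% rownames(co$expression)))
  expect_error(generate_cohort(net, 10, 10, driver = "NOPE", seed = 1),
               "driver")
})

test_that("planted activated TFs shift case expression upward", {
  net <- tiny_network()
  co <- generate_cohort(net, n_case = 60, n_control = 10, effect_size = 2,
                        noise_sd = 0.5, seed = 3)
  is_case <- co$labels == "case"
  for (tf in net$activated) {
    tt <- t.test(co$expression[tf, is_case], co$expression[tf, !is_case])
    expect_gt(tt$statistic, 0)
    expect_lt(tt$p.value, 0.01)
  }
  for (tf in net$repressed) {
    expect_lt(t.test(co$expression[tf, is_case],
                     co$expression[tf, !is_case])$statistic, 0)
  }
})

test_that("noiseless single-regulon limit reproduces TF activity", {
  net <- generate_network(n_tf = 2, n_genes = 30, regulon_size = c(5, 5),
                          strength_range = c(1, 1), seed = 2)
  net$regulons <- lapply(net$regulons, function(r) { r$mode <- 1; r })
  co <- generate_cohort(net, 20, 20, effect_size = 0, noise_sd = 1e-9,
                        seed = 4)
  tf <- net$regulators[1]
  for (tg in net$regulons[[tf]]$target) {
    # targets regulated only by this TF track its activity exactly
    if (tg %in% net$regulons[[net$regulators[2]]]$target) next
    expect_gt(cor(co$expression[tf, ], co$expression[tg, ]), 0.999)
  }
})

test_that("driver linkage reaches the configured latent correlation", {
  net <- tiny_network()
  co <- generate_cohort(net, n_case = 500, n_control = 10, grade_rho = 0.6,
                        effect_size = 1, seed = 9)
  a <- co$latent_activity[co$driver, co$clinical$sample]
  # the ordinal grade attenuates the latent correlation; compare on the
  # latent scale via the normal-scores transform of the grade
  r_fib <- cor(a, co$clinical$fibrosis)
  expect_gt(r_fib, 0.3)
  # latent scale itself: abundances of the linked cell type
  r_cell <- cor(co$latent_activity[co$driver, ],
                co$true_abundances[, co$linked_cell])
  expect_lt(abs(r_cell - 0.6), 0.1)
})

test_that("count mode emits non-negative log1p counts", {
  net <- tiny_network()
  co <- tiny_cohort(net, count_mode = TRUE)
  expect_true(all(co$expression >= 0))
  expect_true(all(co$expression == log1p(round(expm1(co$expression)))))
})

test_that("null cohorts give calibrated activity p-values", {
  net <- generate_network(10, 200, c(20, 40), 0, 0, seed = 5)
  regs <- true_regulons(net)
  pvals <- unlist(lapply(1:20, function(r) {
    co <- generate_cohort(net, 20, 20, effect_size = 0, noise_sd = 0.5,
                          n_cell_types = 2, sig_genes_per_type = 5,
                          seed = 1000 + r)
    suppressMessages(permutation_pvalues(co$expression, co$labels, regs,
                                         n_perm = 100,
                                         seed = 2000 + r))$p
  }))
  # binomial 99% band around 0.05 for the observed number of tests
  half <- 2.58 * sqrt(0.05 * 0.95 / length(pvals))
  expect_gt(mean(pvals < 0.05), 0.05 - half)
  expect_lt(mean(pvals < 0.05), 0.05 + half)
})
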