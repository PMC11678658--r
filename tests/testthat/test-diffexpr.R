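test_that("log2(1 + x) transform hits its anchor points and rejects negatives", {
  expect_equal(log2p1(c(0, 1, 3)), c(0, 1, 2))
  expect_true(all(diff(log2p1(seq(0, 50, by = 0.5))) > 0))
  expect_error(log2p1(-1), "non-negative")
})

test_that("one-way ANOVA matches the hand-evaluated sums of squares", {
  # identical groups: no between-group variance
  same <- anova_oneway(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_false(same$degenerate)

  # SSB = 13.5, SSW = 4, df = (1, 4) -> F = 13.5
  res <- anova_oneway(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$statistic, 13.5)
  expect_equal(res$df, c(1L, 4L))
  expect_equal(res$p.value, pf(13.5, 1, 4, lower.tail = FALSE))

  # constant everywhere: degenerate, p = 1
  degen <- anova_oneway(list(c(2, 2), c(2, 2, 2)))
  expect_true(degen$degenerate)
  expect_equal(degen$p.value, 1)
})

test_that("ANOVA agrees with stats::oneway.test and the F = t^2 identity", {
  set.seed(42)
  for (i in 1:50) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(3:8, 1), mean = j / 2))
    mine <- anova_oneway(groups)
    ref <- stats::oneway.test(
      y ~ g,
      data = data.frame(y = unlist(groups),
                        g = factor(rep(seq_len(k), lengths(groups)))),
      var.equal = TRUE
    )
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p.value, unname(ref$p.value), tolerance = 1e-12)
  }
  # two groups: F equals the squared pooled-variance t statistic
  for (i in 1:50) {
    a <- rnorm(5); b <- rnorm(6, 0.5)
    f <- anova_oneway(list(a, b))
    t <- posthoc_t_vs_control(a, b)
    expect_equal(f$statistic, t$statistic^2, tolerance = 1e-10)
    expect_equal(f$p.value, t$p.value, tolerance = 1e-10)
  }
})

test_that("post hoc t-test matches stats::t.test and Bonferroni arithmetic", {
  idem <- posthoc_t_vs_control(c(1, 2, 3), c(1, 2, 3), n_comparisons = 11)
  expect_equal(idem$statistic, 0)
  expect_equal(idem$p.value, 1)
  expect_equal(idem$p.bonferroni, 1)

  set.seed(7)
  for (i in 1:25) {
    a <- rnorm(4, 1); b <- rnorm(4)
    mine <- posthoc_t_vs_control(a, b, n_comparisons = 11)
    ref <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
    expect_identical(mine$p.bonferroni, min(1, mine$p.value * 11))
    welch <- posthoc_t_vs_control(a, b, var_equal = FALSE)
    ref_w <- stats::t.test(a, b)
    expect_equal(welch$p.value, ref_w$p.value, tolerance = 1e-12)
  }

  # zero pooled variance
  flat_eq <- posthoc_t_vs_control(c(2, 2, 2), c(2, 2, 2))
  expect_true(flat_eq$degenerate); expect_equal(flat_eq$p.value, 1)
  flat_ne <- posthoc_t_vs_control(c(3, 3, 3), c(2, 2, 2))
  expect_true(flat_ne$degenerate); expect_equal(flat_ne$p.value, 0)
})

test_that("BH q-values follow the step-up definition", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(19)
  for (i in 1:40) {
    p <- round(stats::runif(sample(1:12, 1)), 3)
    q <- bh_fdr(p)
    expect_equal(q, bh_brute(p), tolerance = 1e-12)
    # monotone non-decreasing along the sorted p order
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    expect_true(all(q >= 0 & q <= 1))
  }
})

test_that("log2 fold change uses pseudocounted mean ratios", {
  expect_equal(log2_fold_change(c(1, 3), c(2, 2)), 0)
  expect_equal(log2_fold_change(c(3, 3), c(1, 1), pseudocount = 1), 1)
  expect_equal(log2_fold_change(c(0, 0), c(0, 0)), 0)
  expect_error(log2_fold_change(1, 1, pseudocount = 0), "pseudocount")
})

test_that("call_group_de drops all-zero transcripts and recovers a planted marker", {
  sim <- simulate_expression(synthetic_spec(
    n_groups = 11, n_neuronopathic = 7, replicates = 4,
    n_null = 50, n_universal = 1, n_shared_partial = 0,
    n_neuro_specific = 0, n_singleton = 0,
    effect_log2fc = 3, noise_sd = 0.1, seed = 5
  ))
  expr <- sim$expr
  zero_row <- expr[1, ]
  zero_row$transcript_id <- "ALLZERO"
  zero_row[-1] <- 0
  expr <- dplyr::bind_rows(expr, zero_row)

  de <- call_group_de(expr, sim$design)
  expect_false("ALLZERO" %in% de$transcript_id)

  planted <- sim$truth$transcript_id[sim$truth$class == "universal"]
  calls <- de[de$transcript_id == planted, ]
  expect_identical(nrow(calls), 11L)
  expect_true(all(calls$altered))
  expected_dir <- if (sim$truth$sign[sim$truth$class == "universal"] > 0) "up" else "down"
  expect_true(all(calls$direction == expected_dir))
  # Bonferroni factor is the number of disease groups, exactly
  expect_identical(de$t_p_bonf, pmin(1, de$t_p_raw * 11))
})

test_that("DE calls are invariant under sample-column permutation", {
  sim <- simulate_expression(synthetic_spec(
    n_null = 30, n_universal = 5, n_shared_partial = 5,
    n_neuro_specific = 5, n_singleton = 5, seed = 9
  ))
  de1 <- call_group_de(sim$expr, sim$design)
  set.seed(1)
  perm <- c(1L, 1L + sample(ncol(sim$expr) - 1L))
  de2 <- call_group_de(sim$expr[, perm], sim$design)
  expect_equal(tidy(de1), tidy(de2))
})

test_that("zero-noise null data yields no altered calls via the degenerate rule", {
  sim <- simulate_expression(synthetic_spec(
    n_null = 20, n_universal = 0, n_shared_partial = 0,
    n_neuro_specific = 0, n_singleton = 0, noise_sd = 0, seed = 2
  ))
  de <- call_group_de(sim$expr, sim$design)
  expect_identical(sum(de$altered), 0L)
  expect_true(all(de$direction == "none"))
})

test_that("the alternative BH composition over post hoc p is selectable", {
  sim <- simulate_expression(synthetic_spec(
    n_null = 100, n_universal = 5, n_shared_partial = 0,
    n_neuro_specific = 0, n_singleton = 0, seed = 13
  ))
  de <- call_group_de(sim$expr, sim$design, analysis_config(fdr_on = "posthoc"))
  # q is the BH adjustment of the raw post hoc p within each group
  for (g in de_groups(de)[1:3]) {
    sub <- de[de$group == g, ]
    expect_equal(sub$fdr_q, bh_brute(sub$t_p_raw), tolerance = 1e-12)
  }
})
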