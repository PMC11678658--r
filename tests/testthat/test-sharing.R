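test_that("profiles collapse DE calls to altered-group sets", {
  de <- mpsmarkers:::new_de_table(tibble::tibble(
    transcript_id = rep(c("t1", "t2"), each = 3),
    group = rep(c("I", "II", "III"), 2),
    log2fc = c(2, -1, 0.5, 1, 1, 1),
    anova_f = NA_real_, anova_p = NA_real_, t_stat = NA_real_,
    t_p_raw = NA_real_, t_p_bonf = NA_real_, fdr_q = NA_real_,
    altered = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    direction = c("up", "down", "none", "none", "none", "none")
  ), groups = c("I", "II", "III"))
  prof <- build_profiles(de)
  expect_identical(nrow(prof), 2L)
  expect_setequal(prof$altered_groups[[1]], c("I", "II"))
  expect_identical(prof$altered_groups[[2]], character(0))
  expect_identical(prof$direction[[1]][["II"]], "down")

  expect_error(build_profiles(dplyr::bind_rows(de, de[1, ])), "duplicate")
})

test_that("the printed shared-marker table yields the published sharing spectrum", {
  prof <- build_profiles(ingest_printed_table(shared_fixture()))
  expect_identical(prof$transcript_id[prof$n_altered == 11], "PFN1")
  sp <- sharing_spectrum(prof)
  expect_identical(sp$exactly_k[sp$k == 11], 1L)
  expect_identical(sp$exactly_k[sp$k == 10], 8L)
  expect_identical(sp$at_least_k[sp$k == 1], 9L)
  # conservation: exact counts sum to the transcripts altered anywhere
  expect_identical(sum(sp$exactly_k), sum(prof$n_altered >= 1))
  expect_true(all(diff(sp$at_least_k) <= 0))
})

test_that("sharing spectrum of no alterations is all zero", {
  allx <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tI\tII", "t1\tX\tX", "t2\tX\tX"), allx)
  prof <- build_profiles(ingest_printed_table(allx))
  sp <- sharing_spectrum(prof)
  expect_true(all(sp$exactly_k == 0L))
  expect_true(all(sp$at_least_k == 0L))
})

test_that("shared-marker selection reproduces the printed table and its rules", {
  prof <- build_profiles(ingest_printed_table(shared_fixture()))
  mk <- select_shared_markers(prof, min_groups = 10, fc_threshold = log2(2.5))
  expect_identical(nrow(mk), 9L)
  expect_identical(mk$transcript_id[1], "PFN1") # 11 groups sorts first
  expect_true(all(mk$n_groups_altered >= 10))
  # every retained row has some altered |log2fc| beyond the threshold
  hm <- heatmap_matrix(mk)
  expect_true(all(apply(abs(hm), 1, max, na.rm = TRUE) > log2(2.5)))

  # min_groups above the group count empties the table
  expect_identical(nrow(select_shared_markers(prof, min_groups = 12)), 0L)

  # a vanishing threshold reduces selection to the pure min-groups rule
  mk0 <- select_shared_markers(prof, min_groups = 10, fc_threshold = 1e-12)
  expect_identical(nrow(mk0), sum(prof$n_altered >= 10))

  # selection is invariant under permutation of the profile rows
  set.seed(3)
  prof_perm <- prof[sample(nrow(prof)), ]
  attr(prof_perm, "groups") <- attr(prof, "groups")
  class(prof_perm) <- class(prof)
  expect_equal(as.data.frame(select_shared_markers(prof_perm, 10, log2(2.5))),
               as.data.frame(mk))
})

test_that("heatmap masking matches the altered flags cell by cell", {
  de <- ingest_printed_table(shared_fixture())
  prof <- build_profiles(de)
  mk <- select_shared_markers(prof, 10, log2(2.5))
  hm <- heatmap_matrix(mk)
  expect_identical(sum(is.na(hm)), 8L)
  expect_false(anyNA(hm["PFN1", ]))
  expect_identical(names(which(is.na(hm["ABHD5", ]))), "IVB")
  for (tr in rownames(hm)) {
    for (g in colnames(hm)) {
      flagged <- de$altered[de$transcript_id == tr & de$group == g]
      expect_identical(is.na(hm[tr, g]), !flagged)
    }
  }
})

test_that("planted universal markers fill the top of the spectrum", {
  sim <- simulate_expression(synthetic_spec(
    n_null = 200, n_universal = 10, n_shared_partial = 0,
    n_neuro_specific = 0, n_singleton = 0,
    effect_log2fc = 3, noise_sd = 0.1, replicates = 4, seed = 21
  ))
  prof <- build_profiles(call_group_de(sim$expr, sim$design))
  mk <- select_shared_markers(prof, min_groups = 11)
  planted <- sim$truth$transcript_id[sim$truth$class == "universal"]
  expect_setequal(mk$transcript_id, planted)
  sp <- sharing_spectrum(prof)
  expect_identical(sum(sp$exactly_k), sum(prof$n_altered >= 1))
})
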