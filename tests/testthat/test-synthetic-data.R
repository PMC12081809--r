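test_that("null-effect screens give treated ~ untreated (KS p-values uniform)", {
  truth <- screen_truth(markers = sprintf("M%02d", 1:10),
                        treatments = "tis",
                        isotype_groups = list(IgG1 = sprintf("M%02d", 1:10)),
                        events_per_well = 400L)
  pvals <- vapply(1:15, function(s) {
    scr <- generate_screen(truth, seed = s)
    suppressWarnings(stats::ks.test(event_sample(scr, "M01", "tis"),
                                    event_sample(scr, "M01", "untreated"))$p.value)
  }, numeric(1))
  # under the null the KS p-values are ~ uniform on (0,1)
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif")$p.value), 0.01)
  expect_gt(max(pvals), 0.5)
})

test_that("planted multiplicative effects shift the sample median", {
  truth <- screen_truth(markers = sprintf("M%02d", 1:10),
                        treatments = "tis",
                        isotype_groups = list(IgG1 = sprintf("M%02d", 1:10)),
                        events_per_well = 5000L)
  truth$marker_effects["M01", "tis"] <- 3.0
  scr <- generate_screen(truth, seed = 42)
  ratio <- median(event_sample(scr, "M01", "tis")) /
    median(event_sample(scr, "M01", "untreated"))
  expect_lt(abs(ratio - 3.0) / 3.0, 0.10)
})

test_that("screen generation is deterministic and matches the truth layout", {
  truth <- screen_truth(markers = sprintf("M%02d", 1:8),
                        isotype_groups = list(IgA = sprintf("M%02d", 1:8)),
                        events_per_well = 150L)
  s1 <- generate_screen(truth, seed = 9)
  s2 <- generate_screen(truth, seed = 9)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$plate_map, s2$plate_map)
  s3 <- generate_screen(truth, seed = 10)
  expect_false(identical(s1$events, s3$events))

  expect_identical(s1$conditions, c("untreated", truth$treatments))
  for (cond in s1$conditions) {
    expect_equal(nrow(s1$events[[cond]]), 150L)
    expect_setequal(colnames(s1$events[[cond]]),
                    c(truth$markers, "ISO_IgA"))
  }
})

test_that("empirical fold change converges with events per well", {
  errs <- vapply(c(250L, 1000L, 4000L), function(n) {
    truth <- screen_truth(markers = "M1", treatments = "tis",
                          isotype_groups = list(IgG1 = "M1"),
                          events_per_well = n)
    truth$marker_effects["M1", "tis"] <- 2.0
    mean(vapply(1:8, function(s) {
      scr <- generate_screen(truth, seed = s)
      r <- median(event_sample(scr, "M1", "tis")) /
        median(event_sample(scr, "M1", "untreated"))
      abs(r - 2.0)
    }, numeric(1)))
  }, numeric(1))
  expect_lt(errs[3], errs[1])
})

test_that("screen truth invariants are enforced", {
  expect_error(screen_truth(markers = c("A", "B"),
                            isotype_groups = list(I1 = "A")),
               "without isotype group")
  expect_error(screen_truth(markers = c("A", "B"),
                            isotype_groups = list(I1 = c("A", "B"), I2 = "A")),
               "more than one isotype group")
  expect_error(
    screen_truth(markers = "A", isotype_groups = list(I1 = "A"),
                 bimodal_markers = list(A = list(weight = 1.2,
                                                 logmeans = c(1, 2),
                                                 logsds = c(.1, .1)))),
    "strictly in"
  )
  truth <- screen_truth(markers = "A", isotype_groups = list(I1 = "A"),
                        events_per_well = 50L)
  expect_error(generate_screen(truth), "events_per_well")
})

test_that("LFC generator: zero effect and zero noise give all-zero LFC", {
  truth <- transcriptome_truth(n_genes = 200, set_size = 10, n_sets = 5,
                               planted_sets = c(SET_01 = 0),
                               n_membrane_per_class = 0L,
                               n_membrane_decoys = 0L, n_panel_genes = 0L,
                               lfc_noise_sd = 0)
  tab <- generate_lfc_table(truth, seed = 1)
  expect_true(all(tab$lfc$lfc == 0))
})

test_that("planted set effect is recovered by the member mean", {
  truth <- transcriptome_truth(n_genes = 500, set_size = 25, n_sets = 5,
                               planted_sets = c(SET_02 = 2),
                               lfc_noise_sd = 0.1)
  tab <- generate_lfc_table(truth, seed = 3)
  members <- truth$gene_sets$SET_02
  sub <- tab$lfc[tab$lfc$gene %in% members &
                   tab$lfc$cell_line == "HUH7" &
                   tab$lfc$treatment == "alisertib" &
                   tab$lfc$timepoint == "t1", ]
  expect_lt(abs(mean(sub$lfc) - 2), 0.1)
})

test_that("LFC generator is reproducible and validates planted sets", {
  truth <- transcriptome_truth(n_genes = 200, set_size = 10, n_sets = 5)
  expect_identical(generate_lfc_table(truth, seed = 7)$lfc,
                   generate_lfc_table(truth, seed = 7)$lfc)
  expect_error(transcriptome_truth(n_genes = 200, set_size = 10, n_sets = 5,
                                   planted_sets = c(NOT_A_SET = 2)),
               "absent from collection")
})
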