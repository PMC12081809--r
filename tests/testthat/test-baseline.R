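test_that("MFI is the sample median", {
  expect_equal(compute_mfi(c(1, 2, 3, 4, 100)), 3)
  expect_equal(compute_mfi(rep(7.5, 10)), 7.5)
  expect_equal(compute_mfi(c(1, 2, 3, 4)), 2.5)
  expect_error(compute_mfi(numeric(0)), "empty")
  expect_error(compute_mfi(c(1, NA)), "non-finite")

  set.seed(31)
  x <- 10^rnorm(10000, mean = 2.3, sd = 0.25)
  expect_lt(abs(compute_mfi(x) - 10^2.3) / 10^2.3, 0.02)
})

test_that("kde_mode finds the density peak on the log10 scale", {
  # point mass
  expect_lt(abs(log10(kde_mode(rep(50, 10))) - log10(50)), 1e-3)

  # symmetric sample about log10 = 2
  set.seed(7)
  vals <- 10^rnorm(1000, 2, 0.2)
  m <- kde_mode(vals)
  expect_lt(abs(log10(m) - 2), 0.02)
  expect_lt(abs(log10(m) - log10(fine_grid_kde_mode(vals))),
            kde_grid_step(vals))

  # robust to a high minority tail, unlike the mean
  set.seed(8)
  vals45 <- 10^c(rnorm(40, 2, 0.05), rnorm(5, 3.5, 0.05))
  m45 <- kde_mode(vals45)
  expect_lt(abs(log10(m45) - 2), 0.05)
  expect_gt(mean(vals45), 3 * m45)
  expect_lt(abs(log10(m45) - log10(fine_grid_kde_mode(vals45))),
            kde_grid_step(vals45))

  expect_error(kde_mode(c(0, 1)), "positive")
  expect_error(kde_mode(5), ">= 2")
})

test_that("small isotype sets use the control well directly", {
  markers <- paste0("M", 1:5)
  wells <- c(setNames(as.list(c(300, 400, 500, 600, 700)), markers),
             list(ISO_I1 = 120))
  pm <- data.frame(marker = markers, isotype_id = "I1",
                   well = paste0("w", 1:5))
  scr <- constant_screen(wells, pm)
  bl <- assign_baselines(scr)
  expect_equal(bl$baseline, rep(120, 5))
  expect_equal(unique(bl$baseline_method), "direct-isotype")
})

test_that("large isotype sets use the KDE mode of member MFIs", {
  set.seed(12)
  markers <- sprintf("M%02d", 1:60)
  mfis <- c(10^rnorm(55, 2, 0.05), 10^rnorm(5, log10(3000), 0.05))
  wells <- setNames(as.list(mfis), markers)
  pm <- data.frame(marker = markers, isotype_id = "I1",
                   well = paste0("w", 1:60))
  scr <- constant_screen(wells, pm)   # no ISO well: must not be needed
  bl <- assign_baselines(scr)
  expect_equal(unique(bl$baseline_method), "kde-mode")
  base <- unique(bl$baseline)
  expect_length(base, 1)
  expect_lt(abs(log10(base) - 2), 0.05)
  expect_lt(abs(log10(base) - log10(fine_grid_kde_mode(mfis))),
            kde_grid_step(mfis))
})

test_that("the cutoff is a strict inequality at 40 markers", {
  markers <- sprintf("M%02d", 1:40)
  wells <- c(setNames(as.list(rep(200, 40)), markers), list(ISO_I1 = 110))
  pm <- data.frame(marker = markers, isotype_id = "I1",
                   well = paste0("w", 1:40))
  bl <- assign_baselines(constant_screen(wells, pm))
  expect_equal(unique(bl$baseline_method), "direct-isotype")
  expect_equal(unique(bl$baseline), 110)

  # a 40-set without its control well is an error
  wells$ISO_I1 <- NULL
  expect_error(assign_baselines(constant_screen(wells, pm)),
               "ISO_I1 absent")
})

test_that("baseline method flag matches isotype-set size on random maps", {
  set.seed(99)
  for (rep in 1:5) {
    n_big <- sample(41:70, 1)
    n_small <- sample(1:40, 1)
    markers <- sprintf("M%03d", seq_len(n_big + n_small))
    big <- markers[seq_len(n_big)]
    small <- setdiff(markers, big)
    wells <- c(setNames(as.list(10^stats::runif(length(markers), 1.8, 2.2)),
                        markers),
               list(ISO_S = 95))
    pm <- data.frame(marker = markers,
                     isotype_id = ifelse(markers %in% big, "B", "S"),
                     well = markers)
    bl <- assign_baselines(constant_screen(wells, pm))
    expect_true(all(bl$baseline_method[bl$marker %in% big] == "kde-mode"))
    expect_true(all(bl$baseline_method[bl$marker %in% small] ==
                      "direct-isotype"))
  }
})

test_that("normalized MFI is mfi/baseline and is scale equivariant", {
  markers <- paste0("M", 1:3)
  wells <- c(list(M1 = 120, M2 = 240, M3 = 600), list(ISO_I1 = 120))
  pm <- data.frame(marker = markers, isotype_id = "I1",
                   well = paste0("w", 1:3))
  np <- normalize_screen(constant_screen(wells, pm))
  expect_equal(np$normalized_mfi, c(1, 2, 5))

  # multiplying every intensity in a condition by k leaves ratios unchanged
  truth <- screen_truth(markers = sprintf("M%02d", 1:45),
                        treatments = "tis",
                        isotype_groups = list(I1 = sprintf("M%02d", 1:45)),
                        events_per_well = 200L)
  scr <- generate_screen(truth, seed = 3)
  np1 <- normalize_screen(scr)
  scr$events$tis <- scr$events$tis * 7.3
  np2 <- normalize_screen(scr)
  expect_equal(np2$normalized_mfi, np1$normalized_mfi, tolerance = 1e-10)
})

test_that("planted fold effects survive normalization", {
  truth <- screen_truth(markers = sprintf("M%02d", 1:45),
                        treatments = "tis",
                        isotype_groups = list(I1 = sprintf("M%02d", 1:45)),
                        events_per_well = 5000L)
  truth$marker_effects["M07", "tis"] <- 3.0
  scr <- generate_screen(truth, seed = 21)
  np <- normalize_screen(scr)
  get <- function(cond) np$normalized_mfi[np$marker == "M07" &
                                            np$condition == cond]
  expect_lt(abs(get("tis") / get("untreated") - 3) / 3, 0.10)
})
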