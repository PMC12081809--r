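test_that("quantile function is the empirical log10 quantile", {
  # uniform grid on [0,1] in log10 space -> Q(p) = p/100 up to interpolation
  x <- 10^seq(0, 1, length.out = 10001)
  Q <- quantile_function(x)
  expect_equal(unname(Q), (0:100) / 100, tolerance = 1e-3)
  expect_false(is.unsorted(Q))

  Qc <- quantile_function(rep(42, 200))
  expect_equal(unname(Qc), rep(log10(42), 101))

  set.seed(3)
  Qr <- quantile_function(10^rnorm(500))
  expect_false(is.unsorted(Qr))

  expect_error(quantile_function(10^rnorm(50)), ">= 100 events")
  expect_error(quantile_function(c(rep(1, 150), -1)), "positive")
})

test_that("QDF of a linear quantile function is its slope", {
  Q <- 0.013 * (0:100) + 2
  q <- qdf(Q)
  expect_equal(unname(q), rep(0.013, 101), tolerance = 1e-10)
  expect_error(qdf(Q[1:3], window = 5), "window larger")
})

test_that("QDF matches closed-form quantile densities of known laws", {
  # relative agreement is measured as the mean absolute deviation over the
  # band: per-point sampling noise of an empirical quantile density at
  # n = 10,000 with a 5-point window is itself ~5%
  p <- 10:90
  set.seed(101)
  x_exp <- 10^stats::rexp(10000)
  q_exp <- qdf(quantile_function(x_exp))
  closed_exp <- (1 / 100) / (1 - p / 100)
  expect_lt(mean(abs(q_exp[p + 1] - closed_exp) / closed_exp), 0.05)

  x_norm <- 10^stats::rnorm(10000)
  q_norm <- qdf(quantile_function(x_norm))
  closed_norm <- (1 / 100) / stats::dnorm(stats::qnorm(p / 100))
  expect_lt(mean(abs(q_norm[p + 1] - closed_norm) / closed_norm), 0.05)
})

test_that("unclipped QDF integrates back to the quantile range", {
  set.seed(11)
  x <- 10^rnorm(5000, 2, 0.3)
  Q <- quantile_function(x)
  q <- qdf(Q, clip = FALSE)
  integral <- sum((q[-1] + q[-length(q)]) / 2)  # trapezoid, step 1
  expect_lt(abs(integral - (Q[101] - Q[1])) / (Q[101] - Q[1]), 0.05)
})

test_that("reference function is the pointwise 95th percentile", {
  q1 <- rep(1, 101)
  mat <- rbind(matrix(rep(q1, 99), 99, byrow = TRUE), rep(10, 101))
  ref <- reference_function(mat)
  # type-7 quantile of {1 x99, 10} at 0.95 is 1; always >= 95th order stat
  expect_equal(ref, rep(1, 101))
  expect_true(all(ref >= apply(mat, 2, function(v) sort(v)[95])))

  same <- matrix(rep(2:102, 25), 25, byrow = TRUE)
  expect_equal(reference_function(same), as.numeric(2:102))
  # quantile equivariance under pointwise scaling
  expect_equal(reference_function(3 * same), 3 * reference_function(same))
  expect_warning(reference_function(same[1:5, ]), "unstable")
})

test_that("scores, classes and separating quantiles follow the ratio bands", {
  ref <- rep(0.02, 101)
  sc <- bimodality_score(ref, ref)
  expect_equal(sc$score, 1)
  expect_equal(sc$class, "unimodal")

  q <- ref
  q[51] <- 0.03   # ratio 1.5 at percentile 50
  sc2 <- bimodality_score(q, ref)
  expect_equal(sc2$score, 1.5)
  expect_equal(sc2$class, "potentially-bimodal")
  expect_equal(sc2$separating_quantile, 50)

  q[71] <- 0.05   # ratio 2.5 at percentile 70
  sc3 <- bimodality_score(q, ref)
  expect_equal(sc3$class, "bimodal")
  expect_equal(sc3$separating_quantile, 70)

  # the band excludes the extreme percentiles
  q4 <- ref
  q4[1] <- 1
  expect_equal(bimodality_score(q4, ref)$score, 1)

  bad_ref <- ref
  bad_ref[51] <- 0
  expect_error(bimodality_score(q, bad_ref), "nonpositive")
})

test_that("a planted mixture is flagged at the mixture-weight quantile", {
  for (s in 1:2) {
    truth <- bimodal_test_truth(weight = 0.5)
    scr <- generate_screen(truth, seed = s)
    bi <- screen_bimodality(scr)
    bi_u <- bi[bi$condition == "untreated", ]
    planted <- bi_u[bi_u$marker == "M050", ]
    expect_equal(planted$class, "bimodal")
    expect_lt(abs(planted$separating_quantile - 50), 5 + 1e-9)
    expect_lte(mean(bi_u$class[bi_u$marker != "M050"] == "bimodal"), 0.05)
  }

  # a 30/70 mixture separates near the 30th percentile
  truth37 <- bimodal_test_truth(weight = 0.3)
  scr37 <- generate_screen(truth37, seed = 4)
  bi37 <- screen_bimodality(scr37)
  planted37 <- bi37[bi37$marker == "M050" & bi37$condition == "untreated", ]
  expect_equal(planted37$class, "bimodal")
  expect_lt(abs(planted37$separating_quantile - 30), 5 + 1e-9)
})

test_that("scores are invariant to a global intensity rescale", {
  truth <- bimodal_test_truth(n_markers = 50, events = 500)
  scr <- generate_screen(truth, seed = 6)
  b1 <- screen_bimodality(scr)
  scr$events <- lapply(scr$events, function(df) df * 12.5)
  b2 <- screen_bimodality(scr)
  expect_equal(b2$score, b1$score, tolerance = 1e-10)
  expect_equal(b2$separating_quantile, b1$separating_quantile)
})

test_that("sensitivity grows with mixture separation", {
  scores <- vapply(c(3, 4.5, 6), function(sep) {
    truth <- bimodal_test_truth(sep_sds = sep, events = 2000)
    scr <- generate_screen(truth, seed = 13)
    bi <- screen_bimodality(scr)
    bi$score[bi$marker == "M050" & bi$condition == "untreated"]
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})
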