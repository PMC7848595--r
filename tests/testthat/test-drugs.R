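# Pore-block arithmetic, drug application, Hill fitting, trial mechanics.

test_that("block_fraction has exact closed-form anchors and monotonicity", {
  expect_identical(block_fraction(0, 0.72, 1.06), 0)
  for (h in c(0.5, 1, 1.06, 2.7))
    expect_equal(block_fraction(0.72, 0.72, h), 0.5, tolerance = 1e-15)
  cc <- 10^seq(-3, 2, length.out = 60)
  expect_true(all(diff(block_fraction(cc, 0.72, 1.06)) > 0))
  # steeper Hill increases block above the IC50
  expect_gt(block_fraction(3, 0.72, 2), block_fraction(3, 0.72, 1))
  expect_error(block_fraction(1, -1, 1))
})

test_that("quinidine IKr block matches the published percentages", {
  tab <- read_drug_table()
  q <- tab$quinidine$channels
  ikr <- q[q$current == "IKr", ]
  expect_equal(ikr$ic50, 0.72)
  expect_equal(ikr$hill, 1.06)
  expect_equal(round(100 * block_fraction(0.3, ikr$ic50, ikr$hill)), 28)
  expect_equal(round(100 * block_fraction(3, ikr$ic50, ikr$hill)), 82)
  v <- tab$verapamil$channels
  ical <- v[v$current == "ICaL", ]
  expect_equal(ical$ic50, 0.2)
  expect_equal(ical$hill, 0.8)
})

test_that("apply_drug scales exactly the listed channels and guards misuse", {
  ep <- make_params("torord", "endo")
  d <- drug_profile("ikr_blocker", data.frame(current = "IKr", ic50 = 1,
                                              hill = 1))
  e0 <- apply_drug(ep, d, 0)
  expect_identical(e0$channel_scale, ep$channel_scale)
  e1 <- apply_drug(ep, d, 1)
  expect_equal(e1$channel_scale[["IKr"]], 0.5)
  others <- setdiff(names(ep$channel_scale), "IKr")
  expect_identical(e1$channel_scale[others], ep$channel_scale[others])
  expect_error(apply_drug(e1, d, 1), "already applied")
  expect_error(drug_profile("x", data.frame(current = "IFoo", ic50 = 1,
                                            hill = 1)), "unknown current")
})

test_that("a placebo trial produces no biomarker deltas", {
  placebo <- drug_profile("placebo",
                          data.frame(current = character(0),
                                     ic50 = numeric(0), hill = numeric(0)))
  x <- drug_trial("torord", "endo", placebo, 1, n_drug_beats = 12,
                  record_last = 2)
  expect_lt(abs(x$delta[["apd90"]]), 0.5)
  expect_lt(abs(x$delta[["ta_peak"]]), 0.05)
  expect_identical(x$outcome, "normal")
  expect_false(x$flags$ead)
  expect_length(x$flags$escape_beats, 0)
})

test_that("Hill-fit recovery: exact without noise, within 10% at 1% noise", {
  concs <- c(0.001, 0.01, 0.05, 0.2, 1, 5)
  ic50 <- 0.05; h <- 1.3
  y <- 100 * block_fraction(concs, ic50, h)
  f0 <- fit_hill(concs, y)
  expect_equal(f0$ic50, ic50, tolerance = 1e-4)
  expect_equal(f0$hill, h, tolerance = 1e-4)
  set.seed(42)
  for (k in 1:20) {
    yn <- pmin(100, pmax(0, y + stats::rnorm(length(y), 0, 1)))
    f <- fit_hill(concs, yn)
    expect_lt(abs(f$ic50 - ic50) / ic50, 0.10)
    expect_lt(abs(f$hill - h) / h, 0.10)
  }
})

test_that("non-monotone dose-response data are fitted but flagged", {
  concs <- c(0.01, 0.1, 1, 10)
  y <- c(5, 40, 30, 90)
  f <- fit_hill(concs, y)
  expect_false(f$monotone)
  expect_true(is.finite(f$ic50))
  expect_length(f$residuals, 4)
})

test_that("ead_onset_concentration returns NA for a placebo scan", {
  placebo <- drug_profile("placebo",
                          data.frame(current = character(0),
                                     ic50 = numeric(0), hill = numeric(0)))
  res <- ead_onset_concentration("torord", placebo, c(0.1, 1),
                                 n_drug_beats = 6, record_last = 2)
  expect_true(is.na(res))
})
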