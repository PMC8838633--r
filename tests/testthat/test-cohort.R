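# Cohort sampling, trial schedules and ground-truth vessel state.

test_that("cohort sampler converges to the reference per-sex moments", {
  coh <- make_cohort(1000, 1000, 2)
  tab <- table1_parameters()
  for (v in c("scm_thickness", "ijv_depth", "csa_baseline")) {
    for (sx in c("F", "M")) {
      mu <- tab[[v]][[sx]][1]
      sdv <- tab[[v]][[sx]][2]
      # the sampler targets the truncated-normal mean (3 sd; baseline CSA is
      # additionally floored above the collapse limit)
      target <- truncnorm_mean(mu, sdv, if (v == "csa_baseline") 0.10 else 1e-6)
      got <- mean(coh[[v]][coh$sex == sx])
      expect_lt(abs(got - target), 3 * sdv / sqrt(1000))
      # and stays close to the nominal reference mean
      expect_lt(abs(got - mu), 0.2 * sdv)
    }
  }
  ratio <- mean(coh$hb_scale[coh$sex == "M"]) / mean(coh$hb_scale[coh$sex == "F"])
  expect_lt(abs(ratio - 1.15), 0.01)
})

test_that("small-cohort demographics match the reference table within sampling error", {
  coh <- make_cohort(10, 9, 1)
  expect_equal(nrow(coh), 19)
  m_scm <- mean(coh$scm_thickness[coh$sex == "M"])
  f_scm <- mean(coh$scm_thickness[coh$sex == "F"])
  expect_lt(abs(m_scm - 1.13), 3 * 0.23 / sqrt(10))
  expect_lt(abs(f_scm - 0.81), 3 * 0.14 / sqrt(9))
  expect_gt(m_scm, f_scm)
})

test_that("sampled parameters always satisfy positivity invariants", {
  for (k in 1:20) {
    coh <- make_cohort(1, 1, k)
    expect_true(all(coh$scm_thickness > 0))
    expect_true(all(coh$ijv_depth > 0))
    expect_true(all(coh$csa_baseline > 0))
    expect_true(all(coh$hb_scale > 0))
    expect_true(all(coh$jva_gain > 0))
    expect_true(all(coh$hdt_delta > 0))
  }
  expect_error(make_cohort(0, 5, 1), "n_men")
})

test_that("cohort generation is reproducible and participants nest across sizes", {
  a <- make_cohort(4, 4, 7)
  b <- make_cohort(4, 4, 7)
  expect_identical(a, b)
  big <- make_cohort(6, 6, 7)
  expect_equal(big[big$id %in% a$id, ], a, ignore_attr = TRUE)
})

test_that("trial schedules hold 3 HDT + 4 LBNP levels in fixed within-block order", {
  coh <- make_cohort(2, 2, 5)
  lv <- condition_levels()
  hdt_first <- logical(200)
  for (s in 1:200) {
    sch <- schedule_trials(coh[1, ], s)
    expect_equal(nrow(sch), 7)
    expect_equal(sch$level[sch$condition == "HDT"], lv$HDT)
    expect_equal(sch$level[sch$condition == "LBNP"], lv$LBNP)
    hdt_first[s] <- sch$condition[1] == "HDT"
  }
  # block order is a fair coin across seeds
  expect_gt(mean(hdt_first), 0.5 - 3 * 0.5 / sqrt(200))
  expect_lt(mean(hdt_first), 0.5 + 3 * 0.5 / sqrt(200))
})

test_that("true CSA is deterministic, anchored at baseline and monotone over levels", {
  coh <- make_cohort(5, 5, 11)
  for (i in seq_len(nrow(coh))) {
    p <- coh[i, ]
    expect_identical(true_csa(p, "HDT", 0), p$csa_baseline)
    expect_identical(true_csa(p, "LBNP", 0), p$csa_baseline)
    hdt <- vapply(c(0, -3, -6), function(l) true_csa(p, "HDT", l), numeric(1))
    lbnp <- vapply(c(0, -20, -30, -40), function(l) true_csa(p, "LBNP", l), numeric(1))
    expect_true(all(diff(hdt) >= 0))
    expect_true(all(diff(lbnp) <= 0))
    expect_true(all(lbnp >= 0.05))
    expect_identical(true_csa(p, "HDT", -6), true_csa(p, "HDT", -6))
  }
  expect_error(true_csa(coh[1, ], "TILT", 0), "unknown condition")
  expect_error(true_csa(coh[1, ], "HDT", -4), "not valid")
})

test_that("group-mean CSA reduction at -40 mmHg equals the configured closed form", {
  coh <- make_cohort(50, 50, 13)
  red <- vapply(seq_len(nrow(coh)), function(i) {
    true_csa(coh[i, ], "LBNP", 0) - true_csa(coh[i, ], "LBNP", -40)
  }, numeric(1))
  expect_equal(mean(red), 0.75 * (mean(coh$csa_baseline) - 0.05), tolerance = 1e-12)
})

test_that("vessel dynamics have the right length, positivity and PPG anti-phase", {
  coh <- make_cohort(1, 1, 3)
  p <- coh[1, ]
  dyn <- render_dynamics(p, "HDT", 0, 30, 60, 21)
  expect_length(dyn$csa_t, 1800)
  expect_true(all(dyn$csa_t > 0))
  expect_lt(cor(dyn$cardiac, dyn$signals$ppg), 0)
  # zero amplitudes give a constant series at the ground truth
  flat <- render_dynamics(p, "HDT", 0, 2, 30, 21, cardiac_amp = 0, resp_amp = 0)
  expect_equal(flat$csa_t, rep(true_csa(p, "HDT", 0), 60))
  # same seed means the same heart across levels
  d1 <- render_dynamics(p, "LBNP", 0, 5, 30, 9)
  d2 <- render_dynamics(p, "LBNP", -40, 5, 30, 9)
  expect_equal(d1$csa_t / d1$mean_csa, d2$csa_t / d2$mean_csa)
})

test_that("cohort tables round-trip through CSV", {
  coh <- make_cohort(2, 2, 17)
  path <- tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back$id, coh$id)
  expect_equal(back$jva_gain, coh$jva_gain, tolerance = 1e-12)
  unlink(path)
})
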