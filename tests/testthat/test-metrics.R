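std <- wq_weighting("standard")

test_that("transition specs enforce their field requirements", {
  expect_error(transition_spec("numeric"), "threshold")
  expect_error(transition_spec("numeric", threshold = 120), "threshold")
  expect_error(transition_spec("classification"), "level")
  expect_error(transition_spec("classification", threshold = 80, level = "enhanced"),
               "no threshold")
  expect_error(transition_spec("behaviour_benefit", threshold = 50), "neither")
})

test_that("benefit flags follow the per-kind rules", {
  tr <- transition_spec("numeric", threshold = 70)
  fl <- resolve_benefit_flags(c(60, 70, 80, 50), c(60, 70, 80, 50), tr)
  expect_equal(unname(fl$sp[1, ]), c(FALSE, TRUE, TRUE, FALSE))

  # per-stage classification: SP just enhanced, FP fails the >=20 floor
  tr <- transition_spec("classification", level = "enhanced")
  fl <- resolve_benefit_flags(c(55, 55, 20, 20), c(10, 90, 90, 90), tr)
  expect_true(all(fl$sp))
  expect_false(any(fl$fp))
  # an excellent stage also meets the enhanced transition
  fl2 <- resolve_benefit_flags(c(80, 80, 55, 55), c(55, 55, 20, 20), tr)
  expect_true(all(fl2$sp))

  tr <- transition_spec("behaviour_benefit")
  fl <- resolve_benefit_flags(runif(4, 0, 100), runif(4, 0, 100), tr)
  expect_equal(unname(fl$sp[1, ]), c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(fl$sp, fl$fp)
})

test_that("principle contributions implement both branches of the summand", {
  expect_equal(principle_contribution(100, 0.35, 0.001, TRUE), -0.035)
  expect_equal(principle_contribution(0, 0.35, 0.001, FALSE), 0.035)
  # the discontinuity: same score, opposite branch
  expect_equal(principle_contribution(50, 1, 1, FALSE), 50)
  expect_equal(principle_contribution(50, 1, 1, TRUE), -50)
})

test_that("welfare cost reproduces the worked example and closed forms", {
  spec70 <- metric_spec(transition_spec("numeric", threshold = 70), "standard")
  res <- welfare_cost(c(60, 70, 80, 50), c(40, 60, 70, 30), spec70,
                      y_sp = 1.5e-3, y_fp = 4.9e-3)
  expect_equal(res$cost, -16 * 1.5e-3 + 24 * 4.9e-3, tolerance = 1e-12)
  expect_equal(res$cost, 0.0936, tolerance = 1e-10)
  expect_equal(res$cost, res$cost_sp + res$cost_fp, tolerance = 1e-12)

  spec100 <- metric_spec(transition_spec("numeric", threshold = 100), "equal")
  y_sp <- 2e-3; y_fp <- 5e-3
  all100 <- welfare_cost(rep(100, 4), rep(100, 4), spec100, y_sp, y_fp)
  expect_equal(all100$cost, -100 * (y_sp + y_fp), tolerance = 1e-12)
  all0 <- welfare_cost(rep(0, 4), rep(0, 4), spec100, y_sp, y_fp)
  expect_equal(all0$cost, +100 * (y_sp + y_fp), tolerance = 1e-12)
})

test_that("welfare cost equals the independent 8-term oracle on the grid", {
  set.seed(13)
  specs <- canonical_metric_grid()
  for (k in 1:60) {
    cs <- random_metric_case()
    for (spec in specs) {
      got <- welfare_cost(cs$sp, cs$fp, spec, cs$y_sp, cs$y_fp)$cost
      tr <- spec$transition
      want <- oracle_welfare_cost(cs$sp, cs$fp, spec$weighting,
                                  cs$y_sp, cs$y_fp, tr$kind,
                                  tr$threshold, tr$level)
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("cost is strictly decreasing in every principle score", {
  set.seed(17)
  specs <- list(
    metric_spec(transition_spec("numeric", threshold = 60), "standard"),
    metric_spec(transition_spec("classification", level = "enhanced"), "equal"),
    metric_spec(transition_spec("behaviour_benefit"), "extreme"))
  for (k in 1:20) {
    cs <- random_metric_case()
    for (spec in specs) {
      base <- welfare_cost(cs$sp, cs$fp, spec, cs$y_sp, cs$y_fp)$cost
      i <- sample(4, 1)
      up <- cs$sp; up[i] <- up[i] + runif(1, 0.5, 100 - up[i])
      expect_lt(welfare_cost(up, cs$fp, spec, cs$y_sp, cs$y_fp)$cost, base)
    }
  }
})

test_that("cost is non-increasing as the numeric transition decreases", {
  set.seed(19)
  thresholds <- c(100, 90, 80, 70, 60, 50, 40)
  for (k in 1:25) {
    cs <- random_metric_case()
    costs <- vapply(thresholds, function(T) {
      spec <- metric_spec(transition_spec("numeric", threshold = T), "standard")
      welfare_cost(cs$sp, cs$fp, spec, cs$y_sp, cs$y_fp)$cost
    }, numeric(1))
    expect_true(all(diff(costs) <= 1e-12))  # T decreasing along the vector
  }
})

test_that("cost is linear in the life-years (functional-unit scaling)", {
  set.seed(23)
  spec <- metric_spec(transition_spec("numeric", threshold = 70), "equal")
  cs <- random_metric_case()
  base <- welfare_cost(cs$sp, cs$fp, spec, cs$y_sp, cs$y_fp)$cost
  for (c_scale in c(0.1, 2, 17)) {
    expect_equal(
      welfare_cost(cs$sp, cs$fp, spec, c_scale * cs$y_sp,
                   c_scale * cs$y_fp)$cost,
      c_scale * base, tolerance = 1e-12)
  }
})

test_that("the canonical grid has 30 uniquely-named variants in fixed order", {
  specs <- canonical_metric_grid()
  expect_length(specs, 30)
  expect_false(anyDuplicated(names(specs)) > 0)
  expect_identical(names(specs)[1:3],
                   c("T100/standard", "T100/equal", "T100/extreme"))
  expect_true(all(c("excellent/standard", "enhanced/equal",
                    "behaviour/extreme") %in% names(specs)))
})

test_that("metric_grid is one row per system x spec, deterministically ordered", {
  sys <- pig_systems(make_systems_df(2))
  g <- metric_grid(sys)
  expect_equal(nrow(g), 60)
  expect_identical(g, g[order(g$system_id, g$metric_id), ],
                   ignore_attr = TRUE)
  expect_error(metric_grid(sys, list()), "at least one")
  dup <- canonical_metric_grid()[c(1, 1)]
  expect_error(metric_grid(sys, dup), "duplicate metric_id")
})
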