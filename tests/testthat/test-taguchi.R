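test_that("smaller-the-better S/N matches hand-evaluated cases", {
  expect_equal(sn_smaller_better(1.0), 0.0)
  expect_equal(sn_smaller_better(0.1), 20.0)
  expect_equal(sn_smaller_better(c(0.1, 0.2, 0.3)), -10 * log10(0.14 / 3))
  expect_identical(sn_smaller_better(c(0, 0)), Inf)
  expect_error(sn_smaller_better(numeric(0)), "at least one")
})

test_that("S/N obeys the scale law sn(c*y) = sn(y) - 20*log10(c)", {
  set.seed(7)
  y <- runif(5, 0.05, 0.5)
  for (cc in c(0.1, 2, 10)) {
    expect_equal(sn_smaller_better(cc * y),
                 sn_smaller_better(y) - 20 * log10(cc), tolerance = 1e-12)
  }
})

test_that("the L18 array is balanced: 9 runs per 2-level, 6 per 3-level setting", {
  d <- taguchi_l18()
  expect_equal(nrow(d), 18)
  expect_equal(as.vector(table(d$socket_arrangement)), c(9, 9))
  for (f in c("roller_speed", "motor_speed", "box_inclination",
              "chute_inclination", "belt_type")) {
    expect_equal(as.vector(table(d[[f]])), c(6, 6, 6))
  }
  expect_error(taguchi_design(data.frame(run = 1:3, f = c("a", "a", "b"))),
               "unbalanced")
})

test_that("a response driven by one factor ranks that factor first, rest at zero delta", {
  d <- taguchi_l18()
  resp <- as.numeric(factor(d$roller_speed, levels = c("50", "150", "250")))
  rs <- taguchi_runset(d, data.frame(run = d$run, response = resp))
  rk <- response_ranks(response_table(rs))
  expect_equal(rk$rank_mean[rk$factor == "roller_speed"], 1L)
  expect_equal(rk$delta_mean[rk$factor != "roller_speed"], rep(0, 5))
  # constant responses tie every factor at rank 1
  rs0 <- taguchi_runset(d, data.frame(run = d$run, response = rep(0.3, 18)))
  rk0 <- response_ranks(response_table(rs0))
  expect_true(all(rk0$rank_mean == 1L))
})

test_that("occurrence-weighted level means recover the grand mean for every factor", {
  d <- taguchi_l18()
  set.seed(11)
  obs <- data.frame(run = rep(d$run, each = 3), response = rnorm(54, 0.25, 0.1))
  rs <- taguchi_runset(d, obs)
  rt <- response_table(rs)
  grand <- mean(rs$runs$run_mean)
  grand_sn <- mean(rs$runs$run_sn)
  for (f in unique(rt$factor)) {
    sub <- rt[rt$factor == f, ]
    expect_equal(weighted.mean(sub$mean, sub$n_runs), grand, tolerance = 1e-9)
    expect_equal(weighted.mean(sub$sn, sub$n_runs), grand_sn, tolerance = 1e-9)
  }
})

test_that("factor SS equals total minus within-level SS by direct enumeration", {
  d <- taguchi_l18()
  set.seed(13)
  obs <- data.frame(run = d$run, response = rnorm(18))
  rs <- taguchi_runset(d, obs)
  rt <- response_table(rs)
  fac_ss <- anova_from_levels(rt, "mean", n_runs_total = 18)
  y <- rs$runs$run_mean
  for (f in unique(rt$factor)) {
    lv <- d[[f]]
    within <- sum(unlist(lapply(split(y, lv), function(g) sum((g - mean(g))^2))))
    total <- sum((y - mean(y))^2)
    expect_equal(fac_ss$ss[fac_ss$factor == f], total - within, tolerance = 1e-9)
  }
  # level means all at the grand mean give SS = 0
  rt0 <- response_table(taguchi_runset(d, data.frame(run = d$run, response = rep(1, 18))))
  expect_true(all(anova_from_levels(rt0, "sn")$ss < 1e-18))
})

test_that("ANOVA partitions total SS and uses 6 error dof on the L18", {
  d <- taguchi_l18()
  set.seed(19)
  rs <- taguchi_runset(d, data.frame(run = d$run, response = rnorm(18, 0.3, 0.05)))
  an <- taguchi_anova(rs, "mean")
  ss_fac <- sum(an$ss[!an$source %in% c("error", "total")])
  expect_equal(ss_fac + an$ss[an$source == "error"],
               an$ss[an$source == "total"], tolerance = 1e-9)
  expect_equal(an$dof[an$source == "error"], 6L)
  expect_true(all(an$ss >= 0))
})

test_that("null responses give uniform ANOVA p-values", {
  d <- taguchi_l18()
  set.seed(29)
  pvals <- replicate(400, {
    rs <- taguchi_runset(d, data.frame(run = d$run, response = rnorm(18)))
    an <- taguchi_anova(rs, "mean")
    an$p[!an$source %in% c("error", "total")]
  })
  ks <- suppressWarnings(ks.test(as.vector(pvals), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a dominant injected factor gets the largest F and smallest p", {
  d <- taguchi_l18()
  set.seed(37)
  effect <- c(`50` = 0, `150` = 1, `250` = 2)[d$motor_speed]
  rs <- taguchi_runset(d, data.frame(run = d$run, response = effect + rnorm(18, 0, 0.05)))
  an <- taguchi_anova(rs, "mean")
  fac <- an[!an$source %in% c("error", "total"), ]
  expect_equal(fac$source[which.max(fac$f)], "motor_speed")
  expect_equal(fac$source[which.min(fac$p)], "motor_speed")
})

test_that("ANOVA recovers an injected effect ranking at moderate noise", {
  d <- taguchi_l18()
  set.seed(41)
  hits <- replicate(200, {
    eff <- c(`50` = 0, `150` = 0.3, `250` = 0.6)[d$roller_speed]
    rs <- taguchi_runset(d, data.frame(run = d$run, response = eff + rnorm(18, 0, 0.1)))
    fac <- taguchi_anova(rs, "mean")
    fac <- fac[!fac$source %in% c("error", "total"), ]
    fac$source[which.max(fac$f)] == "roller_speed"
  })
  expect_gte(mean(hits), 0.95)
})

test_that("optimal-level ties are reported and resolved to the first level", {
  rt <- response_table(tibble::tibble(
    factor = rep("f1", 3), level = c("a", "b", "c"),
    n_runs = c(6, 6, 6), mean = c(0.2, 0.2, 0.5), sn = c(10, 10, 5)))
  opt <- optimal_levels(rt)
  expect_equal(opt$level_by_mean, "a")
  expect_true(opt$tie_mean)
  expect_equal(opt$level_by_sn, "a")
  expect_true(opt$tie_sn)
})
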