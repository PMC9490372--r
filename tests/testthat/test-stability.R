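test_that("environment index centers column means on the grand mean", {
  # 2x2 means [[1,3],[2,4]]: grand mean 2.5, column means 1.5 / 3.5
  tw <- two_way_table(matrix(c(1, 2, 3, 4), 2))
  expect_equal(unname(environment_index(tw)), c(-1, 1))
  tw2 <- two_way_table(matrix(9, 3, 4))
  expect_equal(unname(environment_index(tw2)), rep(0, 4))
  for (seed in 1:10) {
    expect_equal(sum(environment_index(random_table(5, 4, seed))), 0,
                 tolerance = 1e-10)
  }
})

test_that("joint-regression slopes and deviations match the per-genotype least-squares oracle", {
  for (seed in 1:20) {
    tw <- random_table(6, 5, seed)
    er <- er_regression(tw, error_correction = FALSE)
    oracle <- lm_slopes(tw)
    expect_equal(er$bi, unname(oracle[, "bi"]), tolerance = 1e-10)
    expect_equal(er$s2di, unname(oracle[, "dev_ms"]), tolerance = 1e-10)
  }
})

test_that("a genotype tracking the environment means has slope 1 and zero deviations", {
  idx <- c(-2, 0, 1, 1)
  m <- rbind(5 + idx, 3 + idx, 4 + idx)
  er <- er_regression(two_way_table(m), error_correction = FALSE)
  expect_equal(er$bi, rep(1, 3), tolerance = 1e-10)
  expect_equal(er$s2di, rep(0, 3), tolerance = 1e-12)
  # row (0,1,2) against index (-1,0,1): slope 1, residuals 0 by direct
  # least squares on the 3 points
  m2 <- rbind(c(0, 1, 2), c(2, 3, 4), c(-2, -1, 0))  # col means (0,1,2)
  expect_equal(unname(environment_index(two_way_table(m2))), c(-1, 0, 1))
  er2 <- er_regression(two_way_table(m2), error_correction = FALSE)
  expect_equal(er2$bi, c(1, 1, 1), tolerance = 1e-12)
  expect_equal(er2$s2di, c(0, 0, 0), tolerance = 1e-12)
})

test_that("mean slope is 1 and mean Perkins-Jinks slope deviation is 0 on balanced tables", {
  for (seed in 1:25) {
    tw <- random_table(sample(4:9, 1), sample(3:7, 1), seed)
    er <- er_regression(tw, error_correction = FALSE)
    pj <- pj_regression(tw)
    expect_equal(mean(er$bi), 1, tolerance = 1e-10)
    expect_equal(mean(pj$Bi), 0, tolerance = 1e-10)
    expect_equal(pj$Bi, er$bi - 1, tolerance = 1e-10)
  }
})

test_that("deviation conventions differ by the constant pooled-error correction", {
  tw <- random_table(6, 5, seed = 31, error_df = 40,
                     pooled_error_ms = 0.9)
  tw$replicates <- 3L
  er <- er_regression(tw, error_correction = TRUE)
  pj <- pj_regression(tw)
  offset <- pj$dji - er$s2di
  expect_equal(offset, rep(0.9 / 3, 6), tolerance = 1e-10)
})

test_that("ecovalence matches hand-computed residuals and sums to the interaction SS", {
  # 2x2 means [[0,0],[0,1]]: interaction residuals all +-0.25
  tw <- two_way_table(matrix(c(0, 0, 0, 1), 2))
  wi <- wricke_ecovalence(tw)
  expect_equal(unname(wi), c(0.125, 0.125))
  ge <- env_collapsed_anova(tw, basis = "means")
  expect_equal(sum(wi), ge$ss[ge$source == "G x E"], tolerance = 1e-12)
  # additive table: all wi = 0
  add <- two_way_table(5 + outer(c(-1, 0, 1), c(-2, 2, 0), "+"))
  expect_equal(unname(wricke_ecovalence(add)), rep(0, 3),
               tolerance = 1e-12)
  for (seed in 1:25) {
    tw <- random_table(sample(4:9, 1), sample(3:7, 1), seed + 100)
    ge <- env_collapsed_anova(tw, basis = "means")
    expect_equal(sum(wricke_ecovalence(tw)),
                 ge$ss[ge$source == "G x E"], tolerance = 1e-8)
  }
})

test_that("Francis-Kannenberg SD and CV follow the sample-sd definition", {
  tw <- two_way_table(rbind(c(2, 4), c(3, 3)))
  fk <- francis_kannenberg(tw)
  expect_equal(fk$sd, c(sqrt(2), 0), tolerance = 1e-12)
  expect_equal(fk$cv, c(100 * sqrt(2) / 3, 0), tolerance = 1e-12)
  expect_error(francis_kannenberg(two_way_table(rbind(c(-1, 1), c(2, 4)))),
               "zero genotype mean")
})

test_that("adaptation classes follow the slope band crossed with mean performance", {
  cls <- classify_adaptation(bi = c(1, 1.2, 0.7, 1.04),
                             genotype_means = c(5, 6, 4, 5.5),
                             grand_mean = 5.1)
  expect_identical(cls$slope_class,
                   c("average", "favorable", "unfavorable", "average"))
  expect_identical(cls$performance[2], "above-average")
  expect_match(cls$adaptation[3], "unfavorable environments")
})

test_that("the assembled stability table is internally consistent", {
  sim <- simulate_met(seed = 21)
  tw <- cell_means(sim$data, "yield")
  st <- stability_table(tw)
  expect_identical(nrow(st), 13L)
  expect_equal(st$Bi, st$bi - 1, tolerance = 1e-12)
  expect_equal(mean(st$bi), 1, tolerance = 1e-10)
  expect_equal(sum(st$wi),
               env_collapsed_anova(tw, "means")$ss[3], tolerance = 1e-8)
  expect_true(all(st$wi >= 0))
  expect_true(all(c("t_bi", "p_bi", "f_s2di", "p_s2di") %in% names(st)))
})

test_that("degenerate tables are rejected with informative errors", {
  flat <- two_way_table(matrix(4, 3, 4))
  expect_error(er_regression(flat), "no variance")
  expect_error(pj_regression(flat), "no variance")
  expect_error(er_regression(two_way_table(matrix(rnorm(6), 3, 2))),
               "at least 3 environments")
})
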