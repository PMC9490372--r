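test_that("an additive table yields all-zero singular values", {
  m <- 5 + outer(c(-1, 0, 1), c(-2, 0, 1, 1), "+")
  fit <- fit_ammi(two_way_table(m))
  expect_equal(fit$singular_values, rep(0, 2), tolerance = 1e-10)
  co <- ammi1_coords(fit)
  expect_equal(co$ipca1, rep(0, 7), tolerance = 1e-10)
})

test_that("the decomposition reconstructs the table exactly and satisfies the SVD identities", {
  for (seed in 1:15) {
    tw <- random_table(sample(4:8, 1), sample(4:7, 1), seed + 200)
    fit <- fit_ammi(tw, basis = "means")
    # Sum lambda^2 = interaction SS (Eckart-Young identity)
    ge <- env_collapsed_anova(tw, basis = "means")
    expect_equal(sum(fit$singular_values^2),
                 ge$ss[ge$source == "G x E"], tolerance = 1e-8)
    # full reconstruction equals the cell means
    expect_equal(ammi_fitted(fit), tw$means, tolerance = 1e-8)
    # orthonormal scores
    n <- length(fit$singular_values)
    expect_equal(crossprod(fit$genotype_scores), diag(n),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(crossprod(fit$environment_scores), diag(n),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # main effects sum to zero
    expect_equal(sum(fit$genotype_effects), 0, tolerance = 1e-10)
    expect_equal(sum(fit$environment_effects), 0, tolerance = 1e-10)
  }
})

test_that("coordinates of a 3x3 table match a direct SVD oracle", {
  m <- matrix(c(4, 5, 9, 2, 8, 5, 7, 6, 1), 3)
  tw <- two_way_table(m)
  z <- sweep(sweep(m, 1, rowMeans(m)), 2, colMeans(m)) + mean(m)
  dec <- svd(z)
  fit <- fit_ammi(tw)
  expect_equal(fit$singular_values, dec$d[1:2], tolerance = 1e-10)
  co1 <- ammi1_coords(fit)
  gen <- co1[co1$entity == "genotype", ]
  expect_equal(gen$mean, rowMeans(m), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(abs(gen$ipca1),
               abs(sqrt(dec$d[1]) * dec$u[, 1]), tolerance = 1e-10,
               ignore_attr = TRUE)
  # genotype with the largest main effect sits rightmost
  expect_identical(gen$label[which.max(gen$mean)],
                   tw$genotypes[which.max(rowMeans(m))])
})

test_that("Gollob df, percent-explained and df bookkeeping hold for the IPCA partition", {
  expect_identical(gollob_df(13, 8, 1), 18L)
  expect_identical(gollob_df(13, 8, 2), 16L)
  tw <- random_table(13, 8, seed = 77)
  fit <- fit_ammi(tw)
  n_full <- length(fit$singular_values)
  # Gollob df over all components sums to (g-1)(e-1)
  expect_identical(sum(gollob_df(13, 8, seq_len(n_full))), 84L)
  at <- ammi_anova(fit, n_axes = n_full)
  ipca <- grepl("^IPCA", at$source)
  expect_equal(sum(at$pct_explained[ipca]), 100, tolerance = 1e-8)
  expect_equal(at$ss[at$source == "Residual"], 0, tolerance = 1e-8)
  at2 <- ammi_anova(fit, n_axes = 2)
  expect_identical(at2$df[at2$source %in% c("IPCA1", "IPCA2")],
                   c(18L, 16L))
  expect_equal(sum(at2$ss[grepl("IPCA|Residual", at2$source)]),
               at2$ss[at2$source == "G x E"], tolerance = 1e-8)
  expect_error(ammi_anova(fit, n_axes = n_full + 1), "exceeds")
})

test_that("plot-basis singular values square-sum to the plot interaction SS and F uses pooled error", {
  sim <- simulate_met(g = 6, n_locations = 3, n_years = 2, r = 3,
                      seed = 55)
  tw <- cell_means(sim$data, "yield")
  fit <- fit_ammi(tw, basis = "plot")
  ge <- env_collapsed_anova(tw, basis = "plot")
  expect_equal(sum(fit$singular_values^2),
               ge$ss[ge$source == "G x E"], tolerance = 1e-8)
  at <- ammi_anova(fit, n_axes = 2)
  i1 <- at$source == "IPCA1"
  expect_equal(at$f[i1], at$ms[i1] / tw$pooled_error_ms,
               tolerance = 1e-10)
})

test_that("AMMI2 distances are sign-invariant and rank zero-interaction genotypes most stable", {
  tw <- random_table(6, 5, seed = 91)
  # a row that is a constant offset of the mean of the other rows has
  # zero interaction residuals
  m <- tw$means
  m[3, ] <- 2 + colMeans(m[-3, ])
  tw <- two_way_table(m)
  fit <- fit_ammi(tw)
  co <- ammi2_coords(fit)
  gen <- co[co$entity == "genotype", ]
  expect_identical(gen$label[gen$stability_rank == 1], "G03")
  expect_equal(gen$distance[gen$label == "G03"], 0, tolerance = 1e-8)
  # distances are invariant to flipping any component's sign
  flipped <- fit
  flipped$genotype_scores[, 1] <- -flipped$genotype_scores[, 1]
  flipped$environment_scores[, 1] <- -flipped$environment_scores[, 1]
  co2 <- ammi2_coords(flipped)
  expect_equal(co$distance, co2$distance, tolerance = 1e-12)
  # rank-1 model: ipca2 = 0 and distance = |ipca1|
  sim <- simulate_met(g = 5, n_locations = 5, n_years = 1, r = 1,
                      interaction_rank = 1, interaction_sds = 2,
                      error_sd = 0, seed = 14)
  tw1 <- suppressWarnings(cell_means(sim$data, "yield"))
  co3 <- ammi2_coords(fit_ammi(tw1))
  expect_equal(co3$ipca2, rep(0, nrow(co3)), tolerance = 1e-8)
  expect_equal(co3$distance, abs(co3$ipca1), tolerance = 1e-8)
})

test_that("a noisy rank-2 interaction subspace is recovered by the leading components", {
  # principal angles between implanted and estimated score planes < 5 deg
  # with cell error at one tenth of the smaller component's per-cell
  # scale (lambda_2 / sqrt(g e) / 10 here)
  for (seed in 1:50) {
    sim <- simulate_met(g = 8, n_locations = 3, n_years = 2, r = 1,
                        interaction_rank = 2, interaction_sds = c(3, 2),
                        error_sd = 0.1 * 2 / sqrt(8 * 6),
                        seed = seed + 400)
    tw <- suppressWarnings(cell_means(sim$data, "yield"))
    fit <- fit_ammi(tw)
    est <- fit$genotype_scores[, 1:2]
    true <- sim$truth$genotype_scores
    angles <- acos(pmin(1, svd(crossprod(true, est))$d))
    expect_lt(max(angles) * 180 / pi, 5)
  }
})
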