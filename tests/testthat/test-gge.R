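test_that("environment-centering keeps G + GE: zero column means and the SS identity", {
  for (seed in 1:15) {
    tw <- random_table(sample(4:8, 1), sample(3:6, 1), seed + 300)
    fit <- fit_gge(tw)
    expect_equal(colMeans(fit$centered),
                 rep(0, ncol(fit$centered)), tolerance = 1e-10,
                 ignore_attr = TRUE)
    ge <- env_collapsed_anova(tw, basis = "means")
    ss_g_ge <- sum(ge$ss[ge$source %in% c("Genotype", "G x E")])
    expect_equal(sum(fit$singular_values^2), ss_g_ge, tolerance = 1e-8)
  }
})

test_that("a table with pure environment effects has all singular values zero", {
  m <- 4 + outer(rep(0, 4), c(-1, 0, 3), "+")
  fit <- fit_gge(two_way_table(m))
  expect_equal(fit$singular_values, rep(0, 3), tolerance = 1e-12)
})

test_that("markers of a 3x3 table match the direct SVD oracle under every SVP mode", {
  m <- matrix(c(4, 5, 9, 2, 8, 5, 7, 6, 1), 3)
  tw <- two_way_table(m)
  p <- sweep(m, 2, colMeans(m))
  dec <- svd(p)
  for (mode in c("symmetric", "genotype", "environment")) {
    fit <- fit_gge(tw, svp = mode)
    a <- switch(mode, genotype = 1, environment = 0, symmetric = 0.5)
    gexp <- sweep(dec$u[, 1:2], 2, dec$d[1:2]^a, `*`)
    eexp <- sweep(dec$v[, 1:2], 2, dec$d[1:2]^(1 - a), `*`)
    expect_equal(abs(unname(fit$genotype_markers)), abs(gexp),
                 tolerance = 1e-10)
    expect_equal(abs(unname(fit$environment_markers)), abs(eexp),
                 tolerance = 1e-10)
    # rank-2 marker product approximates P with Eckart-Young error
    approx <- fit$genotype_markers %*% t(fit$environment_markers)
    expect_equal(sum((p - approx)^2), sum(dec$d[-(1:2)]^2),
                 tolerance = 1e-8)
  }
})

test_that("sd-scaling divides columns by their sd and flags zero-variance environments", {
  tw <- random_table(5, 4, seed = 61)
  fit <- fit_gge(tw, scaling = "sd")
  manual <- sweep(sweep(tw$means, 2, tw$environment_means), 2,
                  apply(tw$means, 2, sd), `/`)
  expect_equal(fit$centered, manual, tolerance = 1e-12)
  bad <- tw$means
  bad[, 2] <- 3
  expect_error(fit_gge(two_way_table(bad), scaling = "sd"), "ENV2")
})

test_that("which-won-where winners equal the rank-2 argmax oracle across random tables", {
  n_checked <- 0L
  for (seed in 1:100) {
    g <- sample(5:8, 1)
    e <- sample(4:6, 1)
    tw <- random_table(g, e, seed + 500)
    fit <- fit_gge(tw, svp = "symmetric")
    part <- which_won_where(fit)
    recon <- fit$genotype_markers %*% t(fit$environment_markers)
    oracle <- rownames(recon)[apply(recon, 2, which.max)]
    expect_identical(part$winners$winner, oracle)
    # every environment in exactly one sector; winners are hull members
    expect_identical(sort(part$winners$environment),
                     sort(tw$environments))
    expect_true(all(part$winners$winner %in% part$hull))
    n_checked <- n_checked + 1L
  }
  expect_identical(n_checked, 100L)
})

test_that("a uniformly dominant genotype wins every environment", {
  set.seed(9)
  m <- matrix(rnorm(24, 10, 0.3), 6, 4)
  m[2, ] <- m[2, ] + 50  # overwhelming genotype main effect
  part <- which_won_where(fit_gge(two_way_table(m)))
  expect_true(all(part$winners$winner == "G02"))
})

test_that("collinear genotype markers raise the degenerate-geometry error", {
  # rank-1 G+GE structure: markers lie on a line through the origin
  m <- 4 + outer(c(-2, -1, 0, 1, 2), c(1, 2, 3))
  expect_error(which_won_where(fit_gge(two_way_table(m))),
               "collinear")
})

test_that("an additive offset genotype tops the AEC projection with zero instability", {
  set.seed(17)
  base <- matrix(rnorm(20, 8, 1), 5, 4)
  base[3, ] <- colMeans(base[-3, ]) + 2  # uniformly +2 over env means
  tw <- two_way_table(base)
  fit <- fit_gge(tw, svp = "genotype")
  ms <- mean_vs_stability(fit)
  top <- ms$scores[1, ]
  expect_identical(top$genotype, "G03")
  # its marker has (near) zero perpendicular component
  expect_lt(abs(top$stability_projection) / max(abs(ms$scores$mean_projection)),
            0.05)
  # and it is ranked first against the ideal point
  rk <- rank_genotypes(fit)
  expect_identical(rk$genotype[1], "G03")
})

test_that("projections reconstruct the markers and are rotation-invariant", {
  tw <- random_table(6, 5, seed = 71)
  fit <- fit_gge(tw, svp = "genotype")
  ms <- mean_vs_stability(fit)
  d <- ms$direction
  expect_equal(sum(d^2), 1, tolerance = 1e-12)
  perp <- c(-d[2], d[1])
  sc <- ms$scores[match(rownames(fit$genotype_markers),
                        ms$scores$genotype), ]
  rebuilt <- outer(sc$mean_projection, d) +
    outer(sc$stability_projection, perp)
  expect_equal(rebuilt, unname(fit$genotype_markers), tolerance = 1e-10,
               ignore_attr = TRUE)
  # rotating the whole marker set leaves projections unchanged
  th <- 0.83
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  fit2 <- fit
  fit2$genotype_markers <- fit$genotype_markers %*% rot
  fit2$environment_markers <- fit$environment_markers %*% rot
  ms2 <- mean_vs_stability(fit2)
  expect_equal(ms2$scores$mean_projection, ms$scores$mean_projection,
               tolerance = 1e-10)
  expect_equal(abs(ms2$scores$stability_projection),
               abs(ms$scores$stability_projection), tolerance = 1e-10)
})

test_that("genotype ranking matches a brute-force distance computation", {
  tw <- random_table(4, 3, seed = 81)
  fit <- fit_gge(tw, svp = "genotype")
  rk <- rank_genotypes(fit)
  d <- mean_vs_stability(fit)$direction
  gm <- fit$genotype_markers
  ideal <- d * max(gm %*% d)
  dist <- sqrt(colSums((t(gm) - ideal)^2))
  expect_identical(rk$genotype, names(sort(dist)))
  expect_equal(sort(rk$distance), unname(sort(dist)), tolerance = 1e-10)
})

test_that("discriminativeness is the marker norm and representativeness its AEC cosine", {
  tw <- random_table(6, 5, seed = 86)
  fit <- fit_gge(tw, svp = "environment")
  dr <- discrimination_representativeness(fit)
  em <- fit$environment_markers
  expect_equal(dr$vector_length, unname(sqrt(rowSums(em^2))),
               tolerance = 1e-12)
  d <- mean_vs_stability(fit)$direction
  expect_equal(dr$cos_angle,
               unname(as.numeric(em %*% d) / sqrt(rowSums(em^2))),
               tolerance = 1e-12)
  expect_identical(sum(dr$ideal), 1L)
  expect_identical(dr$environment[dr$ideal],
                   dr$environment[which.max(dr$vector_length * dr$cos_angle)])
  # genotype-marker norms are bounded by SS_G + SS_GE, equal iff rank <= 2
  fitg <- fit_gge(tw, svp = "genotype")
  ge <- env_collapsed_anova(tw, basis = "means")
  ss_g_ge <- sum(ge$ss[ge$source %in% c("Genotype", "G x E")])
  expect_lte(sum(fitg$genotype_markers^2), ss_g_ge + 1e-8)
  expect_equal(sum(fitg$genotype_markers^2),
               sum(fit$singular_values[1:2]^2), tolerance = 1e-8)
})

test_that("an environment with an all-zero centered column has zero vector length", {
  set.seed(23)
  m <- matrix(rnorm(15), 5, 3)
  m[, 2] <- 7  # no genotype differences in ENV2
  fit <- fit_gge(two_way_table(m), svp = "environment")
  dr <- discrimination_representativeness(fit)
  expect_equal(dr$vector_length[2], 0, tolerance = 1e-10)
  expect_true(is.na(dr$cos_angle[2]))
})
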