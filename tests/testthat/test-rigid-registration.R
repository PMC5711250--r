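test_that("Euler angles and rotation matrices round-trip", {
  set.seed(3)
  for (i in 1:50) {
    ang <- runif(3, -60, 60)
    R <- euler_to_matrix(ang)
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
    expect_equal(matrix_to_euler(R), ang, tolerance = 1e-9)
  }
  expect_error(matrix_to_euler(diag(c(1, 1, -1))), "reflection")
})

test_that("apply_transform is rigid and invertible", {
  set.seed(4)
  p <- test_constellation()
  tf <- random_transform(p, max_t = 20, max_r = 30)
  q <- apply_transform(tf, p)
  # pairwise distances preserved
  expect_equal(as.numeric(dist(q)), as.numeric(dist(p)), tolerance = 1e-10)
  back <- apply_transform(invert_transform(tf), q)
  expect_lt(max(abs(back - p)), 1e-12)
  expect_equal(apply_transform(rigid_transform(), p), p,
               ignore_attr = TRUE)
})

test_that("fit_rigid recovers noiseless transforms exactly", {
  set.seed(5)
  p <- test_constellation()
  expect_error(fit_rigid(p[1:2, ], p[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(fit_rigid(line, line), "collinear")
  id <- fit_rigid(p, p)
  expect_lt(max(abs(id$rotations_deg)), 1e-10)
  expect_lt(max(abs(id$translations_mm)), 1e-10)
  for (i in 1:20) {
    tf <- random_transform(p)
    q <- apply_transform(tf, p)
    fit <- fit_rigid(p, q)
    expect_equal(fit$rotations_deg, tf$rotations_deg, tolerance = 1e-9)
    expect_equal(fit$translations_mm, tf$translations_mm, tolerance = 1e-9)
  }
})

test_that("fitted transform beats random rigid candidates", {
  set.seed(6)
  p <- test_constellation()
  tf <- random_transform(p)
  q <- apply_transform(tf, p) +
    matrix(rnorm(length(p), 0, 0.8), nrow(p), 3)
  fit <- fit_rigid(p, q)
  ss_fit <- sum((apply_transform(fit, p) - q)^2)
  for (i in 1:1000) {
    cand <- rigid_transform(
      fit$rotations_deg + rnorm(3, 0, 0.5),
      fit$translations_mm + rnorm(3, 0, 0.5),
      fit$center_mm)
    expect_gte(sum((apply_transform(cand, p) - q)^2), ss_fit - 1e-9)
  }
})

test_that("residuals vanish for exact rigid data and are equivariant", {
  set.seed(7)
  p <- test_constellation()
  tf <- random_transform(p)
  q <- apply_transform(tf, p)
  res <- residual_displacements(p, q)
  expect_lt(max(res$distances_mm), 1e-9)
  expect_equal(res$median_mm, 0, tolerance = 1e-9)
  # perturb one marker: residual summary matches a brute-force refit
  q2 <- q
  q2[4, ] <- q2[4, ] + c(0, 1, 0)
  fit2 <- fit_rigid(p, q2)
  res2 <- residual_displacements(p, q2, fit2)
  expect_equal(res2$median_mm, oracle_median(res2$distances_mm))
  # rotating both sets by a common rigid map leaves residuals unchanged
  g <- rigid_transform(c(10, -5, 20), c(30, -10, 5))
  res3 <- residual_displacements(apply_transform(g, p),
                                 apply_transform(g, q2))
  expect_equal(sort(res3$distances_mm), sort(res2$distances_mm),
               tolerance = 1e-8)
})

test_that("worst session is the one with maximum mean 3D distance", {
  p <- test_constellation()
  s1 <- sweep(p, 2, c(0, 5, 4))   # mean distance 6.4 mm
  s2 <- sweep(p, 2, c(2, 8, 11))  # mean distance 13.7 mm
  ws <- worst_session(p, list(s1, s2))
  expect_identical(ws$session, 2L)
  expect_equal(ws$mean_distance_mm, c(sqrt(41), sqrt(189)))
  expect_identical(worst_session(p, list(s1))$session, 1L)
  # tie broken towards the earliest session
  expect_identical(worst_session(p, list(s1, s1))$session, 1L)
})

test_that("population error decomposition is definitional", {
  tbl <- data.frame(patient = rep(1:3, each = 2),
                    t_cc = c(1, 1, 2, 2, 3, 3))
  pe <- population_errors(tbl)
  expect_equal(pe$M, 2)
  expect_equal(pe$Sigma, 1)
  expect_equal(pe$sigma, 0)
  # two patients, equal means, within-patient SDs 3 and 4
  tbl2 <- data.frame(patient = rep(1:2, each = 2),
                     t_ap = c(-3, 3, -4, 4) / sd(c(-1, 1)))
  pe2 <- population_errors(tbl2)
  expect_equal(pe2$Sigma, 0)
  expect_equal(pe2$sigma, sqrt((9 + 16) / 2))
  expect_error(population_errors(data.frame(patient = 1:2, x = c(1, 2))),
               ">= 2 breath holds")
  expect_error(population_errors(data.frame(patient = c(1, 1), x = c(1, 2))),
               ">= 2 patients")
})

test_that("translation error scales like noise over sqrt(markers)", {
  set.seed(9)
  p <- test_constellation()
  s <- 0.5
  n_rep <- 400
  terr <- matrix(NA_real_, n_rep, 3)
  tf <- random_transform(p)
  for (i in seq_len(n_rep)) {
    q <- apply_transform(tf, p) + matrix(rnorm(length(p), 0, s), nrow(p), 3)
    fit <- fit_rigid(p, q)
    terr[i, ] <- fit$translations_mm - tf$translations_mm
  }
  rmse <- sqrt(colMeans(terr^2))
  expect_true(all(abs(rmse - s / 3) / (s / 3) < 0.2))
})
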