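test_that("reduced system has the promised algebraic structure", {
  inst <- rand_instance(50, 20, 6, 5, seed = 41)
  sys <- build_reduced_system(inst$Y, inst$D, inst$P, var_retained = 1)
  expect_equal(sys$G, crossprod(inst$Y, inst$D))
  expect_lt(max(abs(sys$B - t(sys$B))), 1e-10)
  expect_equal(crossprod(sys$V_k), diag(ncol(sys$V_k)), tolerance = 1e-10)
  # orthonormal-column Y gives B = identity
  qy <- qr.Q(qr(inst$Y))
  dimnames(qy) <- dimnames(inst$Y)
  sys2 <- build_reduced_system(qy, inst$D, inst$P, var_retained = 1)
  expect_equal(sys2$B, diag(20), ignore_attr = TRUE, tolerance = 1e-10)
  # full-rank reduction reconstructs P exactly
  expect_equal(sys$P_red %*% t(sys$V_k), inst$P, ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("SVD truncation error is bounded by the discarded variance", {
  inst <- rand_instance(50, 20, 5, 12, seed = 42)
  for (vr in c(0.7, 0.9, 0.95)) {
    sys <- build_reduced_system(inst$Y, inst$D, inst$P, var_retained = vr)
    rel <- sum((inst$P - sys$P_red %*% t(sys$V_k))^2) / sum(inst$P^2)
    expect_lte(rel, 1 - vr + 1e-12)
  }
})

test_that("compressed ridge equals the explicit Kronecker oracle", {
  # the 6-gene/4-cell/3-TF/2-protein instance, with and without reduction
  inst <- rand_instance(6, 4, 3, 2, seed = 43)
  Wo <- kron_ridge_oracle(inst$Y, inst$D, inst$P, 0.1)
  for (vr in list(1, NULL)) {
    sys <- build_reduced_system(inst$Y, inst$D, inst$P, var_retained = vr)
    W <- solve_ridge_reduced(sys, 0.1)$W
    expect_lt(norm(W - Wo, "F") / norm(Wo, "F"), 1e-10)
  }
  # SVD safety: var_retained = 1 identical to no reduction on a larger case
  inst2 <- rand_instance(40, 15, 8, 6, seed = 44)
  s1 <- build_reduced_system(inst2$Y, inst2$D, inst2$P, var_retained = 1)
  s0 <- build_reduced_system(inst2$Y, inst2$D, inst2$P, var_retained = NULL)
  expect_lt(norm(solve_ridge_reduced(s1, 0.05)$W -
                 solve_ridge_reduced(s0, 0.05)$W, "F"), 1e-8)
})

test_that("ridge shrinks monotonically and dies at large lambda2", {
  inst <- rand_instance(30, 12, 4, 3, seed = 45)
  sys <- build_reduced_system(inst$Y, inst$D, inst$P, var_retained = 1)
  norms <- vapply(10^seq(-2, 6, by = 1),
                  function(l) norm(solve_ridge_reduced(sys, l)$W, "F"),
                  numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
  expect_lt(norms[length(norms)], 1e-3 * norms[1])
})

test_that("singular system at lambda2 = 0 is refused with advice", {
  inst <- rand_instance(30, 12, 4, 3, seed = 46)
  P_dup <- cbind(inst$P, inst$P[, 1, drop = FALSE])   # collinear proteins
  colnames(P_dup) <- c(colnames(inst$P), "dup")
  sys <- build_reduced_system(inst$Y, inst$D, P_dup, var_retained = NULL)
  expect_error(solve_ridge_reduced(sys, 0), "lambda2 > 0")
})

test_that("elastic net matches ridge at lambda1 = 0 and obeys the kill level", {
  inst <- rand_instance(30, 12, 4, 3, seed = 47)
  sys <- build_reduced_system(inst$Y, inst$D, inst$P, var_retained = 1)
  Wr <- solve_ridge_reduced(sys, 0.1)$W
  en <- solve_elastic_net(sys, 0, 0.1)
  expect_true(en$converged)
  expect_lt(norm(en$W - Wr, "F") / norm(Wr, "F"), 1e-6)
  lmax <- lambda_max(sys)
  expect_true(all(solve_elastic_net(sys, lmax * 1.000001, 0.1)$W == 0))
  expect_gt(sum(solve_elastic_net(sys, lmax * 0.5, 0.1)$W != 0), 0)
})

test_that("zeros are non-decreasing along the lambda1 path", {
  inst <- rand_instance(40, 15, 5, 4, seed = 48)
  sys <- build_reduced_system(inst$Y, inst$D, inst$P, var_retained = 1)
  lmax <- lambda_max(sys)
  path <- lmax * 10^seq(-4, 0, length.out = 10)
  zeros <- vapply(path, function(l1)
    sum(solve_elastic_net(sys, l1, 0.1)$W == 0), numeric(1))
  expect_true(all(diff(zeros) >= 0))
  expect_identical(zeros[10], 20)                 # at lambda_max all dead
})

test_that("elastic-net solution is a minimum of the explicit objective", {
  inst <- rand_instance(20, 8, 4, 3, seed = 49)   # Q*S = 12
  sys <- build_reduced_system(inst$Y, inst$D, inst$P, var_retained = 1)
  fit <- solve_elastic_net(sys, 0.3, 0.2, tol = 1e-10)
  f0 <- compressed_objective(fit$W, inst$Y, inst$D, inst$P, 0.3, 0.2)
  withr::with_seed(50, {
    worse <- replicate(10000, {
      delta <- matrix(rnorm(12, sd = sample(c(1e-4, 1e-2, 0.3), 1)), 4, 3)
      compressed_objective(fit$W + delta, inst$Y, inst$D, inst$P, 0.3, 0.2)
    })
  })
  expect_true(all(worse >= f0 - 1e-9))
})

test_that("planted interaction matrices are recovered from noisy data", {
  cfg <- sim_config(200, 100, 20, 10, prior_density = 0.1, snr = 10, seed = 1)
  inst <- generate_instance(cfg)
  fit <- fit_affinity(inst$Y, inst$D, inst$P_latent, lambda2 = 1e-6,
                      var_retained = 1)
  expect_gte(cor(as.vector(fit$W), as.vector(inst$W_star)), 0.9)
})

test_that("noise-free identifiable instances are recovered exactly", {
  cfg <- sim_config(200, 100, 20, 20, prior_density = 0.1, noise_sd = 0,
                    seed = 1)
  inst <- generate_instance(cfg)
  fit <- fit_affinity(inst$Y, inst$D, inst$P_latent, lambda2 = 1e-10,
                      var_retained = 1)
  expect_lt(norm(fit$W - inst$W_star, "F") / norm(inst$W_star, "F"), 1e-4)
  rho <- spearman_per_cell(predict_expression(fit, inst$D, inst$P_latent),
                           inst$Y)$rho
  expect_true(all(rho == 1))
})

test_that("prediction is the bilinear map and validates feature ids", {
  inst <- rand_instance(20, 8, 4, 3, seed = 51)
  sys <- build_reduced_system(inst$Y, inst$D, inst$P, var_retained = 1)
  fit <- solve_ridge_reduced(sys, 0.1)
  zero <- fit; zero$W[] <- 0
  expect_true(all(predict_expression(zero, inst$D, inst$P) == 0))
  # indicator protein profile selects a column of D W
  e1 <- matrix(0, 1, 3, dimnames = list("new", colnames(inst$P)))
  e1[1, 1] <- 1
  expect_equal(predict_expression(fit, inst$D, e1)[, 1],
               (inst$D %*% fit$W)[, 1], ignore_attr = TRUE)
  bad <- inst$P; colnames(bad) <- c("x1", "x2", "x3")
  expect_error(predict_expression(fit, inst$D, bad), "protein-id mismatch")
})

test_that("cross-validation is seeded, deterministic and tie-broken", {
  inst <- rand_instance(60, 25, 5, 4, seed = 52)
  g1 <- data.frame(lambda1 = 0, lambda2 = 0.01)
  cv1 <- cross_validate(inst$Y, inst$D, inst$P, g1, folds = 5, seed = 9)
  expect_identical(cv1$best$lambda2, 0.01)        # single point wins
  cv2 <- cross_validate(inst$Y, inst$D, inst$P, g1, folds = 5, seed = 9)
  expect_identical(cv1$fold_assignment, cv2$fold_assignment)
  expect_identical(cv1$grid$mean_score, cv2$grid$mean_score)
  expect_error(cross_validate(inst$Y, inst$D, inst$P,
                              data.frame(lambda1 = numeric(),
                                         lambda2 = numeric())),
               "empty")
})

test_that("CV selects a noise-appropriate penalty on planted data", {
  cfg <- sim_config(200, 100, 20, 10, prior_density = 0.1, snr = 10, seed = 7)
  inst <- generate_instance(cfg)
  al <- align_and_unit_normalize(inst$Y, inst$P_latent, inst$D)
  cv <- cross_validate(al$Y, al$D, al$P,
                       grid = expand.grid(lambda1 = 0,
                                          lambda2 = c(1e-6, 1e-2, 1)),
                       folds = 5, seed = 7, var_retained = 1)
  tab <- cv$grid
  expect_gt(cv$best$mean_score, tab$mean_score[tab$lambda2 == 1])
  expect_true(cv$best$lambda2 < 1)
})
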