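test_that("a rank-1 matrix is fully explained by the first component", {
  r1 <- rank1_matrix(8L, 20L, seed = 3L)
  m <- fit_cca(r1$X, n_components = 2L)
  expect_equal(m$explained[1], 1, tolerance = 1e-10)
  expect_equal(abs(cor(m$scores[, 1], r1$u)), 1, tolerance = 1e-10)
  expect_equal(m$explained[2], 0, tolerance = 1e-10)
  expect_true(all(m$converged))
  # cross-check against the SVD: CC1 must be the single latent direction
  sv <- svd(r1$X)
  expect_equal(abs(sum(m$t_unit[, 1] * sv$u[, 1])), 1, tolerance = 1e-8)
})

test_that("identical columns receive identical first-component saliences", {
  X <- random_centered_matrix(9L, 12L, seed = 8L)
  X[, 2] <- X[, 1]
  m <- fit_cca(X, 1L)
  expect_equal(m$saliences[1, 1], m$saliences[2, 1], tolerance = 1e-10)
})

test_that("the converged solution satisfies both fixed-point conditions", {
  X <- random_centered_matrix(10L, 30L, seed = 21L)
  m <- fit_cca(X, 1L)
  t1 <- m$t_unit[, 1]
  lam <- as.vector(crossprod(X, t1))^2
  lam <- lam / sum(lam)
  expect_lt(max(abs(lam - m$saliences[, 1])), 1e-6)
  W <- tcrossprod(X * rep(lam, each = nrow(X)), X)
  e <- eigen(W, symmetric = TRUE)$vectors[, 1]
  expect_lt(1 - abs(sum(e * t1)), 1e-6)
})

test_that("score columns are orthogonal and deflation strictly reduces the residual", {
  X <- random_centered_matrix(10L, 60L, seed = 5L)
  m <- fit_cca(X, 3L)
  G <- crossprod(m$t_unit)
  expect_lt(max(abs(G[lower.tri(G)])), 1e-8)
  norms <- vapply(1:3, function(k)
    sum(ccadigest:::working_matrix(m, k)^2), numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_true(all(m$explained >= 0))
  expect_lte(sum(m$explained), 1 + 1e-8)
})

test_that("fitting is deterministic and flipping a component changes nothing downstream", {
  X <- random_centered_matrix(10L, 25L, seed = 13L)
  m1 <- fit_cca(X, 2L)
  m2 <- fit_cca(X, 2L)
  expect_identical(m1$scores, m2$scores)
  expect_identical(m1$saliences, m2$saliences)
  # sign convention: largest-magnitude loading is positive
  for (k in 1:2) {
    lk <- m1$loadings[, k]
    expect_gt(lk[which.max(abs(lk))], 0)
  }
  # selection is invariant under a sign flip of scores + loadings
  sp <- splot(m1, 1L)
  sel <- select_otus(sp)
  flipped <- m1
  flipped$scores[, 1] <- -flipped$scores[, 1]
  flipped$t_unit[, 1] <- -flipped$t_unit[, 1]
  flipped$loadings[, 1] <- -flipped$loadings[, 1]
  sel_f <- select_otus(splot(flipped, 1L))
  expect_identical(sel$otu_id, sel_f$otu_id)
  expect_equal(abs(sel$covariance), abs(sel_f$covariance))
})

test_that("uncentered input is rejected", {
  X <- random_centered_matrix(8L, 10L)
  X[, 3] <- X[, 3] + 0.5
  expect_error(fit_cca(X), "not column-centered")
  expect_error(fit_cca(random_centered_matrix(5L, 10L), n_components = 5L),
               "n_components")
})

test_that("S-plot covariances and correlations match a direct two-pass computation", {
  X <- random_centered_matrix(10L, 40L, seed = 17L)
  m <- fit_cca(X, 2L)
  for (k in 1:2) {
    sp <- splot(m, k)
    Xk <- ccadigest:::working_matrix(m, k)
    tk <- m$scores[, k]
    n <- length(tk)
    for (j in c(1L, 7L, 40L)) {
      cov_direct <- sum(Xk[, j] * tk) / (n - 1)
      corr_direct <- cov_direct / (sd(Xk[, j]) * sd(tk))
      expect_equal(sp$covariance[j], cov_direct, tolerance = 1e-12)
      expect_equal(sp$correlation[j], corr_direct, tolerance = 1e-12)
    }
    nz <- sp$covariance != 0 & sp$correlation != 0
    expect_identical(sign(sp$covariance[nz]), sign(sp$correlation[nz]))
    expect_true(all(abs(sp$correlation) <= 1 + 1e-12))
  }
})

test_that("in a rank-1 matrix every variable correlates perfectly with CC1", {
  r1 <- rank1_matrix(8L, 15L, seed = 9L)
  m <- fit_cca(r1$X, 1L)
  sp <- splot(m, 1L)
  expect_equal(abs(sp$correlation), rep(1, 15L), tolerance = 1e-8)
})

test_that("the one-SD covariance rule selects exactly the documented set", {
  sp <- fake_splot(c(0, 0, 0, 0, 10))
  sel <- select_otus(sp)
  # sd(c(0,0,0,0,10)) = sqrt(20) ~= 4.47: only the 10 passes
  expect_equal(attr(sel, "threshold"), sqrt(20))
  expect_identical(sel$otu_id, "otu_05")
  expect_identical(sel$sign, 1L)

  # all-equal covariances: zero spread, empty selection by convention
  expect_identical(nrow(select_otus(fake_splot(rep(2, 6)))), 0L)

  # negative covariance gets a negative sign tag
  sel_neg <- select_otus(fake_splot(c(0, 0, 0, 0, -10)))
  expect_identical(sel_neg$sign, -1L)
})

test_that("selection is invariant under global rescaling of the input", {
  X <- random_centered_matrix(10L, 30L, seed = 33L)
  sel1 <- select_otus(splot(fit_cca(X, 1L), 1L))
  sel2 <- select_otus(splot(fit_cca(X * 7.3, 1L), 1L))
  expect_identical(sel1$otu_id, sel2$otu_id)
  expect_identical(sel1$sign, sel2$sign)
})
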