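test_that("the DCT starting dictionary is unit-norm, flat-first and deterministic", {
  A <- init_dictionary(36, 144)
  expect_equal(dim(A), c(36L, 144L))
  expect_lt(max(abs(sqrt(colSums(Mod(A)^2)) - 1)), 1e-12)
  expect_lt(max(Mod(A[, 1] - 1 / 6)), 1e-12)   # constant atom
  expect_identical(A, init_dictionary(36, 144))
  # non-square J falls back to the first J columns, still unit-norm
  A2 <- init_dictionary(16, 20)
  expect_equal(ncol(A2), 20L)
  expect_lt(max(abs(sqrt(colSums(Mod(A2)^2)) - 1)), 1e-12)
  expect_error(init_dictionary(15, 20), "perfect square")
  expect_error(init_dictionary(16, 8), "at least")
})

test_that("OMP recovers a single-atom patch exactly and respects the sparsity cap", {
  A <- init_dictionary(16, 32)
  prm <- dl_params(sparsity = 3, fit_tol = 0)
  x <- 3 * A[, 7, drop = FALSE]
  G <- omp_encode(x, A, prm)
  expect_equal(which(Mod(G[, 1]) > 1e-10), 7L)
  expect_equal(G[7, 1], 3 + 0i, tolerance = 1e-10)
  set.seed(51)
  X <- matrix(complex(real = rnorm(16 * 50), imaginary = rnorm(16 * 50)), 16)
  G <- omp_encode(X, A, prm)
  expect_true(all(colSums(Mod(G) > 0) <= 3))
})

test_that("OMP residuals are orthogonal to the active set after each solve", {
  set.seed(52)
  A <- init_dictionary(16, 24)
  X <- matrix(complex(real = rnorm(16 * 20), imaginary = rnorm(16 * 20)), 16)
  G <- omp_encode(X, A, dl_params(sparsity = 4, fit_tol = 0))
  R <- X - A %*% G
  for (i in 1:20) {
    S <- which(Mod(G[, i]) > 0)
    if (length(S)) expect_lt(max(Mod(Conj(t(A[, S, drop = FALSE])) %*% R[, i])), 1e-8)
  }
})

test_that("with full sparsity budget and a square full-rank dictionary OMP reaches least squares", {
  set.seed(53)
  M <- 9
  B <- matrix(rnorm(M * M), M) + diag(M)      # well-conditioned square frame
  B <- sweep(B, 2, sqrt(colSums(B^2)), "/")
  storage.mode(B) <- "complex"
  X <- matrix(complex(real = rnorm(M * 10), imaginary = rnorm(M * 10)), M)
  G <- omp_encode(X, B, dl_params(sparsity = M, omp_tol = 0, fit_tol = 0))
  expect_lt(max(Mod(B %*% G - X)), 1e-8)
})

test_that("a K-SVD sweep never increases the fit error", {
  for (seed in 1:10) {
    d <- synth_sparse_data(M = 16, J = 18, tau = 3, I = 200, seed = seed)
    A <- init_dictionary(16, 18)
    G <- omp_encode(d$X, A, dl_params(sparsity = 3, fit_tol = 0))
    before <- sqrt(sum(Mod(A %*% G - d$X)^2))
    upd <- ksvd_update(A, G, d$X)
    after <- sqrt(sum(Mod(upd$A %*% upd$G - d$X)^2))
    expect_lte(after, before + 1e-9 * before)
    expect_lt(max(abs(sqrt(colSums(Mod(upd$A)^2)) - 1)), 1e-10)  # unit atoms
  }
})

test_that("exact codes are a K-SVD fixed point up to per-atom phase", {
  d <- synth_sparse_data(M = 12, J = 16, tau = 2, I = 300, seed = 3)
  upd <- ksvd_update(d$A0, d$G0, d$X)   # the true codes themselves
  expect_lt(sqrt(sum(Mod(upd$A %*% upd$G - d$X)^2)), 1e-8)
  match <- Mod(colSums(Conj(upd$A) * d$A0))   # |a_new^H a_old| per atom
  expect_true(all(match > 1 - 1e-8))
})

test_that("alternating coding and dictionary updates drives the error down monotonically", {
  d <- synth_sparse_data(M = 16, J = 20, tau = 3, I = 500, seed = 9)
  fit <- learn_codes_and_dictionary(d$X, A0 = init_dictionary(16, 20),
                                    params = dl_params(sparsity = 3, ksvd_iters = 8, fit_tol = 0))
  expect_true(all(diff(fit$errors) <= 1e-9 * fit$errors[1]))
  # one-atom patches are recovered exactly from the true dictionary
  d1 <- synth_sparse_data(M = 16, J = 20, tau = 1, I = 400, seed = 10)
  fit0 <- learn_codes_and_dictionary(d1$X, A0 = d1$A0,
                                     params = dl_params(sparsity = 1, ksvd_iters = 1, fit_tol = 0))
  expect_lt(tail(fit0$errors, 1), 1e-8)
  # one alternation is exactly one encode plus one update
  G1 <- omp_encode(d1$X, d1$A0, dl_params(sparsity = 1, fit_tol = 0))
  upd <- ksvd_update(d1$A0, G1, d1$X)
  expect_identical(fit0$A, upd$A)
})

test_that("global phase of the patches propagates to the codes and leaves the error unchanged", {
  d <- synth_sparse_data(M = 12, J = 16, tau = 2, I = 100, seed = 13)
  ph <- exp(1i * 0.73)
  prm <- dl_params(sparsity = 2, fit_tol = 0)
  G <- omp_encode(d$X, d$A0, prm)
  Gp <- omp_encode(ph * d$X, d$A0, prm)
  expect_lt(max(Mod(Gp - ph * G)), 1e-9)
  expect_equal(sum(Mod(d$A0 %*% Gp - ph * d$X)^2), sum(Mod(d$A0 %*% G - d$X)^2),
               tolerance = 1e-9)
})

test_that("zero patches receive zero codes and zero atoms are rejected", {
  A <- init_dictionary(9, 12)
  G <- omp_encode(matrix(0 + 0i, 9, 5), A, dl_params(sparsity = 2))
  expect_true(all(G == 0))
  Abad <- A; Abad[, 3] <- 0
  expect_error(omp_encode(matrix(1 + 0i, 9, 1), Abad, dl_params()), "zero atom")
})
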