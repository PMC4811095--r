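make_small_problem <- function(n, seed, cfg = patch_config(4)) {
  set.seed(seed)
  params <- solver_params(beta = runif(1, 0.5, 3), lambda0 = runif(1, 0.2, 1),
                          alpha0 = runif(1, 0.1, 0.6), alpha1 = runif(1, 0.1, 0.8),
                          mu2 = runif(1, 0.5, 2), mu3 = runif(1, 0.5, 2))
  mask <- make_mask("random2d", n, 2, seed = seed)
  state <- rand_admm_state(n)
  bvals <- complex(real = rnorm(sum(mask)), imaginary = rnorm(sum(mask)))
  AG <- matrix(complex(real = rnorm(cfg$M * n^2), imaginary = rnorm(cfg$M * n^2)), cfg$M)
  list(params = params, mask = mask, state = state, bvals = bvals, AG = AG, cfg = cfg)
}

spectral_vs_dense <- function(n, seed) {
  pb <- make_small_problem(n, seed)
  b_embed <- matrix(0 + 0i, n, n); b_embed[as.vector(pb$mask)] <- pb$bvals
  rhs_dl <- pb$params$lambda0 * fft2u(aggregate_patches(pb$AG, n, pb$cfg))
  sys <- spectral_system(pb$mask, pb$params$beta, pb$params, pb$cfg$M)
  got <- solve_up(pb$state, b_embed, rhs_dl, sys)
  ora <- dense_solve_up(pb$state, pb$bvals, pb$mask, pb$AG, pb$cfg, pb$params, pb$params$beta)
  max(relerr(got$u, ora$u), relerr(got$p$p1, ora$p$p1), relerr(got$p$p2, ora$p$p2))
}

test_that("the spectral 3x3 solve equals a dense direct solve of the normal equations", {
  for (seed in 1:3) expect_lt(spectral_vs_dense(8, seed), 1e-8)
  expect_lt(spectral_vs_dense(12, 1), 1e-8)
})

test_that("the y update is the shrinkage of its argument with threshold 1/mu2", {
  n <- 6
  params <- solver_params(mu2 = 1, mu3 = 1)
  st <- list(u = matrix(0 + 0i, n, n),
             p = list(p1 = matrix(0 + 0i, n, n), p2 = matrix(0 + 0i, n, n)),
             ytil = list(p1 = matrix(0 + 0i, n, n), p2 = matrix(0 + 0i, n, n)))
  # Du = p and zero dual: argument is zero, so y is zero
  st$p <- grad(st$u)
  y <- update_y(st, params)
  expect_true(all(y$p1 == 0) && all(y$p2 == 0))
  # single-pixel argument (3, 4) with mu2 = 1 shrinks to (2.4, 3.2)
  st$ytil$p1[2, 2] <- 3; st$ytil$p2[2, 2] <- 4
  y <- update_y(st, params)
  expect_equal(Re(y$p1[2, 2]), 2.4, tolerance = 1e-12)
  expect_equal(Re(y$p2[2, 2]), 3.2, tolerance = 1e-12)
  # huge mu2: threshold vanishes and y tends to its argument
  yb <- update_y(st, solver_params(mu2 = 1e8, mu3 = 1))
  expect_lt(abs(Re(yb$p1[2, 2]) - 3), 1e-7)
})

test_that("the z update mirrors the y update with the Frobenius shrinkage", {
  n <- 6
  params <- solver_params(mu2 = 1, mu3 = 1)
  st <- list(p = list(p1 = matrix(0 + 0i, n, n), p2 = matrix(0 + 0i, n, n)),
             ztil = list(z1 = matrix(0 + 0i, n, n), z2 = matrix(0 + 0i, n, n),
                         z3 = matrix(0 + 0i, n, n)))
  z <- update_z(st, params)
  expect_true(all(z$z1 == 0) && all(z$z2 == 0) && all(z$z3 == 0))
  st$ztil$z1[3, 3] <- 3; st$ztil$z2[3, 3] <- 4
  z <- update_z(st, params)
  expect_equal(Re(z$z1[3, 3]), 2.4, tolerance = 1e-12)
  zb <- update_z(st, solver_params(mu2 = 1, mu3 = 1e8))
  expect_lt(abs(Re(zb$z1[3, 3]) - 3), 1e-7)
})

test_that("dual ascent adds mu times the primal residual and is inert at feasibility", {
  n <- 8
  set.seed(61)
  st <- rand_admm_state(n)
  params <- solver_params(mu = 0.7)
  new <- update_duals(st, params)
  g <- grad(st$u); e <- sym_grad(st$p)
  expect_equal(new$ytil$p1, st$ytil$p1 + 0.7 * (g$p1 - st$p$p1 - st$y$p1))
  expect_equal(new$ztil$z3, st$ztil$z3 + 0.7 * (e$z3 - st$z$z3))
  # exact feasibility: duals unchanged
  st$y <- list(p1 = g$p1 - st$p$p1, p2 = g$p2 - st$p$p2)
  st$z <- e
  same <- update_duals(st, params)
  expect_equal(same$ytil, st$ytil)
  expect_equal(same$ztil, st$ztil)
  st2 <- rand_admm_state(n)
  none <- update_duals(st2, solver_params(mu = 0))
  expect_equal(none$ytil, st2$ytil)
  expect_equal(none$ztil, st2$ztil)
})

test_that("degenerate weights reproduce their closed forms", {
  n <- 8
  cfg <- patch_config(4)
  set.seed(62)
  st <- rand_admm_state(n)
  AG <- matrix(complex(real = rnorm(cfg$M * n^2), imaginary = rnorm(cfg$M * n^2)), cfg$M)
  # alpha = 0, beta = 0, lambda0 > 0: u is the patch average R^T(AG)/M
  params <- solver_params(beta = 1e-300, lambda0 = 0.8, alpha0 = 0, alpha1 = 0)
  mask <- make_mask("full", n)
  sys <- spectral_system(mask, 0, params, cfg$M)
  rhs_dl <- params$lambda0 * fft2u(aggregate_patches(AG, n, cfg))
  sol <- solve_up(st, matrix(0 + 0i, n, n), rhs_dl, sys)
  expect_lt(relerr(sol$u, aggregate_patches(AG, n, cfg) / cfg$M), 1e-8)
  expect_true(all(sol$p$p1 == 0) && all(sol$p$p2 == 0))
  # dominant data term on full sampling returns the measured image
  u_star <- rand_cimage(n)
  b <- forward_measure(u_star, mask)
  b_embed <- matrix(0 + 0i, n, n); b_embed[as.vector(mask)] <- b$values
  params2 <- solver_params(beta = 1e6, lambda0 = 1e-8, alpha0 = 1e-10, alpha1 = 1e-8)
  sys2 <- spectral_system(mask, 1e6, params2, cfg$M)
  sol2 <- solve_up(st, b_embed, matrix(0 + 0i, n, n), sys2)
  expect_lt(relerr(sol2$u, u_star), 1e-3)
})

test_that("the objective decomposes additively and matches a naive summation", {
  n <- 8
  cfg <- patch_config(4)
  set.seed(63)
  mask <- make_mask("random2d", n, 2, seed = 1)
  u_star <- rand_cimage(n)
  b <- forward_measure(u_star, mask)
  st <- rand_admm_state(n)
  st$A <- init_dictionary(cfg$M, 2 * cfg$M)
  st$G <- matrix(complex(real = rnorm(2 * cfg$M * n^2)), 2 * cfg$M)
  params <- solver_params(beta = 2, lambda0 = 0.5, alpha0 = 0.3, alpha1 = 0.4)
  got <- objective(st, b, 2, params, cfg)
  ku <- forward_measure(st$u, mask)
  naive <- 0
  for (q in seq_along(b$values)) naive <- naive + Mod(ku$values[q] - b$values[q])^2
  naive <- naive * 2 / 2
  X <- extract_patches(st$u, cfg)
  D <- st$A %*% st$G - X
  naive <- naive + 0.5 * 0.5 * sum(Mod(D)^2)
  naive <- naive + tgv2_penalty(st$u, st$p, 0.3, 0.4)
  expect_equal(got, naive, tolerance = 1e-12)
  # zero everything gives zero
  z <- matrix(0 + 0i, n, n)
  st0 <- list(u = z, p = list(p1 = z, p2 = z), A = NULL, G = NULL)
  b0 <- b; b0$values <- b$values * 0
  expect_identical(objective(st0, b0, 2, solver_params(lambda0 = 0), cfg), 0)
})

test_that("full noiseless sampling is recovered to machine-level accuracy", {
  n <- 64
  ref <- shepp_logan(n)
  b <- forward_measure(ref, make_mask("full", n))
  res <- reconstruct(b, solver_params(outer_iters = 2, tol = 0),
                     dlp = dl_params(ksvd_iters = 1))
  expect_gte(psnr(ref, res$u), 100)
})

test_that("reconstruction is deterministic: same inputs give bit-identical logs", {
  n <- 32
  ref <- shepp_logan(n)
  mask <- make_mask("radial", n, 3, seed = 5)
  b <- forward_measure(ref, mask)
  prm <- solver_params(outer_iters = 2)
  dlp <- dl_params(ksvd_iters = 1)
  r1 <- reconstruct(b, prm, dlp = dlp)
  r2 <- reconstruct(b, prm, dlp = dlp)
  expect_identical(r1$log, r2$log)
  expect_identical(r1$u, r2$u)
})

test_that("primal residuals contract over the inner iterations", {
  n <- 64
  ref <- shepp_logan(n)
  b <- forward_measure(ref, make_mask("radial", n, 3, seed = 2))
  res <- reconstruct(b, solver_params(lambda0 = 0, outer_iters = 20, tol = 0))
  lg <- res$log
  expect_lt(tail(lg$primal_res_y, 1), 1e-3 * lg$primal_res_y[1])
  expect_lt(tail(lg$primal_res_z, 1), 1e-3 * lg$primal_res_z[1])
})

test_that("non-finite parameter combinations are rejected up front", {
  expect_error(solver_params(beta = -1), "positive")
  expect_error(solver_params(mu2 = 0), "positive")
  expect_error(solver_params(alpha0 = -0.1), "nonnegative")
})
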