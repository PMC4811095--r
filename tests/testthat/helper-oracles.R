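# Independent oracles and fixture generators shared across tests.

rand_cimage <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n)
}
rand_field <- function(n) list(p1 = rand_cimage(n), p2 = rand_cimage(n))
rand_tensor <- function(n) list(z1 = rand_cimage(n), z2 = rand_cimage(n), z3 = rand_cimage(n))

cinner <- function(a, b) sum(a * Conj(b))
field_inner <- function(x, y) cinner(x$p1, y$p1) + cinner(x$p2, y$p2)
# tensor inner product counts the off-diagonal twice (Frobenius of the 2x2)
tensor_inner <- function(x, y) cinner(x$z1, y$z1) + cinner(x$z2, y$z2) + 2 * cinner(x$z3, y$z3)

relerr <- function(a, b) sqrt(sum(Mod(a - b)^2)) / max(sqrt(sum(Mod(b)^2)), 1e-300)

# numeric proximal oracle: argmin_x thr*||x||_w + 0.5*||x - a||_w^2 where
# ||.||_w is the weighted Euclidean norm. In w-scaled coordinates the problem
# is isotropic, so the minimiser lies on the ray through the data point and a
# 1D golden-section search over its radius solves it to high precision without
# using the closed-form positive-part formula under test.
prox_numeric <- function(a, thr, weights = rep(1, length(a))) {
  sw <- sqrt(weights)
  at <- sw * a
  r0 <- sqrt(sum(at^2))
  if (r0 == 0) return(a * 0)
  f1 <- function(t) thr * t + 0.5 * (t - r0)^2
  t_star <- stats::optimize(f1, interval = c(0, r0 + thr + 1), tol = 1e-12)$minimum
  if (f1(0) <= f1(t_star)) t_star <- 0
  (t_star * at / r0) / sw
}

# brute-force dense solve of the coupled (u, p) quadratic, assembling every
# operator as an explicit matrix from its definition
dense_solve_up <- function(state, bvals, mask, AG, cfg, params, beta) {
  n <- nrow(mask); N <- n^2
  opmat <- function(op, ncolN) {
    out <- NULL
    for (k in seq_len(ncolN)) {
      e <- rep(0 + 0i, ncolN); e[k] <- 1
      col <- op(e)
      if (is.null(out)) out <- matrix(0 + 0i, length(col), ncolN)
      out[, k] <- col
    }
    out
  }
  vecim <- function(v) matrix(v, n, n)
  Fm <- opmat(function(v) as.vector(fft2u(vecim(v))), N)
  Pm <- diag(as.numeric(as.vector(mask)))
  Dm <- opmat(function(v) { g <- grad(vecim(v)); c(as.vector(g$p1), as.vector(g$p2)) }, N)
  Em <- opmat(function(v) {
    p <- list(p1 = vecim(v[1:N]), p2 = vecim(v[(N + 1):(2 * N)]))
    e <- sym_grad(p)
    c(as.vector(e$z1), as.vector(e$z2), as.vector(e$z3))
  }, 2 * N)
  Rm <- opmat(function(v) as.vector(extract_patches(vecim(v), cfg)), N)
  Wz <- diag(c(rep(1, N), rep(1, N), rep(2, N)))

  a1m2 <- params$alpha1 * params$mu2
  a0m3 <- params$alpha0 * params$mu3
  l0 <- params$lambda0
  H <- function(Mx) Conj(t(Mx))
  K <- Pm %*% Fm
  bfull <- rep(0 + 0i, N); bfull[as.vector(mask)] <- bvals
  c1 <- c(as.vector(state$y$p1 - state$ytil$p1), as.vector(state$y$p2 - state$ytil$p2))
  c2 <- c(as.vector(state$z$z1 - state$ztil$z1), as.vector(state$z$z2 - state$ztil$z2),
          as.vector(state$z$z3 - state$ztil$z3))
  A11 <- beta * H(K) %*% K + l0 * H(Rm) %*% Rm + a1m2 * H(Dm) %*% Dm
  A12 <- -a1m2 * H(Dm)
  A21 <- -a1m2 * Dm
  A22 <- a1m2 * diag(2 * N) + a0m3 * H(Em) %*% Wz %*% Em
  Afull <- rbind(cbind(A11, A12), cbind(A21, A22))
  r1 <- beta * H(K) %*% bfull + l0 * H(Rm) %*% as.vector(AG) + a1m2 * H(Dm) %*% c1
  r2 <- -a1m2 * c1 + a0m3 * H(Em) %*% Wz %*% c2
  x <- solve(Afull, c(r1, r2))
  list(u = vecim(x[1:N]), p = list(p1 = vecim(x[(N + 1):(2 * N)]),
                                   p2 = vecim(x[(2 * N + 1):(3 * N)])))
}

rand_admm_state <- function(n) {
  list(u = rand_cimage(n), p = rand_field(n),
       y = rand_field(n), z = rand_tensor(n),
       ytil = rand_field(n), ztil = rand_tensor(n))
}

# exactly tau-sparse synthetic patches from a known random dictionary
synth_sparse_data <- function(M, J, tau, I, seed) {
  set.seed(seed)
  A0 <- matrix(rnorm(M * J), M)
  A0 <- sweep(A0, 2, sqrt(colSums(A0^2)), "/")
  storage.mode(A0) <- "complex"
  G0 <- matrix(0 + 0i, J, I)
  for (i in seq_len(I)) {
    s <- sample(J, tau)
    G0[s, i] <- rnorm(tau)
  }
  list(A0 = A0, G0 = G0, X = A0 %*% G0)
}

# greedy one-to-one matching of estimated to true atoms by |a_est^H a_true|
atom_recovery_count <- function(A_est, A_true, thresh = 0.99) {
  C <- Mod(Conj(t(A_est)) %*% A_true)
  count <- 0L
  for (j in seq_len(ncol(A_true))) {
    best <- which.max(C[, j])
    if (C[best, j] > thresh) {
      count <- count + 1L
      C[best, ] <- -1  # each estimated atom may claim one true atom
    }
  }
  count
}
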