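#' Dictionary-learning parameters
#'
#' @param sparsity maximum number of nonzero coefficients per patch
#'   (the OMP stopping level, `tau1`).
#' @param ksvd_iters number of OMP + K-SVD alternations per call to
#'   [learn_codes_and_dictionary()].
#' @param omp_tol relative residual tolerance: OMP also stops once the
#'   residual norm drops below `omp_tol * ||patch||`.
#' @param fit_tol absolute per-pixel residual tolerance in intensity units:
#'   a patch stops being coded once its residual RMS per pixel falls below
#'   `fit_tol`. This is the capacity control of the dictionary prior — coding
#'   each patch only down to the expected aliasing/noise floor is what lets
#'   sparse coding strip incoherent artifacts instead of reproducing them.
#'   Scaled for images in `[0, 255]`; set 0 to code as tightly as `sparsity`
#'   allows.
#' @param seed integer seed (reserved for randomised variants; the default
#'   pipeline is deterministic).
#' @return list of class `"dl_params"`.
#' @export
dl_params <- function(sparsity = 7L, ksvd_iters = 3L, omp_tol = 1e-6,
                      fit_tol = 15, seed = 1L) {
  sparsity <- as.integer(sparsity); ksvd_iters <- as.integer(ksvd_iters)
  if (sparsity < 1) stop("sparsity must be >= 1")
  if (ksvd_iters < 1) stop("ksvd_iters must be >= 1")
  if (fit_tol < 0) stop("fit_tol must be nonnegative")
  structure(list(sparsity = sparsity, ksvd_iters = ksvd_iters,
                 omp_tol = omp_tol, fit_tol = fit_tol, seed = as.integer(seed)),
            class = "dl_params")
}

#' Overcomplete DCT starting dictionary
#'
#' Deterministic initial dictionary: the Kronecker product of two 1D
#' overcomplete cosine frames, columns normalised to unit Euclidean norm. The
#' first atom is the flat (constant) atom, which absorbs patch means. When `J`
#' is not a perfect square the first `J` columns of the next-larger Kronecker
#' construction are used.
#'
#' @param M patch length (`b^2`; must be a perfect square).
#' @param J number of atoms, `J >= M`.
#' @return complex `M x J` matrix with unit-norm columns.
#' @export
init_dictionary <- function(M, J) {
  b <- as.integer(round(sqrt(M)))
  if (b * b != M) stop("M must be a perfect square (M = patch_side^2)")
  if (J < M) stop("J must be at least M")
  K1 <- as.integer(ceiling(sqrt(J)))
  D1 <- outer(0:(b - 1L), 0:(K1 - 1L), function(i, k) cos(pi * i * k / K1))
  A <- kronecker(D1, D1)[, seq_len(J), drop = FALSE]
  A <- sweep(A, 2, sqrt(colSums(A^2)), "/")
  storage.mode(A) <- "complex"
  A
}

#' Sparse-code patches with orthogonal matching pursuit
#'
#' Greedy per-patch coding against a fixed dictionary: select the atom with
#' the largest conjugate correlation `|a_k^H r|`, re-solve least squares on
#' the active set, and stop after `sparsity` atoms or when the residual norm
#' falls below `omp_tol * ||patch||`. The residual after each step is
#' orthogonal to the span of the selected atoms.
#'
#' @param patches `M x I` complex patch matrix.
#' @param A `M x J` dictionary with unit-norm atoms.
#' @param params a [dl_params()].
#' @return `J x I` complex coefficient matrix; each column has at most
#'   `params$sparsity` nonzeros.
#' @export
omp_encode <- function(patches, A, params = dl_params()) {
  if (nrow(patches) != nrow(A)) stop("patch length does not match dictionary")
  an <- sqrt(colSums(Mod(A)^2))
  if (any(an < 1e-12)) stop("dictionary contains a zero atom")
  if (any(abs(an - 1) > 1e-6)) stop("dictionary atoms must be unit-norm")
  if (!is.complex(patches)) storage.mode(patches) <- "complex"
  if (!is.complex(A)) storage.mode(A) <- "complex"
  tol_abs <- params$fit_tol * sqrt(nrow(A))  # per-pixel RMS -> patch norm
  .omp_encode_cpp(patches, A, params$sparsity, params$omp_tol, tol_abs)
}

## residual energy per patch under current (A, G)
patch_residual_norms <- function(A, G, X) sqrt(colSums(Mod(X - A %*% G)^2))

#' One K-SVD dictionary update sweep
#'
#' Updates atoms sequentially. For each atom used by at least one patch, the
#' atom and its nonzero coefficient row are replaced by the leading rank-1
#' term of the complex SVD of the restricted representation residual `E_k`.
#' Atoms used by no patch are replaced by the (normalised) currently
#' worst-represented patch. The Frobenius fit error `||A G - X||_F` never
#' increases. Atom phases are fixed so the largest-magnitude entry is real
#' positive, which makes the sweep deterministic.
#'
#' @param A `M x J` dictionary.
#' @param G `J x I` coefficient matrix.
#' @param patches `M x I` patch matrix.
#' @return list with updated `A` and `G`.
#' @export
ksvd_update <- function(A, G, patches) {
  X <- patches
  J <- ncol(A)
  for (k in seq_len(J)) {
    S <- which(Mod(G[k, ]) > 0)
    if (length(S) == 0L) {
      res <- patch_residual_norms(A, G, X)
      worst <- which.max(res)
      v <- X[, worst]
      nv <- sqrt(sum(Mod(v)^2))
      if (nv > 1e-12) A[, k] <- fix_phase(v / nv)
      next
    }
    Ek <- X[, S, drop = FALSE] - A %*% G[, S, drop = FALSE] +
      A[, k] %*% t(G[k, S])
    sv <- svd(Ek, nu = 1L, nv = 1L)
    if (sv$d[1] < 1e-14) next  # degenerate residual: keep previous atom
    a <- sv$u[, 1]
    g <- sv$d[1] * Conj(sv$v[, 1])
    ph <- phase_of(a)
    A[, k] <- a * Conj(ph)
    G[k, S] <- g * ph
  }
  list(A = A, G = G)
}

phase_of <- function(a) {
  m <- which.max(Mod(a))
  z <- a[m]
  if (Mod(z) < 1e-14) 1 + 0i else z / Mod(z)
}
fix_phase <- function(a) a * Conj(phase_of(a))

#' Alternate sparse coding and dictionary updates
#'
#' Runs `ksvd_iters` alternations of [omp_encode()] followed by
#' [ksvd_update()], solving the dictionary subproblem (fit the patches of the
#' current image by `A G` with at most `tau1` atoms per patch).
#'
#' The recorded fit-error trajectory `||A G - X||_F` is non-increasing: the
#' K-SVD sweep never increases the error, and the coding step is safeguarded
#' per patch — a fresh greedy code replaces the previous one only if it fits
#' that patch at least as well (greedy OMP alone carries no such guarantee
#' near convergence).
#'
#' @param patches `M x I` complex patch matrix.
#' @param A0 starting dictionary (defaults to [init_dictionary()] with
#'   overcompleteness 4).
#' @param params a [dl_params()].
#' @return list with `A`, `G`, and `errors` (fit error after each alternation).
#' @export
learn_codes_and_dictionary <- function(patches, A0 = NULL, params = dl_params()) {
  M <- nrow(patches)
  if (is.null(A0)) A0 <- init_dictionary(M, 4L * M)
  A <- A0
  errors <- numeric(params$ksvd_iters)
  G <- NULL
  for (it in seq_len(params$ksvd_iters)) {
    Gnew <- omp_encode(patches, A, params)
    if (is.null(G)) {
      G <- Gnew
    } else {
      ## monotonicity safeguard, applied lazily: greedy codes are taken as-is
      ## while they improve the total fit; only when they would increase it
      ## (possible near convergence) revert the columns that got worse
      rn_new <- patch_residual_norms(A, Gnew, patches)
      rn_old <- patch_residual_norms(A, G, patches)
      if (sum(rn_new^2) > sum(rn_old^2)) {
        worse <- rn_new > rn_old
        Gnew[, worse] <- G[, worse]
      }
      G <- Gnew
    }
    upd <- ksvd_update(A, G, patches)
    A <- upd$A; G <- upd$G
    errors[it] <- sqrt(sum(Mod(A %*% G - patches)^2))
  }
  list(A = A, G = G, errors = errors)
}
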