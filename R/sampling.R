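#' @useDynLib dltgv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm optim runif fft
#' @importFrom utils write.csv read.csv
NULL

## Unitary 2D DFT helpers. DC sits at matrix index [1,1] (unshifted layout);
## display utilities may fftshift but nothing internal does.

#' Unitary 2D discrete Fourier transform
#'
#' Forward and inverse orthonormal DFT of an `n x n` complex matrix, with the
#' zero-frequency (DC) coefficient at index `[1, 1]`. Orthonormality means
#' `||fft2u(u)|| == ||u||`, so the undersampled-Fourier operator built on top
#' of it has an adjoint that is literally its conjugate transpose.
#'
#' @param u complex (or numeric) square matrix.
#' @return complex matrix of the same size.
#' @export
fft2u <- function(u) {
  stopifnot(is.matrix(u), nrow(u) == ncol(u))
  stats::fft(u) / nrow(u)
}

#' @rdname fft2u
#' @export
ifft2u <- function(u) {
  stopifnot(is.matrix(u), nrow(u) == ncol(u))
  stats::fft(u, inverse = TRUE) / nrow(u)
}

as_complex_image <- function(u) {
  if (!is.matrix(u) || nrow(u) != ncol(u))
    stop("image must be a square matrix")
  if (!is.complex(u)) storage.mode(u) <- "complex"
  if (any(!is.finite(Re(u))) || any(!is.finite(Im(u))))
    stop("image values must be finite")
  u
}

#' Create a k-space sampling mask
#'
#' Generates the selection pattern `P` of the undersampled Fourier operator
#' `K = P F`. All built-in schemes keep the DC location and are pure,
#' deterministic functions of `(scheme, n, target_factor, seed)`.
#'
#' Schemes:
#' \describe{
#'   \item{`radial`}{`L` equiangular straight lines through the k-space centre,
#'     rasterised to the nearest Cartesian grid point; `L` is chosen so the
#'     achieved undersampling factor is closest to `target_factor`.}
#'   \item{`random2d`}{variable-density random selection with sampling density
#'     decaying with k-space radius and a fully kept central disk; the number
#'     of kept locations is exact.}
#'   \item{`cartesian1d`}{full phase-encode rows: a fully kept central band
#'     plus randomly chosen outer rows.}
#'   \item{`spiral`}{single-shot Archimedean spiral, pitch tuned to the target
#'     factor.}
#'   \item{`full`}{every location kept (factor 1).}
#' }
#'
#' @param scheme one of `"radial"`, `"random2d"`, `"cartesian1d"`, `"spiral"`,
#'   `"full"`.
#' @param n grid side length in pixels (>= 8).
#' @param target_factor requested undersampling factor `n^2 / kept`; the
#'   achieved factor is within 15\% of the target for reachable requests.
#' @param seed integer seed for the randomised schemes.
#' @return a logical `n x n` matrix of class `"sampling_mask"` in unshifted
#'   (DC at `[1,1]`) layout, with attributes `scheme` and `seed`.
#' @export
make_mask <- function(scheme = c("radial", "random2d", "cartesian1d", "spiral", "full"),
                      n, target_factor = 1, seed = 1L) {
  scheme <- match.arg(scheme)
  if (n < 8) stop("n must be at least 8")
  if (target_factor < 1) stop("target_factor must be >= 1")
  if (target_factor > n^2) stop("target_factor unreachable: fewer than one location would be kept")
  keep_shifted <- switch(scheme,
    full = matrix(TRUE, n, n),
    radial = mask_radial(n, target_factor),
    random2d = with_seed(seed, mask_random2d(n, target_factor)),
    cartesian1d = with_seed(seed, mask_cartesian1d(n, target_factor)),
    spiral = mask_spiral(n, target_factor)
  )
  ctr <- floor(n / 2) + 1L
  keep_shifted[ctr, ctr] <- TRUE
  keep <- ifftshift2(keep_shifted)
  structure(keep, class = "sampling_mask", scheme = scheme, seed = as.integer(seed),
            target_factor = target_factor)
}

#' Undersampling factor of a mask
#'
#' @param mask a `sampling_mask` (or any logical matrix).
#' @return `n^2 / (number of kept locations)`.
#' @export
undersampling_factor <- function(mask) {
  k <- sum(mask)
  if (k == 0) stop("mask keeps no locations")
  length(mask) / k
}

#' @export
print.sampling_mask <- function(x, ...) {
  cat(sprintf("k-space sampling mask: %dx%d, scheme=%s, kept=%d (factor %.3f)\n",
              nrow(x), ncol(x), attr(x, "scheme"), sum(x), undersampling_factor(x)))
  invisible(x)
}

## shifted <-> unshifted layout (DC centre <-> DC at [1,1])
fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((floor(n1 / 2) + 1L):n1, 1L:floor(n1 / 2)),
    c((floor(n2 / 2) + 1L):n2, 1L:floor(n2 / 2))]
}
ifftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((n1 - floor(n1 / 2) + 1L):n1, 1L:(n1 - floor(n1 / 2))),
    c((n2 - floor(n2 / 2) + 1L):n2, 1L:(n2 - floor(n2 / 2)))]
}

## run expr with a private RNG stream, restoring caller's state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

radius_grid <- function(n) {
  ctr <- floor(n / 2) + 1L
  x <- (1:n) - ctr
  sqrt(outer(x^2, x^2, `+`))
}

## L equiangular lines through the centre, nearest-grid-point rasterisation,
## start angle 0. Kept count is monotone in L, so bisect on L.
rasterize_lines <- function(n, L) {
  ctr <- floor(n / 2) + 1L
  keep <- matrix(FALSE, n, n)
  t <- seq(-n, n, by = 0.5)
  for (l in seq_len(L)) {
    th <- pi * (l - 1) / L
    i <- round(ctr + t * cos(th))
    j <- round(ctr + t * sin(th))
    ok <- i >= 1 & i <= n & j >= 1 & j <= n
    keep[cbind(i[ok], j[ok])] <- TRUE
  }
  keep
}

mask_radial <- function(n, target_factor) {
  target_kept <- n^2 / target_factor
  lo <- 1L; hi <- 4L * n
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (sum(rasterize_lines(n, mid)) < target_kept) lo <- mid else hi <- mid
  }
  klo <- rasterize_lines(n, lo); khi <- rasterize_lines(n, hi)
  if (abs(sum(klo) - target_kept) <= abs(sum(khi) - target_kept)) klo else khi
}

## variable-density random selection: density ~ 1/(1 + (r/r0)^3) outside a
## fully kept central disk; exact kept count via weighted sampling.
mask_random2d <- function(n, target_factor) {
  kept_target <- max(1L, round(n^2 / target_factor))
  r <- radius_grid(n)
  disk <- r <= n / 32
  keep <- disk
  extra <- kept_target - sum(keep)
  if (extra > 0) {
    cand <- which(!disk)
    w <- 1 / (1 + (r[cand] / (n / 16))^3)
    pick <- sample(cand, size = min(extra, length(cand)), prob = w)
    keep[pick] <- TRUE
  }
  keep
}

## full phase-encode rows: central band (a quarter of the budget) + random rows
mask_cartesian1d <- function(n, target_factor) {
  rows_target <- max(1L, round(n / target_factor))
  ctr <- floor(n / 2) + 1L
  nband <- max(1L, round(rows_target / 4))
  band <- (ctr - (nband %/% 2)):(ctr - (nband %/% 2) + nband - 1L)
  band <- band[band >= 1 & band <= n]
  rest <- setdiff(1:n, band)
  extra <- rows_target - length(band)
  rows <- band
  if (extra > 0) {
    d <- abs(rest - ctr)
    w <- 1 / (1 + (d / (n / 8))^2)
    rows <- c(band, sample(rest, size = min(extra, length(rest)), prob = w))
  }
  keep <- matrix(FALSE, n, n)
  keep[rows, ] <- TRUE
  keep
}

rasterize_spiral <- function(n, pitch) {
  ctr <- floor(n / 2) + 1L
  rmax <- n / sqrt(2)
  keep <- matrix(FALSE, n, n)
  th <- 0
  repeat {
    r <- pitch * th
    if (r > rmax) break
    i <- round(ctr + r * cos(th)); j <- round(ctr + r * sin(th))
    if (i >= 1 && i <= n && j >= 1 && j <= n) keep[i, j] <- TRUE
    th <- th + 0.5 / max(r, 1)
  }
  keep
}

mask_spiral <- function(n, target_factor) {
  target_kept <- n^2 / target_factor
  pitches <- exp(seq(log(0.005), log(20), length.out = 80))
  best <- NULL; best_err <- Inf
  for (p in pitches) {
    k <- rasterize_spiral(n, p)
    err <- abs(sum(k) - target_kept)
    if (err < best_err) { best_err <- err; best <- k }
  }
  best
}

#' Apply the undersampled Fourier operator K = P F
#'
#' Computes the unitary 2D DFT of `u` and restricts it to the kept k-space
#' locations of `mask`. Together with [adjoint_measure()] it forms an exact
#' adjoint pair, and `K K*` is the identity on the kept set.
#'
#' @param u complex square matrix (the image).
#' @param mask `sampling_mask` of the same size.
#' @return object of class `"kspace"`: list with `values` (complex vector over
#'   kept locations, in column-major order of the mask), `mask`, and `sigma`
#'   (noise standard deviation, 0 until [add_noise()] is applied).
#' @export
forward_measure <- function(u, mask) {
  u <- as_complex_image(u)
  if (!all(dim(u) == dim(mask))) stop("image and mask dimensions differ")
  fu <- fft2u(u)
  structure(list(values = fu[as.vector(mask)], mask = mask, sigma = 0),
            class = "kspace")
}

#' Zero-filled adjoint K* of the undersampled Fourier operator
#'
#' Inserts the measured values at their kept k-space locations, zeros
#' elsewhere, and applies the inverse unitary DFT. `adjoint_measure(b)` is the
#' standard zero-filled reconstruction used to initialise the solver.
#'
#' @param b a `"kspace"` object.
#' @return complex image matrix.
#' @export
adjoint_measure <- function(b) {
  stopifnot(inherits(b, "kspace"))
  mask <- b$mask
  if (length(b$values) != sum(mask)) stop("measurement length does not match mask")
  full <- matrix(0 + 0i, nrow(mask), ncol(mask))
  full[as.vector(mask)] <- b$values
  ifft2u(full)
}

#' Add complex white Gaussian noise to k-space data
#'
#' Adds independent zero-mean Gaussian noise of standard deviation `sigma` to
#' the real and imaginary channel of every measured sample. Deterministic
#' given `seed`; the caller's RNG state is left untouched.
#'
#' @param b a `"kspace"` object.
#' @param sigma per-channel noise standard deviation (same scale as the
#'   unitary-DFT k-space values); must be >= 0.
#' @param seed integer seed.
#' @return a `"kspace"` object with noisy values and `sigma` recorded.
#' @export
add_noise <- function(b, sigma, seed = 1L) {
  stopifnot(inherits(b, "kspace"))
  if (sigma < 0) stop("sigma must be nonnegative")
  if (sigma == 0) return(b)
  q <- length(b$values)
  noise <- with_seed(seed, complex(real = stats::rnorm(q, 0, sigma),
                                   imaginary = stats::rnorm(q, 0, sigma)))
  b$values <- b$values + noise
  b$sigma <- sigma
  b
}

#' @export
print.kspace <- function(x, ...) {
  cat(sprintf("k-space data: %d samples on a %dx%d grid (factor %.2f), sigma=%g\n",
              length(x$values), nrow(x$mask), ncol(x$mask),
              undersampling_factor(x$mask), x$sigma))
  invisible(x)
}
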