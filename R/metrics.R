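#' Peak signal-to-noise ratio on magnitude images
#'
#' `20 log10(peak / sqrt(MSE))` in dB, where `peak` is the maximum magnitude
#' of the reference and the MSE is taken between the magnitude images. The
#' reference's peak is used (not a fixed 255) so complex-valued experiments
#' are well defined; identical inputs return `Inf`.
#'
#' @param ref reference complex image matrix.
#' @param rec reconstructed complex image matrix of the same size.
#' @return PSNR in dB.
#' @export
psnr <- function(ref, rec) {
  if (!all(dim(ref) == dim(rec))) stop("images must share dimensions")
  peak <- max(Mod(ref))
  if (peak == 0) stop("reference image is identically zero; peak undefined")
  mse <- mean((Mod(rec) - Mod(ref))^2)
  if (mse == 0) return(Inf)
  20 * log10(peak / sqrt(mse))
}

## 15x15 Laplacian-of-Gaussian kernel, sigma = 1.5, adjusted to zero sum
## (the classical 'log' filter construction).
log_kernel <- function(size = 15L, sigma = 1.5) {
  half <- (size - 1) / 2
  x <- matrix(rep(-half:half, size), size, size)
  y <- t(x)
  g <- exp(-(x^2 + y^2) / (2 * sigma^2))
  g <- g / sum(g)
  h <- g * (x^2 + y^2 - 2 * sigma^2) / sigma^4
  h - sum(h) / size^2
}

## 2D correlation with symmetric (reflective) boundary handling
filter2_sym <- function(im, ker) {
  n1 <- nrow(im); n2 <- ncol(im)
  kh <- (nrow(ker) - 1L) %/% 2L
  refl <- function(idx, n) { # reflect without repeating the edge sample
    idx <- ifelse(idx < 1L, 2L - idx, idx)
    ifelse(idx > n, 2L * n - idx, idx)
  }
  pad <- im[refl((1L - kh):(n1 + kh), n1), refl((1L - kh):(n2 + kh), n2)]
  out <- matrix(0, n1, n2)
  for (a in seq_len(nrow(ker)))
    for (bcol in seq_len(ncol(ker)))
      if (ker[a, bcol] != 0)
        out <- out + ker[a, bcol] * pad[(a):(a + n1 - 1L), (bcol):(bcol + n2 - 1L)]
  out
}

#' High-frequency error norm
#'
#' Relative L2 norm of the Laplacian-of-Gaussian-filtered magnitude
#' difference: `||LoG(|rec|) - LoG(|ref|)||_2 / ||LoG(|ref|)||_2`, with a
#' 15x15 LoG kernel of width `sigma = 1.5` and symmetric boundary handling.
#' Captures edge and fine-feature fidelity; 0 for a perfect reconstruction
#' and invariant to constant intensity offsets (the kernel sums to zero).
#'
#' @inheritParams psnr
#' @return nonnegative scalar.
#' @export
hfen <- function(ref, rec) {
  if (!all(dim(ref) == dim(rec))) stop("images must share dimensions")
  ker <- log_kernel()
  lref <- filter2_sym(Mod(ref), ker)
  lrec <- filter2_sym(Mod(rec), ker)
  den <- sqrt(sum(lref^2))
  if (den <= 1e-10 * max(1, max(Mod(ref))))
    stop("reference has no high-frequency content; HFEN undefined")
  sqrt(sum((lrec - lref)^2)) / den
}

## modified Shepp-Logan ellipse table: intensity, semi-axes a, b, centre
## (x0, y0), rotation phi (degrees); coordinates in [-1, 1]^2
shepp_logan_ellipses <- function() {
  matrix(c(
     1.00, 0.6900, 0.9200,  0.00,  0.0000,   0,
    -0.80, 0.6624, 0.8740,  0.00, -0.0184,   0,
    -0.20, 0.1100, 0.3100,  0.22,  0.0000, -18,
    -0.20, 0.1600, 0.4100, -0.22,  0.0000,  18,
     0.10, 0.2100, 0.2500,  0.00,  0.3500,   0,
     0.10, 0.0460, 0.0460,  0.00,  0.1000,   0,
     0.10, 0.0460, 0.0460,  0.00, -0.1000,   0,
     0.10, 0.0460, 0.0230, -0.08, -0.6050,   0,
     0.10, 0.0230, 0.0230,  0.00, -0.6060,   0,
     0.10, 0.0230, 0.0460,  0.06, -0.6050,   0
  ), ncol = 6, byrow = TRUE)
}

#' Modified Shepp-Logan phantom
#'
#' The standard 10-ellipse head phantom, rendered on an `n x n` grid and
#' scaled so the intensity range is `[0, 255]`. Deterministic.
#'
#' @param n side length in pixels.
#' @return real-valued `n x n` matrix (complex storage mode) in `[0, 255]`.
#' @export
shepp_logan <- function(n) {
  E <- shepp_logan_ellipses()
  ax <- seq(-1, 1, length.out = n)
  X <- matrix(rep(ax, n), n, n)          # x varies along rows
  Y <- matrix(rep(ax, each = n), n, n)   # y varies along columns
  img <- matrix(0, n, n)
  for (k in seq_len(nrow(E))) {
    v <- E[k, ]
    phi <- v[6] * pi / 180
    xc <- X - v[4]; yc <- Y - v[5]
    xr <- cos(phi) * xc + sin(phi) * yc
    yr <- -sin(phi) * xc + cos(phi) * yc
    inside <- (xr / v[2])^2 + (yr / v[3])^2 <= 1
    img[inside] <- img[inside] + v[1]
  }
  img <- pmax(img, 0)
  img <- img / max(img) * 255
  storage.mode(img) <- "complex"
  img
}

#' Complex-valued phantom with smooth spatial phase
#'
#' Magnitude equal to the Shepp-Logan phantom, multiplied by a unit-modulus
#' smooth phase field `exp(i * phase_scale * q(x, y))` where `q` is a
#' low-order polynomial with seeded coefficients. Emulates complex-valued MR
#' data whose magnitude is unaffected by the phase: `Mod(complex_phantom(...))`
#' equals `shepp_logan(n)` exactly.
#'
#' @param n side length.
#' @param phase_scale maximum phase excursion in radians (0 gives a real
#'   image).
#' @param seed integer seed for the polynomial coefficients.
#' @return complex `n x n` matrix.
#' @export
complex_phantom <- function(n, phase_scale = 1, seed = 1L) {
  mag <- Re(shepp_logan(n))
  ax <- seq(-1, 1, length.out = n)
  X <- matrix(rep(ax, n), n, n)
  Y <- matrix(rep(ax, each = n), n, n)
  cf <- with_seed(seed, stats::runif(5, -1, 1))
  q <- cf[1] * X + cf[2] * Y + cf[3] * X * Y + cf[4] * X^2 + cf[5] * Y^2
  rng <- max(q) - min(q)
  if (rng > 0) q <- (q - min(q)) / rng  # normalised to [0, 1]
  mag * exp(1i * phase_scale * q)
}

#' Run a sampling-scheme / factor / noise sweep
#'
#' For each combination of scheme, undersampling factor and noise level:
#' generate a mask, simulate measurements from the reference image,
#' reconstruct, and record PSNR and HFEN (plus the zero-filled PSNR
#' baseline). Deterministic given `seed`.
#'
#' @param ref reference complex image.
#' @param schemes character vector of mask schemes.
#' @param factors numeric vector of target undersampling factors.
#' @param sigmas numeric vector of per-channel noise standard deviations.
#' @param params [solver_params()].
#' @param cfg [patch_config()].
#' @param dlp [dl_params()].
#' @param seed base seed; each cell derives its own mask/noise seeds.
#' @param verbose print a line per cell.
#' @return data frame with one row per (scheme, factor, sigma) cell.
#' @export
run_sweep <- function(ref, schemes = "radial", factors = 4, sigmas = 0,
                      params = solver_params(), cfg = patch_config(),
                      dlp = dl_params(), seed = 1L, verbose = FALSE) {
  ref <- as_complex_image(ref)
  n <- nrow(ref)
  rows <- list(); idx <- 0L
  for (sc in schemes) for (f in factors) for (sg in sigmas) {
    idx <- idx + 1L
    cell_seed <- as.integer((seed * 1000L + idx) %% .Machine$integer.max)
    mask <- make_mask(sc, n, f, seed = cell_seed)
    b <- forward_measure(ref, mask)
    if (sg > 0) b <- add_noise(b, sg, seed = cell_seed + 1L)
    res <- reconstruct(b, params, cfg, dlp, reference = ref)
    zf <- adjoint_measure(b)
    rows[[idx]] <- data.frame(scheme = sc, target_factor = f,
                              achieved_factor = undersampling_factor(mask),
                              sigma = sg,
                              psnr_zero_filled = psnr(ref, zf),
                              psnr = psnr(ref, res$u),
                              hfen = hfen(ref, res$u))
    if (verbose)
      cat(sprintf("%s x%g sigma=%g: PSNR %.2f dB (zero-filled %.2f)\n",
                  sc, f, sg, rows[[idx]]$psnr, rows[[idx]]$psnr_zero_filled))
  }
  do.call(rbind, rows)
}
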