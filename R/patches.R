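#' Patch extraction configuration
#'
#' Geometry of the patch operator `R` that maps an `n x n` image to the
#' `M x I` matrix of vectorised patches (`M = b^2`). With `stride = 1` and
#' `wrap = TRUE` (the defaults) every pixel is a patch origin, `I = n^2`, and
#' `R^T R = M * Identity` exactly — the property the closed-form image update
#' relies on.
#'
#' @param patch_side patch side length `b` in pixels.
#' @param stride origin spacing `s` in pixels, `1 <= s <= b`.
#' @param wrap logical; periodic wrap-around at the image borders.
#' @return list of class `"patch_config"` with fields `b`, `s`, `wrap`, `M`.
#' @export
patch_config <- function(patch_side = 6L, stride = 1L, wrap = TRUE) {
  b <- as.integer(patch_side); s <- as.integer(stride)
  if (s < 1 || s > b) stop("stride must satisfy 1 <= stride <= patch_side")
  structure(list(b = b, s = s, wrap = isTRUE(wrap), M = b * b),
            class = "patch_config")
}

patch_origins <- function(n, cfg) {
  if (cfg$b > n) stop("patch_side exceeds image size")
  if (cfg$wrap) seq.int(1L, n, by = cfg$s) else seq.int(1L, n - cfg$b + 1L, by = cfg$s)
}

#' Extract overlapping image patches
#'
#' Applies the linear operator `R`: column `k` of the result is the vectorised
#' `b x b` block at the `k`-th patch origin. Origins are enumerated row-major
#' (column index varying fastest), as is the within-patch ordering; with
#' `wrap = TRUE` indices are taken modulo `n`.
#'
#' @param u complex square image matrix.
#' @param cfg a [patch_config()].
#' @return `M x I` complex matrix with attributes `n` and `cfg`.
#' @export
extract_patches <- function(u, cfg = patch_config()) {
  u <- as_complex_image(u)
  n <- nrow(u)
  org <- patch_origins(n, cfg)
  no <- length(org)
  ## row-major origin grid: (oi, oj) with oj fastest
  oi <- rep(org, each = no)
  oj <- rep(org, times = no)
  I <- no * no
  X <- matrix(0 + 0i, cfg$M, I)
  t <- 0L
  for (di in 0:(cfg$b - 1L)) {      # row-major within patch: dj fastest
    for (dj in 0:(cfg$b - 1L)) {
      t <- t + 1L
      ii <- if (cfg$wrap) ((oi + di - 1L) %% n) + 1L else oi + di
      jj <- if (cfg$wrap) ((oj + dj - 1L) %% n) + 1L else oj + dj
      X[t, ] <- u[cbind(ii, jj)]
    }
  }
  ## row-major within-patch index order is (di, dj) with dj fastest, but the
  ## loop above fills t = di*b + dj + 1 which is exactly that order
  attr(X, "n") <- n
  attr(X, "cfg") <- cfg
  X
}

#' Aggregate patches back into an image (adjoint of extraction)
#'
#' The transpose `R^T`: each patch column is added back at its origin
#' (modulo `n` under wrap), so `<R u, Y> == <u, R^T Y>` for all `u`, `Y`.
#' With `stride = 1` and wrap, `aggregate_patches(extract_patches(u)) == b^2 u`.
#'
#' @param Pm `M x I` patch matrix as produced by [extract_patches()].
#' @param n image side length.
#' @param cfg the [patch_config()] used for extraction (defaults to the one
#'   attached to `Pm`).
#' @return complex `n x n` image matrix.
#' @export
aggregate_patches <- function(Pm, n = attr(Pm, "n"), cfg = attr(Pm, "cfg")) {
  if (is.null(n)) stop("image size n is required")
  if (is.null(cfg)) cfg <- patch_config()
  org <- patch_origins(n, cfg)
  no <- length(org)
  if (ncol(Pm) != no * no || nrow(Pm) != cfg$M)
    stop("patch matrix shape inconsistent with n and configuration")
  oi <- rep(org, each = no)
  oj <- rep(org, times = no)
  u <- matrix(0 + 0i, n, n)
  t <- 0L
  for (di in 0:(cfg$b - 1L)) {
    for (dj in 0:(cfg$b - 1L)) {
      t <- t + 1L
      ii <- if (cfg$wrap) ((oi + di - 1L) %% n) + 1L else oi + di
      jj <- if (cfg$wrap) ((oj + dj - 1L) %% n) + 1L else oj + dj
      ## for a fixed offset each origin maps to a distinct pixel, so plain
      ## assignment-accumulation is safe
      idx <- cbind(ii, jj)
      u[idx] <- u[idx] + Pm[t, ]
    }
  }
  u
}
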