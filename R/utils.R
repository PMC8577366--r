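## Internal numerical utilities shared across modules.

# Derive a per-stage/per-item child seed from a base seed; keeps results
# independently reproducible per stage. Stays below 2^31.
childSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 1000003 * as.numeric(index)) %% 2147483587)
}

withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Gaussian smoothing with circular boundary via FFT; sigma in pixels.
gaussSmooth <- function(z, sigma) {
  if (sigma <= 0) return(z)
  n1 <- nrow(z); n2 <- ncol(z)
  g1 <- stats::dnorm(c(0:(n1 %/% 2), -(((n1 - 1) %/% 2):1)), sd = sigma)
  g2 <- stats::dnorm(c(0:(n2 %/% 2), -(((n2 - 1) %/% 2):1)), sd = sigma)
  K <- outer(g1, g2)
  K <- K / sum(K)
  Re(stats::fft(stats::fft(z) * stats::fft(K), inverse = TRUE)) / (n1 * n2)
}

# Bilinear sampling of matrix `m` (pixel centres at (i - 0.5) * ps um from the
# top-left corner) at physical coordinates (y, x) in um. Edge-replicating.
# NaN-aware: weights of non-finite neighbours are renormalised; all-NaN
# neighbourhoods yield NaN.
bilinearAt <- function(m, ps, y, x) {
  i <- y / ps + 0.5
  j <- x / ps + 0.5
  i0 <- pmin(pmax(floor(i), 1), max(nrow(m) - 1, 1))
  j0 <- pmin(pmax(floor(j), 1), max(ncol(m) - 1, 1))
  di <- pmin(pmax(i - i0, 0), 1)
  dj <- pmin(pmax(j - j0, 0), 1)
  i1 <- pmin(i0 + 1, nrow(m))
  j1 <- pmin(j0 + 1, ncol(m))
  v00 <- m[cbind(i0, j0)]; v10 <- m[cbind(i1, j0)]
  v01 <- m[cbind(i0, j1)]; v11 <- m[cbind(i1, j1)]
  w00 <- (1 - di) * (1 - dj); w10 <- di * (1 - dj)
  w01 <- (1 - di) * dj;       w11 <- di * dj
  if (anyNA(c(v00, v10, v01, v11))) {
    W <- cbind(w00, w10, w01, w11)
    V <- cbind(v00, v10, v01, v11)
    W[!is.finite(V)] <- 0
    V[!is.finite(V)] <- 0
    tot <- rowSums(W)
    out <- ifelse(tot > 0, rowSums(W * V) / tot, NaN)
    # keep hard NaN where the *nearest* source pixel is NaN so that invalid
    # force-map cells stay excluded after upscaling
    nearest <- m[cbind(pmin(pmax(round(i), 1), nrow(m)),
                       pmin(pmax(round(j), 1), ncol(m)))]
    out[!is.finite(nearest)] <- NaN
    out
  } else {
    w00 * v00 + w10 * v10 + w01 * v01 + w11 * v11
  }
}

# Bilinear sampling on a full grid of row positions ys / column positions xs.
bilinearGrid <- function(m, ps, ys, xs) {
  g <- expand.grid(y = ys, x = xs)
  matrix(bilinearAt(m, ps, g$y, g$x), length(ys), length(xs))
}

# Resample a matrix from pixel size psIn to psOut (um), centre-aligned.
resampleBilinear <- function(m, psIn, psOut, outDim = NULL) {
  if (is.null(outDim)) outDim <- pmax(1L, as.integer(round(dim(m) * psIn / psOut)))
  ys <- (seq_len(outDim[1]) - 0.5) * psOut
  xs <- (seq_len(outDim[2]) - 0.5) * psOut
  bilinearGrid(m, psIn, ys, xs)
}

# Block mean over f x f blocks; dims must be multiples of f.
blockMean <- function(m, f) {
  nr <- nrow(m) %/% f; nc <- ncol(m) %/% f
  stopifnot(nr * f == nrow(m), nc * f == ncol(m))
  a <- array(m, c(f, nr, f, nc))
  apply(a, c(2, 4), mean)
}

# Deterministic argmax with smallest-row-then-column tie-breaking.
# Returns c(row, col) 1-based, or NULL if everything is NA.
argmaxRC <- function(m, tol = 1e-12) {
  mx <- suppressWarnings(max(m, na.rm = TRUE))
  if (!is.finite(mx)) return(NULL)
  idx <- which(!is.na(m) & m >= mx - tol)
  rows <- (idx - 1L) %% nrow(m) + 1L
  cols <- (idx - 1L) %/% nrow(m) + 1L
  o <- order(rows, cols)[1]
  c(rows[o], cols[o])
}

# Adjusted Fisher-Pearson standardised third moment (sample-size corrected).
skewnessAdj <- function(x) {
  n <- length(x)
  s2 <- mean((x - mean(x))^2)
  if (s2 == 0 || n < 3) return(0)
  g1 <- mean((x - mean(x))^3) / s2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Scale elastic moduli to the network range
#'
#' Affine bijection between EM in kPa on [0, 2] and the tanh output range
#' [-1, 1]: \code{scaleEM} clamps to [0, 2] kPa and maps x to x - 1;
#' \code{unscaleEM} inverts it (clamping to [-1, 1] first). Intensities in
#' [0, 1] are mapped by \code{scaleIntensity} to [-1, 1].
#'
#' @param x numeric array.
#' @return array of the same shape on the target scale.
#' @examples
#' scaleEM(c(0, 1, 2, 2.5))   # -1 0 1 1
#' unscaleEM(scaleEM(0.7))    # 0.7
#' @export
scaleEM <- function(x) pmin(pmax(x, 0), 2) - 1

#' @rdname scaleEM
#' @export
unscaleEM <- function(x) pmin(pmax(x, -1), 1) + 1

#' @rdname scaleEM
#' @export
scaleIntensity <- function(x) 2 * pmin(pmax(x, 0), 1) - 1
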