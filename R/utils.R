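# Internal helpers shared across modules.

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All stochastic operations in the package go
# through this so that case/cohort/augmentation determinism holds regardless
# of the surrounding session.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of per-item seeds from a master seed, kept inside 32-bit
# integer range.
derive_seeds <- function(seed, n) {
  as.integer((as.double(seed) + 9973 * seq_len(n)) %% 2147483587)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

# Bilinear sampling of matrix `img` at (possibly fractional) 1-based row/col
# coordinate matrices. Out-of-bounds samples are filled with `fill`.
sample_bilinear <- function(img, rows, cols, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  get <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    v <- rep(fill, length(r))
    v[ok] <- img[cbind(r[ok], c[ok])]
    v
  }
  v00 <- get(r0, c0); v01 <- get(r0, c0 + 1)
  v10 <- get(r0 + 1, c0); v11 <- get(r0 + 1, c0 + 1)
  out <- v00 * (1 - fr) * (1 - fc) + v01 * (1 - fr) * fc +
    v10 * fr * (1 - fc) + v11 * fr * fc
  matrix(out, nr = nrow(rows), nc = ncol(rows))
}

# Nearest-neighbour sampling; preserves the value alphabet of `img`.
sample_nearest <- function(img, rows, cols, fill = 0L) {
  nr <- nrow(img); nc <- ncol(img)
  r <- round(rows); c <- round(cols)
  ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
  v <- rep(fill, length(r))
  v[ok] <- img[cbind(r[ok], c[ok])]
  matrix(v, nr = nrow(rows), nc = ncol(rows))
}

# Dense separable Gaussian smoothing operator: row-normalised n x n weight
# matrix. Exact for arbitrary sigma (including sigma much larger than n),
# which matters because the elastic recipe uses sigma = 512 on 256-px slices.
gauss_smooth_matrix <- function(n, sigma) {
  idx <- seq_len(n)
  K <- exp(-outer(idx, idx, function(i, j) (i - j)^2) / (2 * sigma^2))
  K / rowSums(K)
}

smooth_field <- function(m, sigma) {
  Kr <- gauss_smooth_matrix(nrow(m), sigma)
  Kc <- gauss_smooth_matrix(ncol(m), sigma)
  Kr %*% m %*% t(Kc)
}
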