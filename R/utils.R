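# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @importFrom EBImage gblur
gauss_blur2d <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- 2 * ceiling(3 * sigma) + 1
  m <- min(dim(mat))
  if (r > m) r <- if (m %% 2 == 1) m else m - 1L   # kernel must fit the image
  EBImage::gblur(mat, sigma = sigma, radius = r, boundary = "replicate")
}

# Bilinear sampling of a matrix at fractional (row, col) positions
# (0-based, pixel centres). Out-of-range positions clamp to the border.
bilinear_sample <- function(mat, row, col) {
  shp <- dim(row)
  nr <- nrow(mat); nc <- ncol(mat)
  r <- clamp(as.vector(row), 0, nr - 1)
  c <- clamp(as.vector(col), 0, nc - 1)
  r0 <- floor(r); c0 <- floor(c)
  r1 <- pmin(r0 + 1, nr - 1); c1 <- pmin(c0 + 1, nc - 1)
  fr <- r - r0; fc <- c - c0
  i00 <- mat[cbind(r0 + 1, c0 + 1)]
  i01 <- mat[cbind(r0 + 1, c1 + 1)]
  i10 <- mat[cbind(r1 + 1, c0 + 1)]
  i11 <- mat[cbind(r1 + 1, c1 + 1)]
  out <- (1 - fr) * ((1 - fc) * i00 + fc * i01) + fr * ((1 - fc) * i10 + fc * i11)
  if (!is.null(shp)) dim(out) <- shp
  out
}

# Trilinear sampling of a [slice, row, col] array at fractional 0-based
# (slice, row, col) positions.
trilinear_sample <- function(arr, slice, row, col) {
  d <- dim(arr)
  s <- clamp(as.vector(slice), 0, d[1] - 1)
  r <- clamp(as.vector(row), 0, d[2] - 1)
  c <- clamp(as.vector(col), 0, d[3] - 1)
  s0 <- floor(s); r0 <- floor(r); c0 <- floor(c)
  s1 <- pmin(s0 + 1, d[1] - 1)
  r1 <- pmin(r0 + 1, d[2] - 1)
  c1 <- pmin(c0 + 1, d[3] - 1)
  fs <- s - s0; fr <- r - r0; fc <- c - c0
  v <- function(si, ri, ci) arr[cbind(si + 1, ri + 1, ci + 1)]
  lo <- (1 - fr) * ((1 - fc) * v(s0, r0, c0) + fc * v(s0, r0, c1)) +
    fr * ((1 - fc) * v(s0, r1, c0) + fc * v(s0, r1, c1))
  hi <- (1 - fr) * ((1 - fc) * v(s1, r0, c0) + fc * v(s1, r0, c1)) +
    fr * ((1 - fc) * v(s1, r1, c0) + fc * v(s1, r1, c1))
  (1 - fs) * lo + fs * hi
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
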