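# Internal helpers shared across modules.

# Error function via the normal CDF; vectorised, handles Inf.
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Evaluate expr under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Gaussian blur by 2D convolution with a normalized brush.
# `sigma_px` in pixels. Zero padding is right for rendering (dark outside
# the field); flattening uses replicated edges so a uniform image stays
# uniform.
gauss_blur <- function(img, sigma_px, boundary = 0) {
  stop_if_not(sigma_px > 0, "sigma_px must be > 0")
  size <- 2L * as.integer(ceiling(4 * sigma_px)) + 1L
  size <- min(size, 2L * (min(dim(img)) %/% 2L) - 1L)  # brush must fit image
  if (size < 3L) size <- 3L
  brush <- EBImage::makeBrush(size, shape = "gaussian", sigma = sigma_px)
  EBImage::filter2(img, brush, boundary = boundary)
}

# Nearest-pixel index for a physical coordinate.
# Convention: pixel centers sit at integer multiples of pixel_size,
# 0-based, so coordinate 0 is the center of pixel [1] in R indexing.
px_index <- function(coord_um, pixel_size) as.integer(round(coord_um / pixel_size)) + 1L

in_grid <- function(ix, iy, dim_yx) {
  ix >= 1L & ix <= dim_yx[2L] & iy >= 1L & iy <= dim_yx[1L]
}

# Row-normalize a non-negative matrix; zero rows left as zero.
row_normalize <- function(m) {
  rs <- rowSums(m)
  nz <- rs > 0
  m[nz, ] <- m[nz, , drop = FALSE] / rs[nz]
  m
}
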