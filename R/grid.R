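#' Uniform periodic grid
#'
#' Cell-centred periodic lattice with 0-based physical coordinates
#' `x = i * dx`, `i = 0..nx-1`.  Fields on the grid are stored as `nx x ny`
#' matrices with rows indexing x and columns indexing y.
#'
#' @param nx,ny Number of grid points.
#' @param dx Grid spacing (same in both directions).
#' @return A `grid_spec` with coordinate vectors `x`, `y`, coordinate matrices
#'   `X`, `Y`, and spectral wavenumber matrices: `KX`, `KY` (full), `DKX`,
#'   `DKY` (Nyquist-zeroed, used for odd derivatives so real fields stay
#'   real), and `K2` (full \eqn{|k|^2} for the Laplacian).
#' @export
grid_spec <- function(nx, ny, dx) {
  stopifnot(nx >= 4, ny >= 4, dx > 0)
  nx <- as.integer(nx); ny <- as.integer(ny)
  x <- (seq_len(nx) - 1) * dx
  y <- (seq_len(ny) - 1) * dx
  kx <- 2 * pi / (nx * dx) * fft_freq(nx)
  ky <- 2 * pi / (ny * dx) * fft_freq(ny)
  dkx <- kx; dky <- ky
  if (nx %% 2 == 0) dkx[nx / 2 + 1] <- 0
  if (ny %% 2 == 0) dky[ny / 2 + 1] <- 0
  KX <- matrix(kx, nx, ny)
  KY <- matrix(ky, nx, ny, byrow = TRUE)
  DKX <- matrix(dkx, nx, ny)
  DKY <- matrix(dky, nx, ny, byrow = TRUE)
  structure(list(nx = nx, ny = ny, dx = dx, x = x, y = y,
                 X = matrix(x, nx, ny), Y = matrix(y, nx, ny, byrow = TRUE),
                 KX = KX, KY = KY, DKX = DKX, DKY = DKY, K2 = KX^2 + KY^2,
                 Lx = nx * dx, Ly = ny * dx),
            class = "grid_spec")
}

# integer FFT frequencies 0, 1, ..., n/2, -(n/2 - 1), ..., -1
fft_freq <- function(n) {
  half <- floor(n / 2)
  c(0:half, seq_len(n - half - 1) - (n - half))
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d, dx = %g (box %g x %g)\n",
              x$nx, x$ny, x$dx, x$Lx, x$Ly))
  invisible(x)
}

#' 2/3-rule dealiasing mask
#'
#' @param grid A [grid_spec()].
#' @return A 0/1 matrix zeroing modes with |k index| > n/3.
#' @export
dealias_mask <- function(grid) {
  fx <- abs(fft_freq(grid$nx)) <= floor(grid$nx / 3)
  fy <- abs(fft_freq(grid$ny)) <= floor(grid$ny / 3)
  outer(fx, fy) * 1.0
}

# ---- spectral helpers (R reference path) -----------------------------------

spec_fft <- function(a) stats::fft(a)

spec_ifft <- function(ah) Re(stats::fft(ah, inverse = TRUE)) / length(ah)

# first derivatives use the Nyquist-zeroed wavenumbers
ddx <- function(a, grid) spec_ifft(1i * grid$DKX * spec_fft(a))

ddy <- function(a, grid) spec_ifft(1i * grid$DKY * spec_fft(a))

laplacian <- function(a, grid) spec_ifft(-grid$K2 * spec_fft(a))

check_finite <- function(a, what = "field") {
  if (!all(is.finite(a))) stop("non-finite values in ", what, call. = FALSE)
  invisible(a)
}

# minimal-image displacement on the periodic box
wrap_delta <- function(d, L) d - L * round(d / L)

wrap_coord <- function(x, L) x %% L
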