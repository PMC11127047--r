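# Independent oracles used across the suite: plain-loop tensor algebra,
# finite-difference derivatives, and a dense real-space Stokes saddle-point
# solve.  These deliberately avoid the package's vectorized/spectral paths.

# 2x2 matrix per node from component matrices
node_mat <- function(xx, xy, yx, yy, i, j) {
  matrix(c(xx[i, j], yx[i, j], xy[i, j], yy[i, j]), 2, 2)
}

# brute-force flow coupling S(u, Q) by looping over nodes and contracting
# with explicit sums; E, W supplied as component matrices
loop_flow_coupling <- function(q1, q2, exx, exy, wxy, lambda) {
  nx <- nrow(q1); ny <- ncol(q1)
  sxx <- sxy <- matrix(0, nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    Q <- matrix(c(q1[i, j], q2[i, j], q2[i, j], -q1[i, j]), 2, 2)
    E <- matrix(c(exx[i, j], exy[i, j], exy[i, j], -exx[i, j]), 2, 2)
    W <- matrix(c(0, -wxy[i, j], wxy[i, j], 0), 2, 2)
    QE <- sum(Q * E)   # Q_kl E_kl
    S <- Q %*% W - W %*% Q - 2 * lambda * QE * Q + lambda * E +
      lambda * (E %*% Q + Q %*% E - diag(2) * QE)
    sxx[i, j] <- S[1, 1]; sxy[i, j] <- S[1, 2]
  }
  list(sxx = sxx, sxy = sxy)
}

# brute-force elastic stress given Q, H and the four gradient matrices
loop_elastic_stress <- function(q1, q2, h1, h2, dq1x, dq1y, dq2x, dq2y,
                                K, lambda) {
  nx <- nrow(q1); ny <- ncol(q1)
  out <- list(sxx = matrix(0, nx, ny), sxy = matrix(0, nx, ny),
              syx = matrix(0, nx, ny), syy = matrix(0, nx, ny))
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    Q <- matrix(c(q1[i, j], q2[i, j], q2[i, j], -q1[i, j]), 2, 2)
    H <- matrix(c(h1[i, j], h2[i, j], h2[i, j], -h1[i, j]), 2, 2)
    dQ <- array(0, c(2, 2, 2))   # dQ[i, k, l] = d_i Q_kl
    dQ[1, , ] <- matrix(c(dq1x[i, j], dq2x[i, j], dq2x[i, j], -dq1x[i, j]),
                        2, 2)
    dQ[2, , ] <- matrix(c(dq1y[i, j], dq2y[i, j], dq2y[i, j], -dq1y[i, j]),
                        2, 2)
    QH <- sum(Q * H)
    grad <- matrix(0, 2, 2)
    for (a in 1:2) for (b in 1:2)
      grad[a, b] <- sum(dQ[a, , ] * dQ[b, , ])
    S <- Q %*% H - H %*% Q - K * grad +
      lambda * (2 * Q + diag(2)) * QH -
      lambda * H %*% (Q + diag(2) / 2) -
      lambda * (Q + diag(2) / 2) %*% H
    out$sxx[i, j] <- S[1, 1]; out$sxy[i, j] <- S[1, 2]
    out$syx[i, j] <- S[2, 1]; out$syy[i, j] <- S[2, 2]
  }
  out
}

# periodic central-difference first derivative along rows (x) / cols (y)
fd_ddx <- function(a, dx) {
  n <- nrow(a)
  (a[c(2:n, 1), , drop = FALSE] - a[c(n, 1:(n - 1)), , drop = FALSE]) /
    (2 * dx)
}

fd_ddy <- function(a, dx) t(fd_ddx(t(a), dx))

fd_laplacian <- function(a, dx) {
  n <- nrow(a); m <- ncol(a)
  (a[c(2:n, 1), ] + a[c(n, 1:(n - 1)), ] +
   a[, c(2:m, 1)] + a[, c(m, 1:(m - 1))] - 4 * a) / dx^2
}

# dense saddle-point Stokes solve with central differences: unknowns
# (ux, uy, p); gauge fixed by minimum-norm least squares.  The forcing is
# computed from the package's stress fields by central differences.
dense_stokes_oracle <- function(q, alpha, params) {
  g <- q$grid
  n <- g$nx * g$ny
  H <- molecular_field(q, params)
  sel <- elastic_stress(q, H, params)
  sa <- active_stress(q, alpha, params)
  sxx <- sel$sxx + sa$sxx; sxy <- sel$sxy + sa$sxy
  syx <- sel$syx + sa$syx; syy <- sel$syy + sa$syy
  fx <- fd_ddx(sxx, g$dx) + fd_ddy(syx, g$dx)
  fy <- fd_ddx(sxy, g$dx) + fd_ddy(syy, g$dx)
  idx <- function(i, j) (j - 1) * g$nx + i
  wrap <- function(i, n) (i - 1) %% n + 1
  trip <- list(i = integer(0), j = integer(0), x = numeric(0))
  add <- function(r, c, v) {
    trip$i <<- c(trip$i, r); trip$j <<- c(trip$j, c); trip$x <<- c(trip$x, v)
  }
  nun <- 3 * n   # ux (1..n), uy (n+1..2n), p (2n+1..3n)
  rows <- 3 * n
  for (j in seq_len(g$ny)) for (i in seq_len(g$nx)) {
    e <- idx(i, j)
    ip <- idx(wrap(i + 1, g$nx), j); im <- idx(wrap(i - 1, g$nx), j)
    jp <- idx(i, wrap(j + 1, g$ny)); jm <- idx(i, wrap(j - 1, g$ny))
    # x momentum (row e): -Gamma ux + eta lap ux - dx p + fx = 0
    trip_row <- e
    add(trip_row, ip, params$eta / g$dx^2)
    add(trip_row, im, params$eta / g$dx^2)
    add(trip_row, jp, params$eta / g$dx^2)
    add(trip_row, jm, params$eta / g$dx^2)
    add(trip_row, e, -4 * params$eta / g$dx^2 - params$Gamma)
    add(trip_row, 2 * n + ip, -1 / (2 * g$dx))
    add(trip_row, 2 * n + im, +1 / (2 * g$dx))
    # y momentum (row n + e)
    r2 <- n + e
    add(r2, n + ip, params$eta / g$dx^2)
    add(r2, n + im, params$eta / g$dx^2)
    add(r2, n + jp, params$eta / g$dx^2)
    add(r2, n + jm, params$eta / g$dx^2)
    add(r2, n + e, -4 * params$eta / g$dx^2 - params$Gamma)
    add(r2, 2 * n + jp, -1 / (2 * g$dx))
    add(r2, 2 * n + jm, +1 / (2 * g$dx))
    # incompressibility (row 2n + e)
    r3 <- 2 * n + e
    add(r3, ip, 1 / (2 * g$dx)); add(r3, im, -1 / (2 * g$dx))
    add(r3, n + jp, 1 / (2 * g$dx)); add(r3, n + jm, -1 / (2 * g$dx))
  }
  A <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                            dims = c(rows, nun))
  b <- c(-as.vector(fx), -as.vector(fy), rep(0, n))
  # minimum-norm least-squares solve (pressure has null modes under central
  # differences)
  sol <- MASS::ginv(as.matrix(A)) %*% b
  list(ux = matrix(sol[1:n], g$nx, g$ny),
       uy = matrix(sol[n + 1:n], g$nx, g$ny))
}

# band-limited random field (smooth on the grid)
bandlimited_field <- function(grid, kmax_index = 2, amp = 0.1, seed = 1) {
  set.seed(seed)
  a <- matrix(0, grid$nx, grid$ny)
  for (kx in -kmax_index:kmax_index) for (ky in -kmax_index:kmax_index) {
    a <- a + stats::rnorm(1, sd = amp) *
      cos(2 * pi * (kx * grid$X / grid$Lx + ky * grid$Y / grid$Ly) +
            stats::runif(1, 0, 2 * pi))
  }
  a
}

# brute-force O(n^2) segment-intersection crossing counter for world lines
# projected on (coord, time)
brute_crossings <- function(df, coord = "x") {
  ids <- sort(unique(df$id))
  count <- 0L
  for (a in seq_along(ids)) for (b in seq_along(ids)) {
    if (b <= a) next
    da <- df[df$id == ids[a], ]; db <- df[df$id == ids[b], ]
    shared <- sort(intersect(da$frame, db$frame))
    if (length(shared) < 2) next
    xa <- da[[coord]][match(shared, da$frame)]
    xb <- db[[coord]][match(shared, db$frame)]
    for (m in seq_len(length(shared) - 1)) {
      d1 <- xa[m] - xb[m]; d2 <- xa[m + 1] - xb[m + 1]
      if (d1 == 0) d1 <- .Machine$double.eps
      if (d2 == 0) d2 <- .Machine$double.eps
      if (sign(d1) != sign(d2)) count <- count + 1L
    }
  }
  count
}
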