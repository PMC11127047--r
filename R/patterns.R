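#' Space-time activity patterns
#'
#' An `activity_pattern` wraps a pure function `(grid, t) -> alpha matrix`
#' (activity in dimensionless units of \eqn{K\Gamma/\gamma}) together with
#' metadata: the pattern kind, its extremal value `alpha0`, angular harmonic
#' content, and validity flags (sign-constancy, below-threshold).  Patterns
#' compose additively with [superpose()].
#'
#' @param fn Function of `(grid, t)` returning an `nx x ny` activity matrix.
#' @param kind Character tag.
#' @param alpha0 Extremal activity value.
#' @param harmonics Integer vector of angular harmonic indices present.
#' @param sign_constant Logical: the sampled field never changes sign.
#' @param ... Further metadata stored alongside.
#' @return An object of class `activity_pattern`.
#' @export
activity_pattern <- function(fn, kind = "custom", alpha0 = NA_real_,
                             harmonics = integer(0), sign_constant = NA, ...) {
  stopifnot(is.function(fn))
  structure(list(fn = fn, kind = kind, alpha0 = alpha0,
                 harmonics = harmonics, sign_constant = sign_constant,
                 meta = list(...)),
            class = "activity_pattern")
}

#' @export
print.activity_pattern <- function(x, ...) {
  cat(sprintf("<activity_pattern> kind = %s, alpha0 = %g, harmonics = {%s}\n",
              x$kind, x$alpha0, paste(x$harmonics, collapse = ",")))
  invisible(x)
}

#' Sample an activity pattern on a grid
#'
#' @param pattern An [activity_pattern()], a matrix, a scalar, or `NULL`
#'   (zero activity).
#' @param grid A [grid_spec()].
#' @param t Time.
#' @return An `nx x ny` activity matrix (dimensionless units).
#' @export
sample_pattern <- function(pattern, grid, t = 0) {
  if (is.null(pattern)) return(matrix(0, grid$nx, grid$ny))
  if (is.matrix(pattern)) return(pattern)
  if (is.numeric(pattern) && length(pattern) == 1)
    return(matrix(pattern, grid$nx, grid$ny))
  stopifnot(inherits(pattern, "activity_pattern"))
  a <- pattern$fn(grid, t)
  stopifnot(all(dim(a) == c(grid$nx, grid$ny)))
  a
}

# polar angle about a centre with periodic minimal-image displacements
polar_about <- function(grid, center) {
  dxm <- wrap_delta(grid$X - center[1], grid$Lx)
  dym <- wrap_delta(grid$Y - center[2], grid$Ly)
  list(r = sqrt(dxm^2 + dym^2), phi = atan2(dym, dxm), dx = dxm, dy = dym)
}

resolve_path <- function(x, t) if (is.function(x)) x(t) else x

#' Active topological tweezer
#'
#' A disc of radius `R` about a (possibly moving) centre carrying the
#' sign-constant quadrupolar profile
#' \eqn{\alpha(r) = \alpha_0 [1 + A \sin 2\phi + B \cos 2\phi]} for
#' \eqn{r \le R} and 0 outside, with \eqn{\phi} the polar angle about the
#' centre.  The quadrupole (n = 2 harmonic) satisfies the translation
#' selection rule \eqn{|s - n| = 1} for both defect species; sign constancy
#' requires \eqn{A^2 + B^2 \le 1}, and stability of the surrounding nematic
#' requires \eqn{|\alpha_0|} below [max_stable_activity()].
#'
#' @param alpha0 Overall (extensile, negative) activity.
#' @param R Disc radius.
#' @param center Length-2 centre, or a function `t -> c(x, y)` (the tweezer
#'   path).
#' @param A,B Quadrupole coefficients, constants or functions of `t`.
#' @param params Optional [model_params()]: if given, `|alpha0|` above the
#'   bend bound triggers a warning (not an error; nucleation deliberately
#'   exceeds it).
#' @param smooth Optional edge-smoothing margin (0 = hard cutoff, as defined).
#' @param core_radius Optional radius over which the quadrupolar part grows
#'   quadratically from the centre, `A(r) = min(1, (r/core_radius)^2)`
#'   (0 = radially constant quadrupole).  A smooth quadratic core gives the
#'   pattern a finite second derivative at the defect position, which is
#'   what actually propels a -1/2 defect; the radially constant profile has
#'   a conical singularity there whose drive the texture largely
#'   compensates.
#' @return An [activity_pattern()].
#' @export
tweezer <- function(alpha0, R, center, A = 0, B = 0, params = NULL,
                    smooth = 0, core_radius = 0) {
  stopifnot(R > 0)
  if (!is.function(A) && !is.function(B) && A^2 + B^2 > 1 + 1e-12)
    stop("A^2 + B^2 > 1: quadrupole would violate sign constancy")
  if (!is.null(params) && abs(alpha0) > max_stable_activity(R, params))
    warning("|alpha0| exceeds the bend-instability bound for this radius")
  fn <- function(grid, t) {
    ct <- resolve_path(center, t)
    At <- resolve_path(A, t); Bt <- resolve_path(B, t)
    if (At^2 + Bt^2 > 1 + 1e-12)
      stop("A(t)^2 + B(t)^2 > 1: sign-constancy violated")
    p <- polar_about(grid, ct)
    ramp <- if (core_radius > 0) pmin(1, (p$r / core_radius)^2) else 1
    prof <- alpha0 * (1 + ramp * (At * sin(2 * p$phi) + Bt * cos(2 * p$phi)))
    if (smooth > 0) prof * logistic((R - p$r) / (smooth / 4)) else
      prof * (p$r <= R)
  }
  activity_pattern(fn, kind = "tweezer", alpha0 = alpha0,
                   harmonics = c(0L, 2L), sign_constant = TRUE,
                   R = R, center = center, A = A, B = B,
                   core_radius = core_radius)
}

#' Harmonic activity disc
#'
#' A disc carrying a single angular harmonic plus the n = 0 offset required
#' for sign constancy: \eqn{\alpha = \alpha_0[1 + \cos(n\phi -
#' \mathrm{phase})]} on \eqn{r \le R} (for `n = 0` simply
#' \eqn{\alpha = \alpha_0} on the disc).  With `include_offset = FALSE` the
#' pure harmonic \eqn{\alpha_0\cos(n\phi - \mathrm{phase})} is returned;
#' such a pattern changes sign and is intended for linear-response
#' measurements, where it equals the difference between the offset pattern
#' and its n = 0 control.
#'
#' @param n Harmonic index (integer, >= 0).
#' @param phase Angular phase of the harmonic.
#' @param R Disc radius.
#' @param alpha0 Activity amplitude.
#' @param center Disc centre (length 2, or function of t).
#' @param include_offset Include the sign-constancy offset (default TRUE).
#' @return An [activity_pattern()].
#' @export
harmonic_disc <- function(n, phase = 0, R, alpha0, center,
                          include_offset = TRUE) {
  stopifnot(n >= 0, n == round(n), R > 0)
  n <- as.integer(n)
  fn <- function(grid, t) {
    p <- polar_about(grid, resolve_path(center, t))
    prof <- if (n == 0) alpha0 + 0 * p$phi else
      if (include_offset) alpha0 * (1 + cos(n * p$phi - phase)) else
        alpha0 * cos(n * p$phi - phase)
    prof * (p$r <= R)
  }
  activity_pattern(fn, kind = "harmonic_disc", alpha0 = alpha0,
                   harmonics = if (n == 0 || include_offset)
                     unique(c(0L, n)) else n,
                   sign_constant = include_offset || n == 0,
                   n = n, phase = phase, R = R, center = center)
}

logistic <- function(z) 1 / (1 + exp(-z))

#' Static activity strip
#'
#' A 1D strip of width `Ws` centred at `X0`, with activity varying as a
#' logistic sigmoid of width parameter \eqn{\delta = w/4} across each
#' interface: \eqn{\alpha(x) = \alpha_0\,\sigma((W_s/2 - |x - X_0|)/\delta)}.
#' The choice \eqn{\delta = w/4} makes the interfacial gradient exactly
#' \eqn{|d\alpha/dx| = |\alpha_0|/w} at \eqn{|x - X_0| = W_s/2}.
#'
#' @param Ws Strip width.
#' @param w Interface width (sets the gradient \eqn{\alpha_x = \alpha_0/w}).
#' @param alpha0 Maximal (interior) activity.
#' @param X0 Strip centre (x), constant or function of t.
#' @return An [activity_pattern()] whose metadata records the interfacial
#'   slope `alpha_x = abs(alpha0)/w`.
#' @export
strip <- function(Ws, w, alpha0, X0) {
  stopifnot(Ws > 0, w > 0)
  if (Ws < 2 * w) warning("Ws < 2w: the two interfaces overlap")
  fn <- function(grid, t) {
    x0 <- resolve_path(X0, t)
    dxm <- abs(wrap_delta(grid$X - x0, grid$Lx))
    alpha0 * logistic((Ws / 2 - dxm) / (w / 4))
  }
  activity_pattern(fn, kind = "strip", alpha0 = alpha0, harmonics = integer(0),
                   sign_constant = TRUE, Ws = Ws, w = w, X0 = X0,
                   alpha_x = abs(alpha0) / w)
}

#' Oscillating-width activity strip
#'
#' Strip whose interface width varies sinusoidally,
#' \eqn{w(t) = \bar w + \Delta w \sin(2\pi f t)} with
#' \eqn{\bar w = (w_{min} + w_{max})/2}.
#'
#' @param Ws Strip width.
#' @param wmin,wmax Extremes of the interface width.
#' @param f Oscillation frequency.
#' @param alpha0 Maximal activity.
#' @param X0 Strip centre.
#' @return An [activity_pattern()]; metadata exposes `f` and `w_bar`.
#' @export
oscillating_strip <- function(Ws, wmin, wmax, f, alpha0, X0) {
  stopifnot(wmin > 0, wmax >= wmin)
  wbar <- (wmin + wmax) / 2; dw <- (wmax - wmin) / 2
  fn <- function(grid, t) {
    wt <- wbar + dw * sin(2 * pi * f * t)
    dxm <- abs(wrap_delta(grid$X - resolve_path(X0, t), grid$Lx))
    alpha0 * logistic((Ws / 2 - dxm) / (wt / 4))
  }
  activity_pattern(fn, kind = "oscillating_strip", alpha0 = alpha0,
                   sign_constant = TRUE, Ws = Ws, wmin = wmin, wmax = wmax,
                   freq = f, w_bar = wbar, X0 = X0)
}

#' Traveling activity strip
#'
#' Strip translating at constant speed V with periodic wrap:
#' \eqn{X_0(t) = X_0(0) + V t}.
#'
#' @param Ws Strip width.
#' @param w Interface width.
#' @param alpha0 Maximal activity.
#' @param V Strip speed.
#' @param X0 Initial centre.
#' @return An [activity_pattern()]; metadata exposes `V`.
#' @export
traveling_strip <- function(Ws, w, alpha0, V, X0) {
  base <- strip(Ws, w, alpha0, X0 = function(t) X0 + V * t)
  base$kind <- "traveling_strip"
  base$meta$V <- V
  base
}

#' Elliptic nucleation patch
#'
#' A localized elliptic patch whose activity is ramped linearly from 0 to
#' `alpha_peak` over `ramp_time` (then held until `t_off`, with an optional
#' linear release).  `alpha_peak` deliberately exceeds the bend-instability
#' bound so that a single \eqn{(+1/2, -1/2)} pair nucleates; the ellipse
#' orientation sets the axis along which the pair separates.
#'
#' @param center Patch centre.
#' @param axes Length-2 semi-axes `c(a, b)` (a = major).
#' @param orientation Major-axis angle (radians).
#' @param alpha_peak Peak activity (large, extensile).
#' @param ramp_time Linear ramp duration (0 = step).
#' @param t_on Switch-on time (default 0).
#' @param t_off Hold end; activity is released linearly over `release_time`
#'   after `t_off` (default `Inf` = held forever).
#' @param release_time Release ramp duration (default 0 = step off).
#' @return An [activity_pattern()].
#' @export
nucleation_patch <- function(center, axes, orientation = 0, alpha_peak,
                             ramp_time, t_on = 0, t_off = Inf,
                             release_time = 0) {
  stopifnot(length(axes) == 2, all(axes > 0))
  fn <- function(grid, t) {
    amp <- if (t < t_on) 0
    else if (ramp_time > 0 && t < t_on + ramp_time) (t - t_on) / ramp_time
    else if (t <= t_off) 1
    else if (release_time > 0 && t < t_off + release_time)
      1 - (t - t_off) / release_time
    else 0
    if (amp == 0) return(matrix(0, grid$nx, grid$ny))
    p <- polar_about(grid, center)
    co <- cos(orientation); si <- sin(orientation)
    xr <- p$dx * co + p$dy * si
    yr <- -p$dx * si + p$dy * co
    inside <- (xr / axes[1])^2 + (yr / axes[2])^2 <= 1
    (alpha_peak * amp) * inside
  }
  activity_pattern(fn, kind = "nucleation_patch", alpha0 = alpha_peak,
                   sign_constant = TRUE, center = center, axes = axes,
                   orientation = orientation, ramp_time = ramp_time,
                   t_on = t_on, t_off = t_off, release_time = release_time)
}

#' Superpose activity patterns
#'
#' Pointwise sum of patterns; by linearity of the Stokes problem at fixed Q,
#' the flows driven by superposed patterns add.
#'
#' @param ... [activity_pattern()] objects (or a single list of them).
#' @return An [activity_pattern()] with merged harmonic metadata.
#' @export
superpose <- function(...) {
  pats <- list(...)
  if (length(pats) == 1 && is.list(pats[[1]]) &&
      !inherits(pats[[1]], "activity_pattern")) pats <- pats[[1]]
  stopifnot(all(vapply(pats, inherits, TRUE, "activity_pattern")))
  fn <- function(grid, t) {
    Reduce(`+`, lapply(pats, function(p) sample_pattern(p, grid, t)))
  }
  activity_pattern(fn, kind = "superpose",
                   alpha0 = sum(vapply(pats, function(p) p$alpha0, 0)),
                   harmonics = sort(unique(unlist(lapply(pats, `[[`,
                                                         "harmonics")))),
                   sign_constant = NA, parts = pats)
}

#' Scale an activity pattern by a constant
#'
#' @param pattern An [activity_pattern()].
#' @param factor Multiplier (use -1 to negate).
#' @return An [activity_pattern()].
#' @export
scale_pattern <- function(pattern, factor) {
  stopifnot(inherits(pattern, "activity_pattern"))
  fn <- function(grid, t) factor * sample_pattern(pattern, grid, t)
  activity_pattern(fn, kind = pattern$kind, alpha0 = factor * pattern$alpha0,
                   harmonics = pattern$harmonics,
                   sign_constant = pattern$sign_constant)
}

#' Symmetry selection rule for defect mobility
#'
#' For a defect texture of dihedral symmetry index `s` (\eqn{s = 2|1-\nu|};
#' 1 for +1/2, 3 for -1/2) in an n-fold symmetric activity pattern, a
#' necessary condition for self-propulsion is \eqn{|s - n| = 1} and for
#' self-rotation \eqn{|s - n| = 0}.
#'
#' @param s Defect symmetry index (odd positive integer).
#' @param n Activity harmonic index (integer >= 0).
#' @return A list `can_translate`, `can_rotate` (vectorized over s, n).
#' @export
predicted_mobility <- function(s, n) {
  stopifnot(all(s >= 1), all(n >= 0))
  list(can_translate = abs(s - n) == 1, can_rotate = abs(s - n) == 0)
}
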