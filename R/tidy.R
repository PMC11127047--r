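#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.sinusoid_fit <- function(x, ...) {
  tibble::tibble(term = c("D_bar", "Delta_D", "tau_D"),
                 estimate = c(x$D_bar, x$Delta_D, x$tau_D),
                 std.error = c(x$se_D_bar, x$se_Delta_D, NA_real_))
}

#' @export
glance.sinusoid_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(f = x$f, r.squared = s$r.squared,
                 sigma = s$sigma, degenerate = x$degenerate,
                 nobs = stats::nobs(x$fit))
}

#' @export
tidy.diffusion_fit <- function(x, ...) {
  tibble::tibble(term = c("Da", "tau_R", "mean_u2"),
                 estimate = c(x$Da, x$tau_R, x$mean_u2),
                 std.error = c(x$sd_Da, NA_real_, NA_real_))
}

#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble::tibble(Da = x$Da, tau_R = x$tau_R, mean_u2 = x$mean_u2,
                 n_segments = x$n_segments, nondecay = x$nondecay)
}

#' @export
tidy.response_calibration <- function(x, ...) {
  tibble::tibble(term = c("zeta1", "zeta2", "zeta3", "zeta4"),
                 estimate = c(x$zeta1, x$zeta2, x$zeta3, x$zeta4))
}

#' @export
tidy.dipole_experiment <- function(x, ...) {
  tibble::tibble(term = sprintf("D(w=%g)", x$w), estimate = x$D,
                 std.error = x$sd)
}

#' @export
glance.tweezer_run <- function(x, ...) {
  tibble::tibble(path_total = x$path_total, max_sep = x$max_sep,
                 success = x$success, V = x$V, R = x$R)
}
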