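#' Gradient amplitude and slew rate of circular encoding
#'
#' A circle of radius `R` traversed at one revolution per spectral dwell
#' (angular rate `omega = 2*pi*sbw`) requires a rotating gradient of
#' constant amplitude `G = R*omega/gamma_bar` and constant slew rate
#' `S = G*omega`; both are constant in time, which is what makes the
#' eccentric-circle readout gentle on gradient hardware compared to
#' trajectories with sharp turns.
#'
#' @param R Circle radius (cycles/m), > 0.
#' @param sbw Spectral bandwidth (Hz), > 0; equals the revolution frequency.
#' @param gamma_bar Gyromagnetic ratio (Hz/T); default 42.577e6 for 1H.
#' @return A list of class `gradient_demand` with `amplitude` (T/m),
#'   `slew` (T/m/s) and `gamma_bar`.
#' @examples
#' gradient_demand(R = 8 / 0.22, sbw = 2280)  # ~12.2 mT/m, ~175 T/m/s
#' @export
gradient_demand <- function(R, sbw, gamma_bar = 42.577e6) {
  if (R <= 0) stop("R must be positive")
  if (sbw <= 0) stop("sbw must be positive")
  omega <- 2 * pi * sbw
  amp <- R * omega / gamma_bar
  structure(list(amplitude = amp, slew = amp * omega, gamma_bar = gamma_bar),
            class = "gradient_demand")
}

#' @export
print.gradient_demand <- function(x, ...) {
  cat(sprintf("gradient_demand: amplitude %.3f mT/m, slew %.1f T/m/s\n",
              1e3 * x$amplitude, x$slew))
  invisible(x)
}

#' Maximum spectral bandwidth under gradient hardware limits
#'
#' Inverts [gradient_demand()]: the largest revolution frequency a circle of
#' radius `R` admits before hitting the amplitude limit `g_max` or the slew
#' limit `s_max`,
#' `min(g_max*gamma_bar/(2*pi*R), sqrt(s_max*gamma_bar/R)/(2*pi))`.
#' Infinite limits give an infinite (unbounded) bandwidth.
#'
#' @param R Circle radius (cycles/m).
#' @param g_max Peak gradient limit (T/m).
#' @param s_max Peak slew-rate limit (T/m/s).
#' @param gamma_bar Gyromagnetic ratio (Hz/T).
#' @return Maximum spectral bandwidth (Hz).
#' @examples
#' max_sbw(8 / 0.22, g_max = 80e-3, s_max = 200)  # ~2436 Hz
#' @export
max_sbw <- function(R, g_max, s_max, gamma_bar = 42.577e6) {
  if (g_max <= 0 || s_max <= 0) stop("limits must be positive")
  min(g_max * gamma_bar / (2 * pi * R),
      sqrt(s_max * gamma_bar / R) / (2 * pi))
}

#' Sequence timing of a plan
#'
#' Total acquisition time is one repetition per circle, `ta = Nc * tr`; the
#' FID duration is `n_time / sbw`. The circle count may be given explicitly
#' (e.g. a protocol's printed count) instead of a plan.
#'
#' @param plan A `trajectory_plan`, or `NULL` if `n_circles_override` given.
#' @param tr Repetition time (s), > 0.
#' @param n_circles_override Explicit number of excitations.
#' @param n_time,sbw Override the plan's spectral settings.
#' @return A list of class `sequence_timing` with `tr`, `n_excitations`,
#'   `ta` (s) and `fid_duration` (s).
#' @examples
#' sequence_timing(NULL, tr = 0.275, n_circles_override = 4072,
#'                 n_time = 500, sbw = 2280)   # ta = 1119.8 s (18 min 40 s)
#' @export
sequence_timing <- function(plan, tr, n_circles_override = NULL,
                            n_time = NULL, sbw = NULL) {
  if (tr <= 0) stop("tr must be positive")
  nc <- if (!is.null(n_circles_override)) as.integer(n_circles_override)
        else n_circles(plan)
  nt <- if (!is.null(n_time)) n_time else plan$n_time
  bw <- if (!is.null(sbw)) sbw else plan$sbw
  structure(list(tr = tr, n_excitations = nc, ta = nc * tr,
                 fid_duration = nt / bw),
            class = "sequence_timing")
}

#' @export
print.sequence_timing <- function(x, ...) {
  mins <- floor(x$ta / 60); secs <- round(x$ta - 60 * mins)
  cat(sprintf("sequence_timing: %d excitations x TR %.3g s = %.1f s (%d min %d s); FID %.1f ms\n",
              x$n_excitations, x$tr, x$ta, mins, secs, 1e3 * x$fid_duration))
  invisible(x)
}
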