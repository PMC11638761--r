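#' Synthetic metabolite spectral basis
#'
#' A small prior-knowledge basis for simulation and linear-combination
#' fitting. Each metabolite is a list of resonances (chemical shift in ppm,
#' relative amplitude) plus an optional extra damping rate (1/s) that
#' broadens it beyond the voxel T2* (used for the mobile-lipid resonance).
#' The chemical-shift axis is referenced so that water (4.7 ppm) is at
#' 0 Hz offset; `hz_per_ppm` defaults to 297.2 Hz/ppm (7 T).
#'
#' @param metabolites Named list; each element a list with `ppm` (numeric
#'   vector), `amp` (matching positive amplitudes) and optional
#'   `extra_damping` (1/s). Defaults: water (4.7), NAA (2.01), total
#'   creatine (3.03 + 3.91), choline (3.2), broad lipid (1.3).
#' @param hz_per_ppm Hz per ppm at the field strength (default 297.2).
#' @param ref_ppm Carrier reference (water, 4.7 ppm).
#' @return Object of class `spectral_basis`.
#' @export
spectral_basis <- function(metabolites = NULL, hz_per_ppm = 297.2, ref_ppm = 4.7) {
  if (is.null(metabolites)) {
    metabolites <- list(
      water = list(ppm = 4.70, amp = 1),
      naa   = list(ppm = 2.01, amp = 1),
      cr    = list(ppm = c(3.03, 3.91), amp = c(0.6, 0.4)),
      cho   = list(ppm = 3.20, amp = 1),
      lipid = list(ppm = 1.30, amp = 1, extra_damping = 1 / 0.010)
    )
  }
  for (nm in names(metabolites)) {
    m <- metabolites[[nm]]
    if (any(m$amp <= 0)) stop("basis amplitudes must be positive")
    if (any(m$ppm < 0 | m$ppm > 9)) stop("chemical shifts must lie in 0-9 ppm")
    if (is.null(m$extra_damping)) metabolites[[nm]]$extra_damping <- 0
  }
  structure(list(metabolites = metabolites, hz_per_ppm = hz_per_ppm,
                 ref_ppm = ref_ppm), class = "spectral_basis")
}

basis_freq_hz <- function(basis, ppm) (ppm - basis$ref_ppm) * basis$hz_per_ppm

#' Synthesize a free induction decay
#'
#' Complex-exponential (Lorentzian-lineshape) signal model:
#' `s(t) = sum_m c_m sum_j a_mj exp(i 2 pi (f_mj + freq_offset) t) *
#' exp(-t * (1/t2star + extra_damping_m))`, with resonance frequencies
#' `f_mj` from the basis chemical shifts relative to water.
#'
#' @param basis A [spectral_basis()].
#' @param concentrations Named numeric vector of concentrations (mM or any
#'   consistent unit); names must be basis metabolites. Missing metabolites
#'   contribute zero.
#' @param t2star Transverse decay time (s), > 0.
#' @param times Sample times (s), starting at the echo time TE >= 0.
#' @param freq_offset Additional frequency offset (Hz), e.g. a B0 shift.
#' @return Complex vector of `length(times)` FID samples.
#' @export
synthesize_fid <- function(basis, concentrations, t2star, times, freq_offset = 0) {
  if (t2star <= 0) stop("t2star must be positive")
  if (any(times < 0)) stop("times must start at TE >= 0")
  s <- complex(real = numeric(length(times)))
  for (nm in names(concentrations)) {
    cm <- concentrations[[nm]]
    if (cm == 0) next
    m <- basis$metabolites[[nm]]
    if (is.null(m)) stop(sprintf("metabolite '%s' not in basis", nm))
    damp <- 1 / t2star + m$extra_damping
    f <- basis_freq_hz(basis, m$ppm) + freq_offset
    for (j in seq_along(f))
      s <- s + cm * m$amp[j] * exp((2i * pi * f[j] - damp) * times)
  }
  s
}

#' Evaluate unit-concentration basis FIDs on a time grid
#'
#' Matrix of per-metabolite FIDs at unit concentration, used by the forward
#' encoder and the linear-combination fit.
#'
#' @inheritParams synthesize_fid
#' @param which Metabolite names (default all).
#' @return Complex `length(times) x length(which)` matrix, columns named.
#' @export
basis_fids <- function(basis, t2star, times, which = NULL, freq_offset = 0) {
  if (is.null(which)) which <- names(basis$metabolites)
  out <- vapply(which, function(nm) {
    cc <- stats::setNames(1, nm)
    synthesize_fid(basis, cc, t2star, times, freq_offset)
  }, complex(length(times)))
  matrix(out, length(times), length(which), dimnames = list(NULL, which))
}
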