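#' Parametric surface-EMG power spectrum
#'
#' Classic two-corner rational model of the surface-EMG power spectral
#' density,
#' \deqn{P(f) = \frac{f_h^4 \, f^2}{(f^2 + f_l^2)(f^2 + f_h^2)^2},}
#' which rises as \eqn{f^2} below the low corner \eqn{f_l}, plateaus, and
#' falls as \eqn{f^{-4}} above the high corner \eqn{f_h}.  Moving both
#' corners down shifts the mean (MPF) and median (MF) power frequency down,
#' which is how symptomatic-side spectral slowing is simulated.
#'
#' @param f_low Low corner frequency (Hz), `0 < f_low < f_high`.
#' @param f_high High corner frequency (Hz), at most 500.
#' @return An object of class `emg_spectrum`.
#' @seealso [spectral_moments()], [fit_spectrum()], [shaped_noise()]
#' @export
#' @examples
#' sp <- emg_spectrum(40, 90)
#' spectral_moments(sp)
emg_spectrum <- function(f_low, f_high) {
  stopifnot(is.numeric(f_low), is.numeric(f_high),
            length(f_low) == 1, length(f_high) == 1)
  if (!(f_low > 0 && f_low < f_high && f_high <= 500))
    stop("emg_spectrum requires 0 < f_low < f_high <= 500 Hz")
  structure(list(f_low = f_low, f_high = f_high), class = "emg_spectrum")
}

#' Evaluate the parametric EMG power spectral density
#'
#' @param f Frequencies (Hz).
#' @param spectrum An [emg_spectrum()].
#' @return Unnormalized PSD values at `f`.
#' @export
emg_psd <- function(f, spectrum) {
  stopifnot(inherits(spectrum, "emg_spectrum"))
  fl <- spectrum$f_low; fh <- spectrum$f_high
  fh^4 * f^2 / ((f^2 + fl^2) * (f^2 + fh^2)^2)
}

#' Mean and median power frequency of a parametric spectrum
#'
#' Computes MPF (power-weighted mean frequency) and MF (frequency splitting
#' the band power in half) of an [emg_spectrum()] by numerical integration on
#' a fine grid.  This is the analytic reference against which empirically
#' extracted MPF/MF of synthesized signals are validated.
#'
#' @param spectrum An [emg_spectrum()].
#' @param band Integration band in Hz, `c(low, high)`.
#' @param df Grid step (Hz).
#' @return List with elements `mpf` and `mf` (Hz).
#' @export
spectral_moments <- function(spectrum, band = c(20, 500), df = 0.1) {
  stopifnot(inherits(spectrum, "emg_spectrum"), length(band) == 2,
            band[1] >= 0, band[1] < band[2])
  f <- seq(max(band[1], df), band[2], by = df)
  p <- emg_psd(f, spectrum)
  tot <- sum(p)
  mpf <- sum(f * p) / tot
  cum <- cumsum(p) - p / 2          # midpoint cumulative
  mf <- approx(cum / tot, f, xout = 0.5, ties = "ordered")$y
  list(mpf = mpf, mf = mf)
}

#' Find spectrum corners matching target MPF (and optionally MF)
#'
#' Inverts [spectral_moments()]: searches the two corner frequencies of the
#' parametric EMG spectrum so that its band-limited MPF (and, if given, MF)
#' match the requested targets in a least-squares sense on the log scale.
#' The family constrains the MF/MPF ratio to roughly 0.78–0.86 over the
#' 20–500 Hz analysis band, so an infeasible pair is matched as closely as
#' the family allows.
#'
#' @param mpf Target mean power frequency (Hz).
#' @param mf Optional target median frequency (Hz).
#' @param band Analysis band used for the moments (Hz).
#' @return An [emg_spectrum()].
#' @export
#' @examples
#' sp <- fit_spectrum(63, 50)
#' spectral_moments(sp)
fit_spectrum <- function(mpf, mf = NULL, band = c(20, 500)) {
  stopifnot(is.numeric(mpf), mpf > band[1], mpf < band[2])
  obj <- function(par) {
    fl <- exp(par[1]); fh <- exp(par[2])
    if (fh <= fl || fh > 500 || fl < 2) return(1e6)
    m <- spectral_moments(emg_spectrum(fl, fh), band = band, df = 0.25)
    e <- (log(m$mpf) - log(mpf))^2
    if (!is.null(mf)) e <- e + (log(m$mf) - log(mf))^2
    e
  }
  o <- optim(c(log(mpf / 2), log(mpf * 1.4)), obj)
  emg_spectrum(exp(o$par[1]), min(500, exp(o$par[2])))
}
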