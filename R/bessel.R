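# Complex-argument Bessel functions J0 and J1.
#
# base::besselJ only accepts real arguments, but the Womersley solution needs
# J0/J1 at z = i^(3/2) * alpha with alpha up to ~25 for pulmonary-scale
# vessels.  Bessel's integral representations
#   J0(z) = (1/pi) Int_0^pi cos(z sin th) dth
#   J1(z) = (1/pi) Int_0^pi cos(th - z sin th) dth
# hold for all complex z and are evaluated here with the midpoint rule, which
# is spectrally accurate for these smooth integrands.  Relative accuracy is
# near machine precision for |z| <= ~40 (the magnitude of the integral is
# commensurate with the magnitude of the result, so there is no catastrophic
# cancellation).  Verified against base::besselJ on the real axis.

bessel_j0_complex <- function(z, n = 256L) {
  th <- (seq_len(n) - 0.5) * pi / n
  s <- sin(th)
  vapply(as.complex(z), function(zz) mean(cos(zz * s)), complex(1))
}

bessel_j1_complex <- function(z, n = 256L) {
  th <- (seq_len(n) - 0.5) * pi / n
  s <- sin(th)
  vapply(as.complex(z), function(zz) mean(cos(th - zz * s)), complex(1))
}
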