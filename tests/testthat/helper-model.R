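## shared fixtures for the suite

default_params <- function(...) qif_params(...)

## closed-form decoupled equilibrium (Je = Ji = 0):
## dr = delta/pi + 2 r v = 0  and  dv = eta + v^2 - pi^2 r^2 = 0
## eliminate v = -delta / (2 pi r); with x = pi^2 r^2:
## x^2 - eta x - delta^2/4 = 0  =>  x = (eta + sqrt(eta^2 + delta^2)) / 2
decoupled_equilibrium <- function(eta_bar = -5, delta = 1) {
  x <- (eta_bar + sqrt(eta_bar^2 + delta^2)) / 2
  r <- sqrt(x) / pi
  v <- -delta / (2 * pi * r)
  c(r = r, v = v)
}

## closed-form free QIF period between reset and peak for drive I > 0
qif_isi_closed_form <- function(I, Vpeak, Vreset = -Vpeak) {
  (atan(Vpeak / sqrt(I)) - atan(Vreset / sqrt(I))) / sqrt(I)
}
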