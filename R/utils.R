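# shared internal helpers

# half-up rounding to `digits` decimals (matches printed-table rendering;
# base round() is half-to-even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# map a standard-normal latent through a lognormal with exact mean/sd
lnorm_from_z <- function(z, mean, sd) {
  stopifnot(mean > 0, sd > 0)
  sdlog <- sqrt(log1p((sd / mean)^2))
  exp(log(mean) - sdlog^2 / 2 + sdlog * z)
}

# multiplicative mean-one day-to-day noise
lnorm_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
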