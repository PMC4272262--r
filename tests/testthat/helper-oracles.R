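# Shared helpers: small independent oracles used across test files.

# Wald-Wolfowitz runs test p-value on the signs of a residual vector
runs_test_p <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  n1 <- sum(s > 0)
  n2 <- sum(s < 0)
  if (n1 == 0 || n2 == 0) return(0)
  r <- 1 + sum(diff(s) != 0)
  mu <- 1 + 2 * n1 * n2 / (n1 + n2)
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n1 - n2) /
    ((n1 + n2)^2 * (n1 + n2 - 1))
  if (v <= 0) return(1)
  2 * stats::pnorm(-abs((r - mu) / sqrt(v)))
}

# physical constants used by closed-form oracles
KB_ERG <- 1.380649e-16
NAV <- 6.02214076e23
ETA_W20 <- 0.01002
RHO_W20 <- 0.99823

# Stokes-law oracles for a sphere of radius R (cm)
stokes_Dt <- function(R, eta = ETA_W20, T = 293.15)
  KB_ERG * T / (6 * pi * eta * R)
stokes_Dr <- function(R, eta = ETA_W20, T = 293.15)
  KB_ERG * T / (8 * pi * eta * R^3)

# a quick small synthetic parallel-quadruplex CD fixture
parallel_fixture <- function(amp = 10) {
  grid <- 220:340
  cdSpectrum(grid, amp * exp(-(grid - 260)^2 / 100) -
               0.5 * amp * exp(-(grid - 240)^2 / 60),
             units = "molar")
}
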