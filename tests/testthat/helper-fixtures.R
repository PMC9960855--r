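# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except through the round-trip IO tests themselves.

# analytic solid-sphere form factor intensity
sphere_curve <- function(R = 100, qmin = 0.004, qmax = 0.35, n = 300) {
  q <- exp(seq(log(qmin), log(qmax), length.out = n))
  amp <- 3 * (sin(q * R) - q * R * cos(q * R)) / (q * R)^3
  scattering_curve(q, amp^2)
}

# analytic sphere pair-distance distribution (unnormalized)
sphere_pddf <- function(r, R) {
  ifelse(r <= 2 * R, r^2 * (1 - 3 * r / (4 * R) + r^3 / (16 * R^3)), 0)
}

# uniform hollow shell (vesicle without head/tail contrast)
shell_curve <- function(R1 = 440, R2 = 475, qmin = 5e-4, qmax = 0.25,
                        n = 400) {
  q <- exp(seq(log(qmin), log(qmax), length.out = n))
  f <- function(R) (sin(q * R) - q * R * cos(q * R)) / q^3
  amp <- f(R2) - f(R1)
  scattering_curve(q, (amp / amp[1])^2)
}

# closed-form radius of gyration of a uniform hollow shell
shell_rg <- function(R1, R2) sqrt(0.6 * (R2^5 - R1^5) / (R2^3 - R1^3))

kB <- 1.380649e-23

# diffusion coefficient of a sphere in water at temp_C [m^2/s]
stokes_D <- function(radius_A, temp_C) {
  kB * (temp_C + 273.15) /
    (6 * pi * water_viscosity(temp_C) * radius_A * 1e-10)
}
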