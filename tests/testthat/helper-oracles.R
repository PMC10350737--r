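# Independent oracles for cross-checking the package implementation.
# Everything here is written directly from the constitutive definitions and
# never calls the package's stress/energy code paths.

# reference third-order Ogden constants (MPa)
OG_MU <- c(-26.133, 12.922, 13.227)
OG_AL <- c(2.719, 3.996, 1.504)

# term-by-term Ogden energy, standard incompressible form
og_energy_indep <- function(l1, l2, l3)
  sum(2 * OG_MU / OG_AL^2 * (l1^OG_AL + l2^OG_AL + l3^OG_AL - 3))

# central finite difference of an energy path W(lambda)
fd_path_stress <- function(Wfun, lam, h = 1e-6)
  (Wfun(lam + h) - Wfun(lam - h)) / (2 * h)

# a constructed Ogden set that is stable near the identity (mu0 = 0.3 MPa)
# but destabilises under compression around lambda ~ 0.8
unstable_ogden <- function()
  ogden_material(mu = c(-2, 2.3), alpha = c(10, 2), label = "unstable_demo")

# Independent material-point solution of the penalty-compressible
# plane-stress uniaxial problem for a standard-convention Neo-Hookean solid:
# minimise W_dev(J^(-1/3) lambda) + kappa/2 (J-1)^2 + p * lambda_y over
# (lambda_y, lambda_lat) with both lateral directions equal by symmetry.
nh_penalty_uniaxial_indep <- function(c10, p, penalty_factor = 1000) {
  kappa <- penalty_factor * 2 * c10
  W <- function(ly, ll) {
    J <- ly * ll^2
    lb <- J^(-1 / 3) * c(ll, ly, ll)
    c10 * (sum(lb^2) - 3) + kappa / 2 * (J - 1)^2
  }
  dW <- function(f, x, h = 1e-7) (f(x + h) - f(x - h)) / (2 * h)
  lat_for <- function(ly)
    stats::uniroot(function(ll) dW(function(z) W(ly, z), ll),
                   c(0.5, 2), tol = 1e-14)$root
  g <- function(ly) dW(function(z) W(z, lat_for(z)), ly) + p
  stats::uniroot(g, c(0.5, 1), tol = 1e-14)$root
}

# sinusoidal test trace: pressure a*cos + mean, displacement with phase lag
make_sine_trace <- function(p_mean = 1.225, a = 0.475, A = 20, lag = 0,
                            offset = 100, n = 400, f = 1) {
  t_cyc <- seq(1 + 1 / n, 2, by = 1 / n)
  t_all <- c(seq(0, 1, by = 1 / n), t_cyc)
  p <- c(p_mean * seq(0, 1, by = 1 / n), p_mean + a * cos(2 * pi * f * (t_cyc - 1)))
  d <- c(offset * seq(0, 1, by = 1 / n),
         offset + A * cos(2 * pi * f * (t_cyc - 1) - lag))
  solution_trace(t_all, p, d, rep(c("ramp", "cyclic"),
                                  c(n + 1, length(t_cyc))),
                 thickness_mm = 1.305, frequency_Hz = f, label = "sine")
}
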