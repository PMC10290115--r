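# shared fixtures and independent oracles

# truncated-sphere volume/area oracles via sphere minus spherical cap:
# cap height h = r - sqrt(r^2 - a^2); V_cap = pi h^2 (3r - h) / 3;
# A_cap = 2 pi r h. Algebraically independent route from the closed forms
# used in the package.
oracle_v3 <- function(a, r) {
  h <- r - sqrt(r^2 - a^2)
  4 / 3 * pi * r^3 - pi * h^2 * (3 * r - h) / 3
}
oracle_a3 <- function(a, r) {
  h <- r - sqrt(r^2 - a^2)
  4 * pi * r^2 - 2 * pi * r * h
}

# plain bisection on the reference-geometry root, built only on the oracle
# forms above
oracle_solve_geometry <- function(a, V = 90, A = 136, tol = 1e-12) {
  l_of_r <- function(r) (A - 2 * pi * a^2 - oracle_a3(a, r)) / (2 * pi * a)
  f <- function(r)
    2 / 3 * pi * a^3 + pi * a^2 * l_of_r(r) + oracle_v3(a, r) - V
  lo <- a * (1 + 1e-6); hi <- 10
  flo <- f(lo)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (flo * fm <= 0) hi <- mid else { lo <- mid; flo <- fm }
    if (hi - lo < tol) break
  }
  r <- (lo + hi) / 2
  c(r = r, l = l_of_r(r))
}

# standard 10-cycle aspiration fixture
std_schedule <- function(n_cycles = 10) cycle_schedule(n_cycles, 1.95, 1.95)

# interior scoring circle used throughout morphology tests: radius 24 px
# inside the default 40 px cell, well clear of the rim
morph_center <- c(64.5, 64.5)
morph_radius <- 24
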