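test_that("screened Coulomb pair energy has the right closed forms", {
  p_inf <- energy_params(gamma = 1.36, debye_length = Inf)
  expect_equal(pair_energy(1.0, +1, -1, p_inf), -1.36)
  expect_equal(pair_energy(0.5, 0, -1, p_inf), 0)
  # screening multiplies the bare form by exp(-1) at r = lambda_D
  p_scr <- energy_params(gamma = 1.36, debye_length = 3.04)
  expect_equal(pair_energy(3.04, +1, -1, p_scr),
               pair_energy(3.04, +1, -1, p_inf) * exp(-1))
  expect_error(pair_energy(0, 1, -1, p_inf), "positive")
})

test_that("total energy matches a brute-force pair-sum oracle", {
  dna <- build_dna()
  cell <- build_cell()
  par <- energy_params()
  set.seed(7)
  n_finite <- 0
  for (sp in c("SPD", "NSPD")) {
    pa <- build_polyamine(sp)
    for (i in 1:25) {
      ref <- c(runif(1, -2.5, 2.5), runif(1, -2.5, 2.5), runif(1, 0, 3.4))
      ax <- rnorm(3)
      e_fast <- total_energy(pa, dna, cell, par, ref, ax)
      e_slow <- brute_energy(pa, dna, cell, par, ref, ax)
      if (is.finite(e_slow)) {
        n_finite <- n_finite + 1
        expect_equal(e_fast, e_slow, tolerance = 1e-12)
      } else {
        expect_identical(e_fast, Inf)
      }
    }
  }
  expect_gt(n_finite, 10)  # the random poses must exercise the finite branch
})

test_that("uncharged non-penetrating configurations have zero energy", {
  pa <- build_polyamine("SPD")
  pa$charges[] <- 0
  dna <- build_dna()
  cell <- build_cell()
  e <- total_energy(pa, dna, cell, energy_params(), c(1.8, 0, 0.1), c(0, 0, 1))
  expect_equal(e, 0)
})

test_that("energy respects the mirror symmetry of the straight-ladder model", {
  dna <- build_dna()  # twist 0
  cell <- build_cell()
  par <- energy_params()
  pa <- build_polyamine("SPD")
  set.seed(11)
  for (i in 1:10) {
    ref <- c(runif(1, -2, 2), runif(1, -2, 2), runif(1, 0, 3.4))
    ax <- rnorm(3)
    e1 <- total_energy(pa, dna, cell, par, ref, ax)
    # reflect through the xz-plane (contains the DNA axis and both rails)
    e2 <- total_energy(pa, dna, cell, par, ref * c(1, -1, 1), ax * c(1, -1, 1))
    expect_equal(e1, e2, tolerance = 1e-12)
  }
})

test_that("identical seeds give bit-identical trajectories", {
  pa <- build_polyamine("NSPD")
  dna <- build_dna()
  cell <- build_cell()
  t1 <- run_mc(pa, dna, cell, energy_params(), n_equil = 5e3, n_prod = 2e4,
               stride = 10, seed = 123)
  t2 <- run_mc(pa, dna, cell, energy_params(), n_equil = 5e3, n_prod = 2e4,
               stride = 10, seed = 123)
  expect_identical(t1$samples, t2$samples)
  expect_identical(t1$bound, t2$bound)
  t3 <- run_mc(pa, dna, cell, energy_params(), n_equil = 5e3, n_prod = 2e4,
               stride = 10, seed = 124)
  expect_false(identical(t1$samples, t3$samples))
})

test_that("recorded energies equal a fresh recomputation on stored states", {
  pa <- build_polyamine("SPD")
  dna <- build_dna()
  cell <- build_cell()
  tr <- run_mc(pa, dna, cell, energy_params(), n_equil = 1e4, n_prod = 5e4,
               stride = 25, seed = 5)
  expect_equal(recompute_energies(tr), unname(tr$samples[, "energy"]),
               tolerance = 1e-9)
})

test_that("with no interactions the sampled density is ideal (rho ~ r, flat mu)", {
  # small free rod so every orientation fits at the radii probed
  ms <- generate_micro_system(micro_spec())
  par0 <- energy_params(gamma = 0, soft_k = 0, hard_core = FALSE)
  tr <- run_mc(ms$polyamine, ms$dna, ms$cell, par0, n_equil = 2e4,
               n_prod = 1e6, stride = 10, seed = 31)
  # radial CDF of the tracked bead conditional on r < R_cyl - rod length:
  # for an ideal annulus P(r < x) = (x/R)^2
  Rin <- ms$cell$R_cyl - ms$polyamine$length
  rr <- tr$r5[tr$r5 < Rin]
  u <- (rr / Rin)^2
  expect_equal(mean(u), 0.5, tolerance = 0.02)
  expect_equal(stats::quantile(u, 0.25, names = FALSE), 0.25, tolerance = 0.03)
  # orientation cosine flat: mean 0, uniform quartiles
  expect_equal(mean(tr$mu), 0, tolerance = 0.03)
  expect_equal(stats::quantile(tr$mu, 0.75, names = FALSE), 0.5,
               tolerance = 0.05)
})

test_that("geometrically impossible systems are rejected", {
  pa <- build_polyamine("SPD")
  dna <- build_dna()
  # rod longer than every cell extent
  expect_error(run_mc(pa, dna, build_cell(R_cyl = 1.2, H = 1.0),
                      energy_params(), n_equil = 10, n_prod = 10, seed = 1),
               "fit")
})
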