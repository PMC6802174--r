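# DNA stand-in with hand-placed phosphates so exact N-P distances can be
# dialled in; the rod lies along z starting at the origin.
synthetic_dna <- function(positions, H = 100) {
  dna <- build_dna()
  dna$positions <- positions
  dna
}

test_that("binding requires all three ammoniums simultaneously in contact", {
  pa <- build_polyamine("SPD")       # ammoniums at z = 0, 1.56, 3.51
  cell <- build_cell(R_cyl = 10, H = 100)
  place <- function(d1, d2, d3)      # one phosphate at distance di from each
    synthetic_dna(rbind(c(d1, 0, 0), c(d2, 0, 1.56), c(d3, 0, 3.51)))
  ref <- c(0, 0, 0); ax <- c(0, 0, 1)
  expect_true(is_bound(pa, place(0.40, 0.42, 0.45), cell, ref, ax, 0.453))
  expect_false(is_bound(pa, place(0.40, 0.42, 0.46), cell, ref, ax, 0.453))
  # far from every phosphate (cell-wall scale distances)
  expect_false(is_bound(pa, place(0.40, 0.42, 0.45), cell,
                        c(5, 0, 0), ax, 0.453))
})

test_that("phase volumes match the closed-form quadrature", {
  cell <- build_cell(R_cyl = 2.591, H = 3.4)
  dna <- build_dna()
  pv <- phase_volumes(cell, dna, binding_params(), literal_eq4 = TRUE)
  # radial factor 2*pi*H int_{R_DNA - sigma/2}^{R_cut} r dr
  radial <- pi * 3.4 * (1.3^2 - (1.0 - 0.476 / 2)^2)
  expect_equal(pv$radial_inner, radial, tolerance = 1e-12)
  expect_equal(pv$V_b, radial * 2 * pi, tolerance = 1e-12)
  # the two mu-slabs have equal measure, so the inner free term equals V_b
  expect_equal(pv$V_f - pv$outer_term, pv$V_b, tolerance = 1e-12)
  # literal outer term: 4*pi*H int_{R_cut}^{R_cyl} r dr
  expect_equal(pv$outer_term, 2 * pi * 3.4 * (2.591^2 - 1.3^2),
               tolerance = 1e-12)
  # dimensionally consistent variant carries the full orientation measure
  pv2 <- phase_volumes(cell, dna, binding_params(), literal_eq4 = FALSE)
  expect_equal(pv2$outer_term, pi * 3.4 * (2.591^2 - 1.3^2) * 4 * pi,
               tolerance = 1e-12)
  expect_error(phase_volumes(build_cell(R_cyl = 1.2), dna), "R_cut")
})

test_that("binding constant collapses to closed forms on degenerate inputs", {
  dna <- build_dna()
  # nearly closed cell: outer free volume ~ 0, so V_b = V_f
  cell <- build_cell(R_cyl = 1.3 + 1e-9, H = 3.4)
  mk_traj <- function(bound) structure(list(
    bound = bound, r5 = rep(1, length(bound)), dna = dna, cell = cell,
    polyamine = build_polyamine("SPD")), class = "pa_trajectory")

  conc <- 20 / (pi * cell$R_cyl^2 * cell$H) * 1e3 / (6.02214076e23 * 1e-24)
  half <- mk_traj(rep(c(TRUE, FALSE), 500))
  bk <- binding_K(half)
  expect_equal(bk$N_binding + bk$N_nonbinding, 1)
  expect_equal(bk$K, 1 / conc, tolerance = 1e-6)

  expect_equal(binding_K(mk_traj(rep(FALSE, 100)))$K, 0)
  expect_true(is.na(binding_K(mk_traj(rep(TRUE, 100)))$K))
})

test_that("phase volumes are a pure function of the geometry", {
  cell <- build_cell()
  dna <- build_dna()
  pv1 <- phase_volumes(cell, dna)
  pv2 <- phase_volumes(cell, dna)
  expect_identical(pv1, pv2)
  # unchanged by anything trajectory-like; only geometry arguments exist
  expect_equal(phase_volumes(build_cell(R_cyl = 5.182), dna)$V_b, pv1$V_b)
})

test_that("K estimates from disjoint trajectory halves agree within error", {
  runs <- production_runs()
  for (key in c("SPD1", "NSPD1")) {
    tr <- runs[[key]]
    n <- length(tr$bound)
    h1 <- tr; h1$bound <- tr$bound[1:(n / 2)]; h1$r5 <- tr$r5[1:(n / 2)]
    h2 <- tr; h2$bound <- tr$bound[(n / 2 + 1):n]; h2$r5 <- tr$r5[(n / 2 + 1):n]
    k1 <- binding_K(h1)
    k2 <- binding_K(h2)
    se <- sqrt(k1$K_se^2 + k2$K_se^2)
    expect_lt(abs(k1$K - k2$K), 3 * se)
  }
})

test_that("without electrostatics binding events are at contact-shell scale", {
  pa <- build_polyamine("SPD")
  dna <- build_dna()
  cell <- build_cell()
  tr <- run_mc(pa, dna, cell, energy_params(gamma = 0), n_equil = 2e4,
               n_prod = 5e5, stride = 10, seed = 17)
  expect_lt(binding_K(tr)$N_binding, 1e-3)
})

test_that("the coupling sweep returns one measured row per combination", {
  sw <- gamma_sweep(species = "NSPD", gamma_grid = c(0.5, 1.36),
                    R_cyl_list = 2.591, seeds = 1, n_equil = 1e4,
                    n_prod = 1e5, stride = 10)
  expect_equal(nrow(sw), 2L)
  expect_true(all(c("species", "gamma", "R_cyl", "K", "K_se") %in% names(sw)))
  expect_true(all(sw$K >= 0))
  expect_gt(sw$K[sw$gamma == 1.36], sw$K[sw$gamma == 0.5])
})
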