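# minimal trajectory-like object for histogram tests
fake_traj <- function(r5, mu) structure(list(r5 = r5, mu = mu),
                                        class = "pa_trajectory")

test_that("density accumulation is a hand-checkable Jacobian histogram", {
  cell <- build_cell(R_cyl = 2, H = 1)
  tr <- fake_traj(r5 = c(0.5, 0.7, 1.5), mu = c(-0.5, -0.2, 0.3))
  g <- accumulate_rho5(tr, r_edges = c(0, 1, 2), mu_edges = c(-1, 0, 1), cell)
  expect_equal(g$counts, matrix(c(2, 0, 0, 1), 2, 2))
  # normalization invariant: sum(rho * measure) = 1
  expect_equal(sum(g$rho5 * g$measure), 1, tolerance = 1e-12)
  # measure of bin (r in (0,1), mu width 1, H = 1) is pi * 1
  expect_equal(g$measure[1, 1], pi)
  expect_equal(g$rho5[1, 1], 2 / (3 * pi))

  # doubling the bin widths preserves the normalization invariant
  g2 <- accumulate_rho5(tr, r_edges = c(0, 2), mu_edges = c(-1, 1), cell)
  expect_equal(sum(g2$rho5 * g2$measure), 1, tolerance = 1e-12)

  expect_error(accumulate_rho5(fake_traj(numeric(0), numeric(0)),
                               c(0, 1), c(-1, 1), cell), "empty")
  expect_error(accumulate_rho5(tr, c(1, 0), c(-1, 1), cell))
})

test_that("free energy is -log density with undefined empty bins", {
  cell <- build_cell(R_cyl = 2, H = 1)
  g <- accumulate_rho5(fake_traj(c(0.5, 0.7, 1.5), c(-0.5, -0.2, 0.3)),
                       c(0, 1, 2), c(-1, 0, 1), cell)
  # planted densities: rho = 1 -> F = 0; rho = e^-2 -> F = 2
  g$rho5 <- matrix(c(1, exp(-2), 1, 1), 2, 2)
  g$counts <- matrix(c(5, 5, 5, 0), 2, 2)
  g <- free_energy(g)
  expect_equal(g$F[1, 1], 0)
  expect_equal(g$F[2, 1], 2)
  expect_true(is.nan(g$F[2, 2]))  # empty bin undefined, never zero
  # minimum of F coincides with the maximum of rho5 (monotone transform)
  gm <- accumulate_rho5(fake_traj(runif(500, 0, 2), runif(500, -1, 1)),
                        seq(0, 2, 0.5), seq(-1, 1, 0.5), cell)
  expect_equal(which.min(gm$F), which.max(gm$rho5))
})

test_that("landscape differences subtract bin-wise with sign symmetry", {
  cell <- build_cell(R_cyl = 2, H = 1)
  mk <- function(r5, mu) accumulate_rho5(fake_traj(r5, mu),
                                         seq(0, 2, 1), c(-1, 0, 1), cell)
  set.seed(3)
  a <- mk(runif(200, 0, 2), runif(200, -1, 1))
  b <- mk(runif(200, 0, 2), runif(200, -1, 1))
  d0 <- delta_F(a, a)
  expect_equal(d0$F, matrix(0, 2, 2))
  dab <- delta_F(a, b)
  dba <- delta_F(b, a)
  expect_equal(dab$F, -dba$F)
  bad <- mk(runif(200, 0, 2), runif(200, -1, 1))
  bad$r_edges <- c(0, 0.5, 1)
  expect_error(delta_F(a, bad), "mismatch")
})

test_that("minimum location honours the radial restriction and tie-breaks", {
  cell <- build_cell(R_cyl = 2, H = 1)
  g <- accumulate_rho5(fake_traj(c(0.25), c(0.5)), c(0, 0.5), c(0, 1), cell)
  m <- locate_minimum(g, r_max = 1)
  expect_equal(m$r, 0.25)

  # planted Gaussian well: sample (r, mu) around a known centre
  set.seed(9)
  n <- 2e4
  r <- pmin(pmax(rnorm(n, 0.9, 0.1), 0.01), 1.99)
  mu <- pmin(pmax(rnorm(n, 0.6, 0.1), -0.999), 0.999)
  gw <- accumulate_rho5(fake_traj(r, mu), seq(0, 2, 0.1), seq(-1, 1, 0.1),
                        cell)
  m <- locate_minimum(gw, r_max = 1.5)
  expect_lt(abs(m$r - 0.85), 0.11)   # within one bin of the density peak
  expect_lt(abs(m$mu - 0.55), 0.11)

  # ties break to smaller r then smaller |mu|
  gt <- gw
  gt$F[] <- 1
  gt$F[3, 4] <- 0
  gt$F[5, 4] <- 0
  gt$F[3, 12] <- 0  # same r as [3,4]; mu centre +0.15 vs -0.65
  m <- locate_minimum(gt, r_max = 2)
  expect_equal(m$r, gt$r_centers[3])
  expect_equal(m$mu, gt$mu_centers[12])
  expect_error(locate_minimum(delta_F(gw, gw), r_max = 0.04))
})

test_that("landscape CSV export round-trips the bin table", {
  cell <- build_cell(R_cyl = 2, H = 1)
  g <- accumulate_rho5(fake_traj(runif(100, 0, 2), runif(100, -1, 1)),
                       seq(0, 2, 0.5), seq(-1, 1, 0.5), cell)
  f <- tempfile(fileext = ".csv")
  write_landscape(g, f)
  df <- read.csv(f)
  expect_equal(nrow(df), length(g$r_centers) * length(g$mu_centers))
  expect_equal(matrix(df$rho5, nrow = 4), g$rho5, ignore_attr = TRUE)
  meta <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(meta$n_samples, 100)
})
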