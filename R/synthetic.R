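#' Specification for a synthetic NMR titration series
#'
#' The generator emulates the structure of a proton-NMR titration of a fixed
#' polyamine concentration against increasing DNA: the inverse relative
#' intensity rises linearly with DNA concentration, with a steeper slope
#' `K2` below the regime boundary and slope `K1` above it. Noise is additive
#' Gaussian on the intensity (integration noise in NMR is additive on signal
#' area), with standard deviation `noise_sd * I0`.
#'
#' Default slopes are the low-regime value 0.36 mM^-1 and high-regime value
#' 0.18 mM^-1 with the boundary at 0.5 mM; the default concentration grid
#' 0, 0.1, ..., 1.6 mM spans both regimes.
#'
#' @param K2 Low-concentration slope, mM^-1.
#' @param K1 High-concentration slope, mM^-1.
#' @param breakpoint Regime boundary, mM.
#' @param I0 Zero-DNA intensity, arbitrary units.
#' @param conc_grid DNA concentrations, mM.
#' @param noise_sd Noise standard deviation as a fraction of `I0`.
#' @param polyamine_conc Fixed polyamine concentration, mM (metadata; 0.1).
#' @param seed Integer seed.
#' @return An object of class `titration_spec`.
#' @export
titration_spec <- function(K2 = 0.36, K1 = 0.18, breakpoint = 0.5, I0 = 100,
                           conc_grid = seq(0, 1.6, by = 0.1),
                           noise_sd = 0.02, polyamine_conc = 0.1, seed = 1L) {
  stopifnot(K2 >= 0, K1 >= 0, breakpoint > 0, I0 > 0, noise_sd >= 0)
  structure(list(K2 = K2, K1 = K1, breakpoint = breakpoint, I0 = I0,
                 conc_grid = sort(unique(conc_grid)), noise_sd = noise_sd,
                 polyamine_conc = polyamine_conc, seed = as.integer(seed)),
            class = "titration_spec")
}

#' Generate a synthetic titration dataset
#'
#' Noiseless intensities follow `I(c) = I0 / (1 + s(c))` with the continuous
#' piecewise-linear accumulated slope
#' `s(c) = K2 * min(c, breakpoint) + K1 * max(0, c - breakpoint)`; additive
#' Gaussian noise `noise_sd * I0` is then applied (floored at a tiny positive
#' value so intensities stay positive). Deterministic under a fixed seed.
#'
#' @param spec A [titration_spec()].
#' @return data.frame with columns `conc` (mM) and `intensity` (a.u.),
#'   carrying the spec as attribute `"spec"`.
#' @examples
#' d <- generate_titration(titration_spec(noise_sd = 0))
#' head(d)
#' @export
generate_titration <- function(spec = titration_spec()) {
  stopifnot(inherits(spec, "titration_spec"))
  cg <- spec$conc_grid
  if (!any(cg < spec$breakpoint) || !any(cg > spec$breakpoint))
    stop("concentration grid must have points below and above the breakpoint")
  s <- spec$K2 * pmin(cg, spec$breakpoint) +
    spec$K1 * pmax(cg - spec$breakpoint, 0)
  I <- spec$I0 / (1 + s)
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    I <- I + stats::rnorm(length(I), 0, spec$noise_sd * spec$I0)
    I <- pmax(I, 1e-6 * spec$I0)
  }
  structure(data.frame(conc = cg, intensity = I), spec = spec)
}

#' Specification for a reduced quadrature micro-system
#'
#' A system small enough that the polyamine's rigid-body configuration space
#' can be enumerated on a dense grid and Boltzmann-integrated directly — the
#' brute-force oracle against which the Metropolis sampler is checked. The
#' default is a 3-bead rod (all beads charged +1) around 2 phosphate pairs in
#' a short periodic cell.
#'
#' @param n_beads Beads in the rod.
#' @param charged_indices Charged bead indices (default all).
#' @param n_pairs Phosphate pairs.
#' @param d Bead diameter, nm.
#' @param R_cyl Cell radius, nm.
#' @param res Named integer vector of grid resolutions for the five
#'   configuration coordinates: radial `r`, positional azimuth `phi`, axial
#'   `z`, orientation cosine `mu`, orientation azimuth `phiu`.
#' @param phosphate_charge Charge on the phosphate spheres (default -1;
#'   +1 gives an all-repulsive system whose smooth Boltzmann factor lets the
#'   midpoint quadrature converge quickly, the preferred oracle setting).
#' @param state_cap Maximum number of grid states (guards runaway grids).
#' @return An object of class `micro_spec`.
#' @export
micro_spec <- function(n_beads = 3L, charged_indices = seq_len(n_beads),
                       n_pairs = 2L, d = 0.39, R_cyl = 2.0,
                       res = c(r = 14L, phi = 10L, z = 6L, mu = 11L,
                               phiu = 10L),
                       phosphate_charge = -1, state_cap = 2e6) {
  stopifnot(n_beads >= 1, n_pairs >= 1,
            all(c("r", "phi", "z", "mu", "phiu") %in% names(res)))
  if (prod(res) > state_cap)
    stop("grid of ", prod(res), " states exceeds the cap of ", state_cap)
  structure(list(n_beads = as.integer(n_beads),
                 charged_indices = as.integer(charged_indices),
                 n_pairs = as.integer(n_pairs), d = d, R_cyl = R_cyl,
                 res = res, phosphate_charge = phosphate_charge,
                 state_cap = state_cap),
            class = "micro_spec")
}

#' Generate the micro-system and its Boltzmann quadrature states
#'
#' Builds the reduced rod/DNA/cell models and enumerates the discretised
#' rigid-body configuration space (position in cylindrical coordinates,
#' orientation as cosine + azimuth, midpoint rule in every coordinate). Each
#' state carries the Boltzmann weight `exp(-E) * dV` with `E` from
#' [total_energy_batch()] and `dV = rho drho dphi dz dmu dphiu` the
#' phase-space element; weights are returned both raw and normalised.
#'
#' @param spec A [micro_spec()].
#' @param params An `energy_params`.
#' @return List with `polyamine`, `dna`, `cell`, `params` and `states`
#'   (data.frame: ref/axis coordinates, `energy`, `dV`, `weight`, `prob`,
#'   plus the tracked central-bead radius `r_track` and orientation cosine
#'   `mu`), and `partition` (the finite partition value `sum(weight)`).
#' @export
generate_micro_system <- function(spec = micro_spec(),
                                  params = energy_params()) {
  stopifnot(inherits(spec, "micro_spec"))
  pa <- structure(list(
    species = "MICRO", n_beads = spec$n_beads, d = spec$d,
    charged_indices = spec$charged_indices,
    charges = as.numeric(seq_len(spec$n_beads) %in% spec$charged_indices),
    offsets = (seq_len(spec$n_beads) - 1) * spec$d,
    length = (spec$n_beads - 1) * spec$d
  ), class = "polyamine_model")
  dna <- build_dna(n_pairs = spec$n_pairs)
  dna$charge <- spec$phosphate_charge
  cell <- build_cell(R_cyl = spec$R_cyl, H = dna$H)

  mid <- function(n, lo, hi) lo + (seq_len(n) - 0.5) * (hi - lo) / n
  rs <- mid(spec$res["r"], 0, cell$R_cyl)
  phis <- mid(spec$res["phi"], 0, 2 * pi)
  zs <- mid(spec$res["z"], 0, cell$H)
  mus <- mid(spec$res["mu"], -1, 1)
  phius <- mid(spec$res["phiu"], 0, 2 * pi)
  g <- expand.grid(r = rs, phi = phis, z = zs, mu = mus, phiu = phius,
                   KEEP.OUT.ATTRS = FALSE)
  refs <- cbind(g$r * cos(g$phi), g$r * sin(g$phi), g$z)
  smu <- sqrt(pmax(1 - g$mu^2, 0))
  axes <- cbind(smu * cos(g$phiu), smu * sin(g$phiu), g$mu)

  E <- total_energy_batch(pa, dna, cell, params, refs, axes)
  dV <- g$r * (cell$R_cyl / spec$res["r"]) * (2 * pi / spec$res["phi"]) *
    (cell$H / spec$res["z"]) * (2 / spec$res["mu"]) *
    (2 * pi / spec$res["phiu"])
  w <- ifelse(is.finite(E), exp(-E) * dV, 0)

  # tracked bead: the middle charged bead (central ammonium analogue)
  imid <- spec$charged_indices[ceiling(length(spec$charged_indices) / 2)]
  off <- pa$offsets[imid]
  r_track <- sqrt((refs[, 1] + off * axes[, 1])^2 +
                  (refs[, 2] + off * axes[, 2])^2)

  states <- data.frame(x = refs[, 1], y = refs[, 2], z = refs[, 3],
                       ux = axes[, 1], uy = axes[, 2], uz = axes[, 3],
                       energy = E, dV = dV, weight = w, prob = w / sum(w),
                       r_track = r_track, mu = g$mu)
  list(polyamine = pa, dna = dna, cell = cell, params = params,
       states = states, partition = sum(w))
}

#' High-resolution streaming quadrature marginal
#'
#' Same Boltzmann integral as [quadrature_marginal()], but computed in
#' compiled code over an independent (usually much finer) midpoint grid
#' without materializing the states, so resolutions of 1e7+ states complete
#' in seconds. Used to verify quadrature convergence and as the oracle side
#' of sampler-correctness checks.
#'
#' @param ms Result of [generate_micro_system()] (models and parameters are
#'   taken from it; its own state table is ignored).
#' @param res Named integer vector (`r`, `phi`, `z`, `mu`, `phiu`) of grid
#'   resolutions.
#' @param r_edges,mu_edges Bin edges of the output marginal.
#' @return Matrix of bin probabilities (rows: r bins, cols: mu bins).
#' @export
fine_quadrature_marginal <- function(ms, res, r_edges, mu_edges) {
  stopifnot(all(c("r", "phi", "z", "mu", "phiu") %in% names(res)))
  pa <- ms$polyamine
  par <- cpp_par(ms$params, ms$dna, ms$cell)
  par$contact <- (pa$d + ms$dna$sigma) / 2
  imid <- pa$charged_indices[ceiling(length(pa$charged_indices) / 2)]
  out <- cg_quad_marginal(pa$offsets, pa$charges, ms$dna$positions,
                          ms$dna$charge, par,
                          as.integer(res[c("r", "phi", "z", "mu", "phiu")]),
                          pa$offsets[imid], r_edges, mu_edges)
  out$bins / sum(out$bins)
}

#' Quadrature marginal over the landscape coordinates
#'
#' Bins the micro-system's quadrature states over `(r_track, mu)` with the
#' Boltzmann probabilities — the exact (up to grid resolution) counterpart of
#' the Monte Carlo `(r5, mu)` histogram.
#'
#' @param ms Result of [generate_micro_system()].
#' @param r_edges,mu_edges Bin edges.
#' @return Matrix of bin probabilities (rows: r bins, cols: mu bins).
#' @export
quadrature_marginal <- function(ms, r_edges, mu_edges) {
  st <- ms$states
  ir <- findInterval(st$r_track, r_edges, rightmost.closed = TRUE)
  imu <- findInterval(st$mu, mu_edges, rightmost.closed = TRUE)
  nr <- length(r_edges) - 1L
  nmu <- length(mu_edges) - 1L
  keep <- ir >= 1 & ir <= nr & imu >= 1 & imu <= nmu
  m <- matrix(0, nr, nmu)
  lin <- (imu[keep] - 1L) * nr + ir[keep]
  acc <- tapply(st$prob[keep], lin, sum)
  m[as.integer(names(acc))] <- acc
  m / sum(m)
}
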