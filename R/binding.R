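#' Binding-detection and phase-volume parameters
#'
#' @param bind_cutoff Ammonium-N to phosphate-P centre distance below which a
#'   contact counts as bound, nm. Default 0.453 nm — the hydrogen-bond
#'   geometry at a 105-degree angle, taken as the maximum length that still
#'   allows binding.
#' @param R_cut Radial boundary separating the strong-binding region from
#'   the weak/free region in the phase-volume bookkeeping, nm (default 1.3).
#' @param mu_split Orientation-cosine split between the aligned (bound-like)
#'   and perpendicular orientation slabs (default 0.5).
#' @return An object of class `binding_params`.
#' @export
binding_params <- function(bind_cutoff = 0.453, R_cut = 1.3, mu_split = 0.5) {
  stopifnot(bind_cutoff > 0, R_cut > 0, mu_split > 0, mu_split < 1)
  structure(list(bind_cutoff = bind_cutoff, R_cut = R_cut,
                 mu_split = mu_split), class = "binding_params")
}

#' Is a configuration bound?
#'
#' TRUE iff every charged bead (all three ammoniums simultaneously) is within
#' `cutoff` (centre-to-centre, minimum image along the periodic axis) of at
#' least one phosphate sphere.
#'
#' @param polyamine A `polyamine_model`.
#' @param dna A `dna_model`.
#' @param cell A `simulation_cell`.
#' @param ref,axis The configuration (bead-1 position and rod axis).
#' @param cutoff Contact cutoff, nm.
#' @return Logical scalar.
#' @export
is_bound <- function(polyamine, dna, cell, ref, axis, cutoff = 0.453) {
  u <- axis / sqrt(sum(axis^2))
  par <- list(gamma = 0, debye_length = Inf, soft_k = 0, hard_core = FALSE,
              contact = 0, R_DNA = dna$R_DNA, H = cell$H, R_cyl = Inf)
  cg_bound_batch(polyamine$offsets, polyamine$charges, dna$positions,
                 dna$charge, par, cutoff,
                 matrix(as.numeric(ref), 1), matrix(u, 1))[1]
}

#' Bound and free phase-space volumes
#'
#' Position-orientation volumes assigned to the bound and free states. The
#' bound volume covers the radial annulus from the phosphate inner surface
#' `R_DNA - sigma/2` out to `R_cut`, restricted to aligned orientations
#' (`|mu|` in `[mu_split, 1]`, both signs, all azimuths):
#' \deqn{V_b = [2\pi H \int r\,dr] \cdot [2 \int_{0.5}^{1} d\mu
#'   \int_0^{2\pi} d\varphi]}
#' The free volume is the same annulus over the perpendicular orientations
#' plus an outer term over `(R_cut, R_cyl)`. As printed, the outer term is
#' `4*pi*H*int r dr`, which carries no orientation measure; with
#' `literal_eq4 = FALSE` the dimensionally consistent variant
#' `[2*pi*H*int r dr] * [4*pi]` (full orientation sphere times 2 azimuthal
#' turns) is used instead. Ratios of binding constants between species are
#' invariant to this choice since the volumes cancel.
#'
#' @param cell A `simulation_cell`.
#' @param dna A `dna_model`.
#' @param params A `binding_params`.
#' @param literal_eq4 Use the printed outer free-volume term (default TRUE).
#' @return List with `V_b`, `V_f` (nm^3 times orientation measure) and the
#'   pieces `radial_inner`, `outer_term`.
#' @export
phase_volumes <- function(cell, dna, params = binding_params(),
                          literal_eq4 = TRUE) {
  r_in <- dna$R_DNA - dna$sigma / 2
  if (!(r_in < params$R_cut && params$R_cut < cell$R_cyl))
    stop("need R_DNA - sigma/2 < R_cut < R_cyl")
  H <- cell$H
  radial_inner <- pi * H * (params$R_cut^2 - r_in^2)   # 2*pi*H*int r dr
  mu_hi <- 2 * (1 - params$mu_split) * 2 * pi          # 2*int_{s}^{1} dmu * int dphi
  mu_lo <- 2 * params$mu_split * 2 * pi
  V_b <- radial_inner * mu_hi
  outer_term <- if (literal_eq4) {
    2 * pi * H * (cell$R_cyl^2 - params$R_cut^2)       # printed 4*pi*H*int r dr
  } else {
    pi * H * (cell$R_cyl^2 - params$R_cut^2) * 4 * pi
  }
  V_f <- radial_inner * mu_lo + outer_term
  list(V_b = V_b, V_f = V_f, radial_inner = radial_inner,
       outer_term = outer_term)
}

# 1 particle/nm^3 = 1/(N_A * 1e-24 L) mol/L = 1.66054 M = 1660.54 mM
NM3_TO_MM <- 1e3 / (6.02214076e23 * 1e-24)

#' Binding constant from a trajectory
#'
#' The bound fraction `N(binding)` is the fraction of samples in which all
#' three ammoniums simultaneously contact phosphates;
#' `N(binding) + N(nonbinding) = 1` (unbound samples inside `R_cut` count as
#' nonbinding). The bound/free concentration ratio is
#' `(N_b / V_b) / (N_f / V_f)` and the binding constant
#' \deqn{K = \frac{[PA\!-\!P]/[PA]}{[Phosphate]}}
#' with the free-phosphate concentration approximated by the total phosphate
#' concentration in the cell, `2 n_pairs / (pi R_cyl^2 H)` converted to mM
#' (1 nm^-3 = 1660.54 mM). The Monte Carlo standard error is estimated by
#' block averaging over `n_blocks` contiguous blocks.
#'
#' @param traj A `pa_trajectory` (bound flags recorded at the trajectory's
#'   `bind_cutoff`).
#' @param params A `binding_params`.
#' @param literal_eq4 Passed to [phase_volumes()].
#' @param n_blocks Blocks for the standard-error estimate (default 10).
#' @param condition_on_Rcut Also require the central ammonium inside `R_cut`
#'   for a sample to count as bound (default FALSE: the distance criterion
#'   alone defines binding).
#' @return An object of class `binding_result`: `N_binding`, `N_nonbinding`,
#'   `V_b`, `V_f`, `phosphate_mM`, `K` (mM^-1), `K_se`, `n_samples`,
#'   `species`. `K` is `NA` (unmeasurable) if no free samples exist, 0 if no
#'   bound samples.
#' @export
binding_K <- function(traj, params = binding_params(), literal_eq4 = TRUE,
                      n_blocks = 10L, condition_on_Rcut = FALSE) {
  stopifnot(inherits(traj, "pa_trajectory"))
  b <- traj$bound
  if (condition_on_Rcut) b <- b & traj$r5 < params$R_cut
  vol <- phase_volumes(traj$cell, traj$dna, params, literal_eq4)
  conc <- 2 * traj$dna$n_pairs / (pi * traj$cell$R_cyl^2 * traj$cell$H) *
    NM3_TO_MM
  k_of <- function(bb) {
    nb <- mean(bb)
    if (nb == 0) return(0)
    if (nb == 1) return(NA_real_)
    ((nb / vol$V_b) / ((1 - nb) / vol$V_f)) / conc
  }
  K <- k_of(b)
  blocks <- split(b, cut(seq_along(b), n_blocks, labels = FALSE))
  Kb <- vapply(blocks, k_of, numeric(1))
  K_se <- if (all(is.finite(Kb))) stats::sd(Kb) / sqrt(n_blocks) else NA_real_
  structure(list(
    N_binding = mean(b), N_nonbinding = 1 - mean(b),
    V_b = vol$V_b, V_f = vol$V_f, phosphate_mM = conc,
    K = K, K_se = K_se, n_samples = length(b),
    species = traj$polyamine$species
  ), class = "binding_result")
}

#' @export
print.binding_result <- function(x, ...) {
  cat(sprintf(
    "<binding_result> %s: N(binding) = %.4g, K = %.4g mM^-1 (se %.2g)\n",
    x$species, x$N_binding, x$K, x$K_se))
  invisible(x)
}

#' Sweep the binding constant over the electrostatic coupling
#'
#' Runs the full simulate-and-measure pipeline for each combination of
#' species, coupling strength and cell radius, one seed per combination
#' (recycled from `seeds`).
#'
#' @param species Character vector of species labels.
#' @param gamma_grid Numeric vector of coupling strengths, kBT nm.
#' @param R_cyl_list Numeric vector of cell radii, nm.
#' @param seeds Integer seeds, recycled across combinations.
#' @param params An `energy_params` template (its `gamma` is overridden).
#' @param bparams A `binding_params`.
#' @param ... Passed to [run_mc()] (e.g. `n_prod`).
#' @return A data.frame with one row per combination: species, gamma, R_cyl,
#'   seed, N_binding, K, K_se.
#' @export
gamma_sweep <- function(species = c("SPD", "NSPD"),
                        gamma_grid = c(0.34, 0.68, 1.02, 1.36),
                        R_cyl_list = 2.591, seeds = 1L,
                        params = energy_params(), bparams = binding_params(),
                        ...) {
  stopifnot(length(species) > 0, length(gamma_grid) > 0, length(R_cyl_list) > 0)
  grid <- expand.grid(species = species, gamma = gamma_grid,
                      R_cyl = R_cyl_list, stringsAsFactors = FALSE)
  grid$seed <- rep_len(as.integer(seeds), nrow(grid))
  res <- lapply(seq_len(nrow(grid)), function(i) {
    pa <- build_polyamine(grid$species[i])
    dna <- build_dna()
    cell <- build_cell(R_cyl = grid$R_cyl[i], H = dna$H)
    p <- params
    p$gamma <- grid$gamma[i]
    traj <- run_mc(pa, dna, cell, p, seed = grid$seed[i],
                   bind_cutoff = bparams$bind_cutoff, ...)
    binding_K(traj, bparams)
  })
  grid$N_binding <- vapply(res, `[[`, numeric(1), "N_binding")
  grid$K <- vapply(res, `[[`, numeric(1), "K")
  grid$K_se <- vapply(res, `[[`, numeric(1), "K_se")
  grid
}
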