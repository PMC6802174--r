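#' Energy-model parameters
#'
#' The electrostatics are a screened Coulomb (Debye-Hueckel) interaction
#' between unit charges, reduced by kBT at T = 298 K:
#' \deqn{u_{ij}/k_BT = \Gamma z_i z_j e^{-r/\lambda_D} / r}
#' where \eqn{\Gamma} is a coupling length (kBT nm per unit-charge pair) and
#' \eqn{\lambda_D} the Debye screening length. The soft DNA boundary is a
#' half-harmonic radial penalty \eqn{\frac{1}{2} k (R_{DNA} - \rho)^2} applied
#' to every bead whose axial radius \eqn{\rho} is below `R_DNA` — penetration
#' into the groove-bearing DNA envelope is allowed but penalised. Bead to
#' phosphate hard cores (contact at `(d + sigma)/2`) reject overlapping
#' configurations.
#'
#' @param gamma Coupling length Gamma, kBT nm (default 1.36).
#' @param debye_length Debye screening length, nm; `Inf` for the unscreened
#'   Coulomb form. Default 3.04 nm (a 10 mM 1:1 buffer at 298 K).
#' @param soft_k Radial boundary stiffness, kBT/nm^2 (default 10).
#' @param hard_core Logical; enforce bead-phosphate contact exclusion.
#' @return An object of class `energy_params`.
#' @export
energy_params <- function(gamma = 1.36, debye_length = 3.04, soft_k = 10,
                          hard_core = TRUE) {
  stopifnot(gamma >= 0, debye_length > 0, soft_k >= 0)
  structure(list(gamma = gamma, debye_length = debye_length,
                 soft_k = soft_k, hard_core = isTRUE(hard_core)),
            class = "energy_params")
}

#' Screened Coulomb pair energy
#'
#' Energy of one charge pair at separation `r`:
#' `gamma * z_i * z_j * exp(-r / debye_length) / r`, in kBT. With
#' `debye_length = Inf` this is the bare Coulomb form, equal to
#' `gamma * z_i * z_j` at r = 1 nm.
#'
#' @param r Separation, nm (> 0).
#' @param z_i,z_j Charges in unit-charge units.
#' @param params An `energy_params` object.
#' @return Energy in kBT (vectorised over `r`).
#' @examples
#' pair_energy(1, 1, -1, energy_params(gamma = 1.36, debye_length = Inf))
#' @export
pair_energy <- function(r, z_i, z_j, params = energy_params()) {
  if (any(r <= 0))
    stop("pair separation must be positive (hard-core overlap?)")
  screen <- if (is.finite(params$debye_length)) exp(-r / params$debye_length) else 1
  params$gamma * z_i * z_j * screen / r
}

# flat-list form consumed by the C++ kernels
cpp_par <- function(params, dna, cell) {
  list(gamma = params$gamma, debye_length = params$debye_length,
       soft_k = params$soft_k, hard_core = params$hard_core,
       contact = 0, R_DNA = dna$R_DNA, H = cell$H, R_cyl = cell$R_cyl)
}

#' Total energy of a polyamine configuration
#'
#' Sum of the screened Coulomb energy over every (charged bead, phosphate)
#' pair — using the minimum-image convention along the periodic axis — plus
#' the soft-boundary penalty for each bead that penetrates below `R_DNA`.
#' Returns `Inf` for rejected states: a bead outside the radial wall at
#' `R_cyl`, or (with `hard_core`) a bead-phosphate centre distance below the
#' contact distance `(d + sigma)/2`.
#'
#' @param polyamine A `polyamine_model`.
#' @param dna A `dna_model`.
#' @param cell A `simulation_cell`.
#' @param params An `energy_params`.
#' @param ref Position of bead 1, nm (length-3).
#' @param axis Rod axis (normalised internally).
#' @return Energy in kBT (scalar; `Inf` for rejected states).
#' @export
total_energy <- function(polyamine, dna, cell, params, ref, axis) {
  stopifnot(inherits(polyamine, "polyamine_model"), inherits(dna, "dna_model"),
            inherits(cell, "simulation_cell"), inherits(params, "energy_params"))
  par <- cpp_par(params, dna, cell)
  par$contact <- (polyamine$d + dna$sigma) / 2
  u <- axis / sqrt(sum(axis^2))
  cg_total_energy(polyamine$offsets, polyamine$charges, dna$positions,
                  dna$charge, par, as.numeric(ref), as.numeric(u))
}

#' Total energies for a batch of configurations
#'
#' Vectorised form of [total_energy()] used by the quadrature oracle and
#' trajectory post-processing.
#'
#' @inheritParams total_energy
#' @param refs n x 3 matrix of bead-1 positions.
#' @param axes n x 3 matrix of unit rod axes.
#' @return Numeric vector of energies in kBT.
#' @export
total_energy_batch <- function(polyamine, dna, cell, params, refs, axes) {
  par <- cpp_par(params, dna, cell)
  par$contact <- (polyamine$d + dna$sigma) / 2
  cg_energy_batch(polyamine$offsets, polyamine$charges, dna$positions,
                  dna$charge, par, refs, axes)
}
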