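#' Metropolis Monte Carlo sampling of one polyamine around DNA
#'
#' Samples rigid-body configurations of a single polyamine in the cylindrical
#' cell with the Metropolis rule: each move is either a random translation of
#' the whole rod (uniform within a cube of half-width `max_trans`) or a
#' rotation about a uniformly random axis by a uniform angle within
#' `max_rot`, accepted with probability `min(1, exp(-dE/kBT))`. The reference
#' bead's z-coordinate is wrapped periodically into the cell; moves that put
#' any bead beyond the radial wall at `R_cyl`, or into hard-core overlap with
#' a phosphate, are rejected. During equilibration the step sizes are tuned
#' towards a 30-50% acceptance rate and then frozen for production (frozen so
#' that detailed balance holds for the recorded samples).
#'
#' @param polyamine A `polyamine_model`.
#' @param dna A `dna_model`.
#' @param cell A `simulation_cell`.
#' @param params An `energy_params`.
#' @param n_equil Equilibration moves (default 1e5).
#' @param n_prod Production moves (default 2e6).
#' @param stride Record every `stride`-th production configuration.
#' @param seed Integer seed; identical seeds give bit-identical trajectories.
#' @param max_trans Initial maximum translation step, nm.
#' @param max_rot Initial maximum rotation angle, rad.
#' @param tune Tune step sizes during equilibration (default TRUE).
#' @param bind_cutoff Ammonium-phosphate contact cutoff recorded per sample
#'   (nm; default 0.453, the 105-degree hydrogen-bond geometry).
#' @return An object of class `pa_trajectory`: list with `samples` (matrix
#'   with columns x, y, z, ux, uy, uz, energy), `bound` (logical per sample:
#'   all three ammoniums simultaneously within `bind_cutoff` of a phosphate),
#'   `r5`/`mu` (radial distance of the central ammonium and orientation
#'   cosine of the bead-1-to-central-ammonium vector), `acceptance`, the
#'   frozen step sizes, the models and all run parameters.
#' @export
run_mc <- function(polyamine, dna, cell, params = energy_params(),
                   n_equil = 1e5, n_prod = 2e6, stride = 10L, seed = 1L,
                   max_trans = 0.15, max_rot = 0.2, tune = TRUE,
                   bind_cutoff = 0.453) {
  stopifnot(inherits(polyamine, "polyamine_model"), inherits(dna, "dna_model"),
            inherits(cell, "simulation_cell"),
            n_equil > 0, n_prod > 0, stride > 0)
  if (polyamine$length >= 2 * cell$R_cyl && polyamine$length >= cell$H)
    stop("polyamine does not fit in the cell in any orientation")
  par <- cpp_par(params, dna, cell)
  par$contact <- (polyamine$d + dna$sigma) / 2

  # valid starting pose: rod along z, midway between DNA surface and wall
  r0 <- (dna$R_DNA + cell$R_cyl) / 2
  init_ref <- c(r0, 0, 0.05)
  init_axis <- c(0, 0, 1)

  set.seed(as.integer(seed))
  raw <- cg_run_mc(polyamine$offsets, polyamine$charges, dna$positions,
                   dna$charge, par, init_ref, init_axis,
                   as.integer(n_equil), as.integer(n_prod), as.integer(stride),
                   max_trans, max_rot, isTRUE(tune), bind_cutoff)
  s <- raw$samples
  colnames(s) <- c("x", "y", "z", "ux", "uy", "uz", "energy")

  # central ammonium (bead #5 for both species): radial distance + tilt cosine
  i5 <- polyamine$charged_indices[2]
  off5 <- polyamine$offsets[i5]
  x5 <- s[, "x"] + off5 * s[, "ux"]
  y5 <- s[, "y"] + off5 * s[, "uy"]

  structure(list(
    samples = s,
    bound = raw$bound,
    r5 = sqrt(x5^2 + y5^2),
    mu = s[, "uz"],
    acceptance = raw$acceptance,
    max_trans = raw$max_trans,
    max_rot = raw$max_rot,
    polyamine = polyamine, dna = dna, cell = cell, params = params,
    n_equil = n_equil, n_prod = n_prod, stride = as.integer(stride),
    seed = as.integer(seed), bind_cutoff = bind_cutoff
  ), class = "pa_trajectory")
}

#' @export
print.pa_trajectory <- function(x, ...) {
  cat(sprintf(
    "<pa_trajectory> %s: %d samples (stride %d), acceptance %.1f%%, bound %.3f%%\n",
    x$polyamine$species, nrow(x$samples), x$stride, 100 * x$acceptance,
    100 * mean(x$bound)))
  invisible(x)
}

#' Recompute trajectory energies from stored configurations
#'
#' Re-evaluates [total_energy()] on every stored configuration; used to check
#' the sampler's bookkeeping against a fresh computation.
#'
#' @param traj A `pa_trajectory`.
#' @return Numeric vector of energies, kBT.
#' @export
recompute_energies <- function(traj) {
  total_energy_batch(traj$polyamine, traj$dna, traj$cell, traj$params,
                     traj$samples[, 1:3, drop = FALSE],
                     traj$samples[, 4:6, drop = FALSE])
}

#' Write a trajectory to a CSV table
#'
#' Persists the sampled configurations as a columnar table (step, position,
#' axis, energy, bound flag) with a JSON sidecar of run metadata (models,
#' parameters, seed, acceptance).
#'
#' @param traj A `pa_trajectory`.
#' @param file Output CSV path; metadata is written to `<file>.json`.
#' @return `file`, invisibly.
#' @export
write_trajectory <- function(traj, file) {
  df <- data.frame(step = seq_len(nrow(traj$samples)) * traj$stride,
                   traj$samples, bound = traj$bound)
  utils::write.csv(df, file, row.names = FALSE)
  meta <- list(species = traj$polyamine$species, seed = traj$seed,
               gamma = traj$params$gamma,
               debye_length = traj$params$debye_length,
               soft_k = traj$params$soft_k,
               R_cyl = traj$cell$R_cyl, H = traj$cell$H,
               n_equil = traj$n_equil, n_prod = traj$n_prod,
               stride = traj$stride, bind_cutoff = traj$bind_cutoff,
               acceptance = traj$acceptance)
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}
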