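#' Build a rigid coarse-grained polyamine model
#'
#' Spermidine (SPD) and norspermidine (NSPD) are represented as rigid linear
#' chains of tangent beads of diameter \code{d}: methylene and ammonium groups
#' are beads on a straight rod with uniform centre-to-centre spacing equal to
#' the bead diameter. SPD has 10 beads with +1 ammonium charges at positions
#' 1, 5 and 10; NSPD has 9 beads with charges at 1, 5 and 9 — the two species
#' differ by one methylene between the second and third amine. Total charge is
#' +3 for both.
#'
#' @param species `"SPD"` or `"NSPD"`.
#' @param d Bead diameter (and centre-to-centre spacing) in nm; default 0.39.
#' @return An object of class `polyamine_model`: list with `species`,
#'   `n_beads`, `d`, `charged_indices`, `charges` (per-bead), `offsets`
#'   (distance of each bead centre from bead 1 along the rod axis, nm) and
#'   `length` (rod length `(n_beads - 1) * d`, nm).
#' @examples
#' spd <- build_polyamine("SPD")
#' spd$length            # 3.51 nm
#' sum(spd$charges)      # +3
#' @export
build_polyamine <- function(species = c("SPD", "NSPD"), d = 0.39) {
  if (!is.character(species) || !(species[1] %in% c("SPD", "NSPD")))
    stop("unknown polyamine species: ", species[1],
         " (expected \"SPD\" or \"NSPD\")")
  species <- species[1]
  stopifnot(d > 0)
  n_beads <- if (species == "SPD") 10L else 9L
  charged <- if (species == "SPD") c(1L, 5L, 10L) else c(1L, 5L, 9L)
  charges <- numeric(n_beads)
  charges[charged] <- 1
  structure(list(
    species = species,
    n_beads = n_beads,
    d = d,
    charged_indices = charged,
    charges = charges,
    offsets = (seq_len(n_beads) - 1) * d,
    length = (n_beads - 1) * d
  ), class = "polyamine_model")
}

#' Build the coarse-grained DNA model
#'
#' A DNA segment is modelled as `n_pairs` pairs of charged spheres (phosphate
#' groups, charge -1, diameter `sigma`) on a soft cylinder of radius `R_DNA`
#' whose axis is the z-axis. Pair `k` (k = 0, ..., n_pairs - 1) sits at axial
#' coordinate `k * spacing`; its two spheres are diametrically opposite
#' (azimuths `phi_k` and `phi_k + 180` degrees) with `phi_k = k *
#' twist_per_pair`. The default twist of 0 gives a straight two-rail ladder.
#' The axial span `n_pairs * spacing` equals the periodic cell height.
#'
#' @param n_pairs Number of phosphate pairs (default 10).
#' @param spacing Axial spacing between adjacent pairs, nm (default 0.34).
#' @param R_DNA Soft cylinder radius, nm (default 1.0).
#' @param sigma Phosphate sphere diameter, nm (default 0.476).
#' @param twist_per_pair Helical twist between adjacent pairs, degrees
#'   (default 0).
#' @return An object of class `dna_model`: list with the parameters plus
#'   `positions` (a `2 * n_pairs` x 3 matrix of phosphate centres, nm),
#'   `charge` (-1 per phosphate) and `H` (axial span, nm).
#' @examples
#' dna <- build_dna()
#' nrow(dna$positions)            # 20 phosphates
#' 2 * dna$n_pairs * dna$charge   # total charge -20
#' @export
build_dna <- function(n_pairs = 10L, spacing = 0.34, R_DNA = 1.0,
                      sigma = 0.476, twist_per_pair = 0) {
  stopifnot(n_pairs >= 1, spacing > 0, R_DNA > 0, sigma > 0)
  k <- seq_len(n_pairs) - 1L
  phi <- k * twist_per_pair * pi / 180
  z <- k * spacing
  pos <- rbind(
    cbind(R_DNA * cos(phi), R_DNA * sin(phi), z),
    cbind(R_DNA * cos(phi + pi), R_DNA * sin(phi + pi), z)
  )
  colnames(pos) <- c("x", "y", "z")
  structure(list(
    n_pairs = as.integer(n_pairs),
    spacing = spacing,
    R_DNA = R_DNA,
    sigma = sigma,
    twist_per_pair = twist_per_pair,
    charge = -1,
    positions = pos,
    H = n_pairs * spacing
  ), class = "dna_model")
}

#' Build the cylindrical simulation cell
#'
#' The cell is the set \eqn{x^2 + y^2 \le R_{cyl}^2, 0 \le z < H} with z
#' periodic. `H` must equal the DNA model's axial span so that the phosphate
#' lattice is consistent with the periodic images.
#'
#' @param R_cyl Outer cell radius, nm. The reference runs use 2.591 nm or
#'   5.182 nm.
#' @param H Cell height, nm (default 3.4).
#' @return An object of class `simulation_cell`.
#' @export
build_cell <- function(R_cyl = 2.591, H = 3.4) {
  stopifnot(R_cyl > 0, H > 0)
  structure(list(R_cyl = R_cyl, H = H, periodic_axis = TRUE),
            class = "simulation_cell")
}

#' Ammonium-phosphate contact distance from hydrogen-bond geometry
#'
#' Nitrogen-centre-to-phosphorus-centre distance for an N-H...O-P contact,
#' from the law of cosines on the triangle with vertex at the hydrogen-bond
#' accepting oxygen: one side is `r_N + d_HB` (nitrogen centre to oxygen,
#' through the hydrogen bond), the other is `r_P` (oxygen to phosphorus
#' centre), and `angle_deg` is the included angle at the oxygen. At 180
#' degrees (linear bond) the distance is maximal, `r_N + d_HB + r_P`.
#'
#' With the ionic radii of ammonium (0.137 nm) and phosphate (0.258 nm, the
#' sulfate value used as a stand-in) and a hydrogen-bond length of 0.174 nm,
#' this gives 0.404, 0.453 and 0.569 nm at 90, 105 and 180 degrees; 0.453 nm
#' (105 degrees) is the default binding cutoff.
#'
#' @param angle_deg Included angle at the oxygen, degrees, in [0, 180].
#' @param r_N Ammonium ionic radius, nm.
#' @param d_HB Hydrogen-bond (H...O) length, nm.
#' @param r_P Phosphate ionic radius, nm.
#' @return N-to-P centre distance in nm.
#' @examples
#' hbond_contact_distance(180) # 0.569
#' hbond_contact_distance(105) # 0.453 (binding cutoff)
#' @export
hbond_contact_distance <- function(angle_deg, r_N = 0.137, d_HB = 0.174,
                                   r_P = 0.258) {
  if (any(angle_deg < 0 | angle_deg > 180))
    stop("hydrogen-bond angle must lie in [0, 180] degrees")
  stopifnot(r_N > 0, d_HB > 0, r_P > 0)
  a <- r_N + d_HB
  b <- r_P
  sqrt(pmax(a^2 + b^2 - 2 * a * b * cos(angle_deg * pi / 180), 0))
}

#' Bead positions of a polyamine configuration
#'
#' A configuration is the position of bead 1 (`ref`) plus the unit rod axis
#' (`axis`, pointing from bead 1 to the last bead); bead i sits at
#' `ref + offsets[i] * axis`.
#'
#' @param polyamine A `polyamine_model`.
#' @param ref Numeric length-3, position of bead 1 (nm).
#' @param axis Numeric length-3 rod direction (normalised internally).
#' @return `n_beads` x 3 matrix of bead centres.
#' @export
bead_positions <- function(polyamine, ref, axis) {
  stopifnot(inherits(polyamine, "polyamine_model"),
            length(ref) == 3, length(axis) == 3)
  u <- axis / sqrt(sum(axis^2))
  t(ref + outer(u, polyamine$offsets))
}

#' Export a model snapshot as an XYZ file
#'
#' Writes phosphates (tag `P`) and, optionally, polyamine beads (`N` for
#' charged beads, `C` for methylene beads) in plain XYZ format for visual
#' inspection in a molecular viewer. Coordinates are in nm.
#'
#' @param file Output path.
#' @param dna A `dna_model`.
#' @param polyamine Optional `polyamine_model`.
#' @param ref,axis Configuration of the polyamine (required with `polyamine`).
#' @param comment Comment line for the XYZ header.
#' @return `file`, invisibly.
#' @export
write_xyz <- function(file, dna, polyamine = NULL, ref = NULL, axis = NULL,
                      comment = "coarse-grained polyamine/DNA snapshot (nm)") {
  stopifnot(inherits(dna, "dna_model"))
  tags <- rep("P", nrow(dna$positions))
  coords <- dna$positions
  if (!is.null(polyamine)) {
    stopifnot(!is.null(ref), !is.null(axis))
    bp <- bead_positions(polyamine, ref, axis)
    tags <- c(tags, ifelse(polyamine$charges != 0, "N", "C"))
    coords <- rbind(coords, bp)
  }
  lines <- c(
    as.character(nrow(coords)), comment,
    sprintf("%s %.6f %.6f %.6f", tags, coords[, 1], coords[, 2], coords[, 3])
  )
  writeLines(lines, file)
  invisible(file)
}
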