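#' Default landscape grid edges
#'
#' Radial bins of width 0.05 nm from 0 to the cell wall and orientation-cosine
#' bins of width 0.1 over [-1, 1]. The 0.05 nm radial width resolves the
#' bound shell (0.762-1.3 nm) with more than ten bins at desk-scale sample
#' counts.
#'
#' @param cell A `simulation_cell`.
#' @param dr Radial bin width, nm.
#' @param dmu Orientation-cosine bin width.
#' @return List with `r_edges` and `mu_edges`.
#' @export
default_grid <- function(cell, dr = 0.05, dmu = 0.1) {
  list(r_edges = seq(0, cell$R_cyl + dr, by = dr),
       mu_edges = seq(-1, 1, by = dmu))
}

#' Accumulate the two-variable density of the central ammonium
#'
#' Histograms the trajectory over `(r, mu)` — the radial distance of the
#' central (#5) ammonium from the DNA axis and the orientation cosine
#' `mu = cos(theta)` of the bead-1-to-central-ammonium vector relative to the
#' axis — and converts counts to a density per unit phase-space volume. The
#' phase-space measure of a bin is `2 * pi * rbar * dr * dmu * H` (axial and
#' azimuthal positions and the azimuthal orientation are integrated out), so
#' an ideal gas (no electrostatics) gives a flat density and hence a flat
#' free-energy surface. With `rbar` the bin mid-radius this measure is exact:
#' `2*pi*rbar*dr = pi*(r_hi^2 - r_lo^2)`.
#'
#' The density is normalised over the samples falling inside the grid:
#' `sum(rho * measure) = 1`.
#'
#' @param traj A `pa_trajectory` (or any list with numeric `r5` and `mu`).
#' @param r_edges,mu_edges Strictly increasing bin edges; `mu_edges` within
#'   [-1, 1].
#' @param cell A `simulation_cell` (for the axial height `H`).
#' @return An object of class `landscape_grid`: `r_edges`, `mu_edges`,
#'   `r_centers`, `mu_centers`, `counts`, `measure`, `rho5` (density),
#'   `F` (free energy `-ln rho5` in kBT, `NaN` on empty bins), `n_samples`.
#' @export
accumulate_rho5 <- function(traj, r_edges, mu_edges, cell) {
  r <- traj$r5
  mu <- traj$mu
  if (length(r) == 0) stop("empty trajectory")
  stopifnot(all(diff(r_edges) > 0), all(diff(mu_edges) > 0),
            min(mu_edges) >= -1 - 1e-12, max(mu_edges) <= 1 + 1e-12)
  ir <- findInterval(r, r_edges, rightmost.closed = TRUE)
  imu <- findInterval(mu, mu_edges, rightmost.closed = TRUE)
  nr <- length(r_edges) - 1L
  nmu <- length(mu_edges) - 1L
  keep <- ir >= 1 & ir <= nr & imu >= 1 & imu <= nmu
  counts <- matrix(0, nr, nmu)
  tab <- table(factor(ir[keep], levels = seq_len(nr)),
               factor(imu[keep], levels = seq_len(nmu)))
  counts[] <- as.numeric(tab)
  n_in <- sum(counts)
  if (n_in == 0) stop("no samples fall inside the grid")

  r_lo <- r_edges[-length(r_edges)]
  r_hi <- r_edges[-1]
  dmu <- diff(mu_edges)
  measure <- outer(pi * (r_hi^2 - r_lo^2), dmu) * cell$H
  rho <- counts / (n_in * measure)
  F <- -log(rho)
  F[counts == 0] <- NaN

  structure(list(
    r_edges = r_edges, mu_edges = mu_edges,
    r_centers = (r_lo + r_hi) / 2,
    mu_centers = (mu_edges[-length(mu_edges)] + mu_edges[-1]) / 2,
    counts = counts, measure = measure, rho5 = rho, F = F,
    n_samples = n_in
  ), class = "landscape_grid")
}

#' Conditional free energy from a density grid
#'
#' `F(r, mu)/kBT = -ln rho5(r, mu)` per bin; bins with no samples are
#' undefined (`NaN`), never zero. Present for pipelines that manipulate the
#' density first; [accumulate_rho5()] already attaches `F`.
#'
#' @param grid A `landscape_grid`.
#' @return The grid with `F` recomputed from `rho5`.
#' @export
free_energy <- function(grid) {
  stopifnot(inherits(grid, "landscape_grid"))
  F <- -log(grid$rho5)
  F[grid$counts == 0] <- NaN
  grid$F <- F
  grid
}

#' Free-energy difference landscape between two species
#'
#' Bin-wise `F_a - F_b` on identical grids; undefined wherever either input
#' is undefined. With `a` = SPD and `b` = NSPD, positive regions (hills) mark
#' configurations where NSPD is favoured and negative regions (valleys) those
#' where SPD is favoured.
#'
#' @param F_a,F_b `landscape_grid` objects on identical edges.
#' @return A `landscape_grid` whose `F` is the difference; `rho5`, `counts`
#'   are dropped.
#' @export
delta_F <- function(F_a, F_b) {
  stopifnot(inherits(F_a, "landscape_grid"), inherits(F_b, "landscape_grid"))
  if (!isTRUE(all.equal(F_a$r_edges, F_b$r_edges)) ||
      !isTRUE(all.equal(F_a$mu_edges, F_b$mu_edges)))
    stop("free-energy grids have mismatched bin edges")
  out <- F_a
  out$F <- F_a$F - F_b$F
  out$rho5 <- NULL
  out$counts <- NULL
  out$delta <- TRUE
  out
}

#' Locate the free-energy minimum in the bound region
#'
#' Global minimum of `F` restricted to bins with centre radius below `r_max`.
#' Ties are broken towards smaller `r`, then smaller `|mu|`. The tilt angle
#' is reported as `acos(|mu|)` in degrees (the rod has head-tail symmetry in
#' the tilt sense).
#'
#' @param grid A `landscape_grid` with `F`.
#' @param r_max Radial restriction, nm (default 1.3, the bound/free split).
#' @return List with `r` (nm), `mu`, `theta_deg` and `F` at the minimum.
#' @export
locate_minimum <- function(grid, r_max = 1.3) {
  stopifnot(inherits(grid, "landscape_grid"))
  sel_r <- grid$r_centers < r_max
  F <- grid$F[sel_r, , drop = FALSE]
  if (all(!is.finite(F))) stop("no defined bins with r < r_max")
  rc <- grid$r_centers[sel_r]
  idx <- which(F == min(F, na.rm = TRUE), arr.ind = TRUE)
  if (nrow(idx) > 1) {  # smaller r, then smaller |mu|
    ord <- order(rc[idx[, 1]], abs(grid$mu_centers[idx[, 2]]))
    idx <- idx[ord[1], , drop = FALSE]
  }
  mu <- grid$mu_centers[idx[1, 2]]
  list(r = rc[idx[1, 1]], mu = mu,
       theta_deg = acos(min(abs(mu), 1)) * 180 / pi,
       F = F[idx])
}

#' Export a landscape as a long-format CSV
#'
#' One row per bin: `r_center, mu_center, rho5, F, count`; grid metadata
#' (edges, sample count, cell height) goes to a JSON sidecar.
#'
#' @param grid A `landscape_grid`.
#' @param file Output CSV path.
#' @return `file`, invisibly.
#' @export
write_landscape <- function(grid, file) {
  df <- expand.grid(r_center = grid$r_centers, mu_center = grid$mu_centers)
  df$rho5 <- if (!is.null(grid$rho5)) as.vector(grid$rho5) else NA_real_
  df$F <- as.vector(grid$F)
  df$count <- if (!is.null(grid$counts)) as.vector(grid$counts) else NA_real_
  utils::write.csv(df, file, row.names = FALSE)
  jsonlite::write_json(
    list(r_edges = grid$r_edges, mu_edges = grid$mu_edges,
         n_samples = grid$n_samples),
    paste0(file, ".json"), digits = NA)
  invisible(file)
}

#' Heat-map of a free-energy landscape
#'
#' Renders `F(r, mu)` with ggplot2 (suggested dependency).
#'
#' @param grid A `landscape_grid`.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_landscape <- function(grid, title = "F(r, cos theta) / kBT") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_landscape() needs the ggplot2 package")
  df <- expand.grid(r = grid$r_centers, mu = grid$mu_centers)
  df$F <- as.vector(grid$F)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$mu,
                                   fill = .data$F)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", direction = -1) +
    ggplot2::labs(x = "r (nm)", y = "cos theta", fill = "F/kBT",
                  title = title)
}
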