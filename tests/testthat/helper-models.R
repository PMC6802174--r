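# Shared fixtures. Expensive production runs are computed once per test
# session and cached here; every run is seeded, so the cache holds the same
# trajectories any fresh session would produce.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# Reference-condition runs: both species, seeds 1:3, default sampling,
# Gamma = 1.36, R_cyl = 2.591.
production_runs <- function() {
  cached("production", {
    dna <- build_dna()
    cell <- build_cell()
    out <- list()
    for (sp in c("SPD", "NSPD"))
      for (s in 1:3)
        out[[paste0(sp, s)]] <- run_mc(build_polyamine(sp), dna, cell,
                                       energy_params(), seed = s)
    out
  })
}

# Long sampling runs for landscape statistics: the Delta-F structure is a
# few tenths of kBT and needs ~1e6+ landscape samples per species to resolve.
long_runs <- function(species) {
  cached(paste0("long_", species), {
    dna <- build_dna()
    cell <- build_cell()
    lapply(1:3, function(s)
      run_mc(build_polyamine(species), dna, cell, energy_params(),
             n_prod = 1.2e7, stride = 30, seed = s))
  })
}

# Landscape of the seed-pooled long-run samples on the default grid.
pooled_landscape <- function(species) {
  cached(paste0("landscape_", species), {
    runs <- long_runs(species)
    cell <- runs[[1]]$cell
    pool <- runs[[1]]
    pool$r5 <- unlist(lapply(runs, `[[`, "r5"), use.names = FALSE)
    pool$mu <- unlist(lapply(runs, `[[`, "mu"), use.names = FALSE)
    accumulate_rho5(pool, seq(0, cell$R_cyl + 0.05, by = 0.05),
                    seq(-1, 1, by = 0.1), cell)
  })
}

# Brute-force energy oracle: plain double loop over bead-phosphate pairs
# with axial minimum image, soft boundary and hard-core/wall rejection.
brute_energy <- function(polyamine, dna, cell, params, ref, axis) {
  u <- axis / sqrt(sum(axis^2))
  pos <- t(ref + outer(u, polyamine$offsets))
  contact <- (polyamine$d + dna$sigma) / 2
  E <- 0
  for (i in seq_len(polyamine$n_beads)) {
    rho <- sqrt(pos[i, 1]^2 + pos[i, 2]^2)
    if (rho > cell$R_cyl) return(Inf)
    if (rho < dna$R_DNA) E <- E + 0.5 * params$soft_k * (dna$R_DNA - rho)^2
    for (j in seq_len(nrow(dna$positions))) {
      dz <- pos[i, 3] - dna$positions[j, 3]
      dz <- dz - cell$H * round(dz / cell$H)
      r <- sqrt((pos[i, 1] - dna$positions[j, 1])^2 +
                (pos[i, 2] - dna$positions[j, 2])^2 + dz^2)
      if (params$hard_core && r < contact) return(Inf)
      if (polyamine$charges[i] != 0)
        E <- E + pair_energy(r, polyamine$charges[i], dna$charge, params)
    }
  }
  unname(E)
}

# Per-bin proportions of a (r, mu) histogram with 10-block standard errors.
binned_props <- function(r, mu, r_edges, mu_edges, n_blocks = 10) {
  nr <- length(r_edges) - 1L
  nmu <- length(mu_edges) - 1L
  ir <- findInterval(r, r_edges, rightmost.closed = TRUE)
  imu <- findInterval(mu, mu_edges, rightmost.closed = TRUE)
  keep <- ir >= 1 & ir <= nr & imu >= 1 & imu <= nmu
  lev <- seq_len(nr * nmu)
  lin <- factor((imu - 1L) * nr + ir, levels = lev)
  p <- as.numeric(table(lin[keep])) / sum(keep)
  blk <- cut(seq_along(r), n_blocks, labels = FALSE)
  pb <- vapply(seq_len(n_blocks), function(b) {
    k <- keep & blk == b
    as.numeric(table(lin[k])) / sum(k)
  }, numeric(nr * nmu))
  list(p = p, se = apply(pb, 1, stats::sd) / sqrt(n_blocks))
}
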