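#' Default pipeline configuration
#'
#' All tunable parameters of the analysis in one flat list, with defaults
#' equal to the reference study conditions: SPD/NSPD bead geometry (d = 0.39
#' nm), 10 phosphate pairs on a 1.0 nm soft cylinder in a periodic cell of
#' height 3.4 nm, coupling Gamma = 1.36 kBT nm, cell radius 2.591 nm,
#' binding cutoff 0.453 nm, R_cut = 1.3 nm, and the two-regime titration
#' defaults (K2 = 0.36, K1 = 0.18 mM^-1, breakpoint 0.5 mM).
#'
#' @param ... Named overrides of any default entry.
#' @return A named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    species = c("SPD", "NSPD"),
    bead_d = 0.39,
    n_pairs = 10L, pair_spacing = 0.34, R_DNA = 1.0, sigma = 0.476,
    twist_per_pair = 0,
    R_cyl = 2.591, H = 3.4,
    gamma = 1.36, debye_length = 3.04, soft_k = 10, hard_core = TRUE,
    n_equil = 1e5, n_prod = 2e6, stride = 10L,
    max_trans = 0.15, max_rot = 0.2,
    dr = 0.05, dmu = 0.1,
    bind_cutoff = 0.453, R_cut = 1.3, mu_split = 0.5, literal_eq4 = TRUE,
    titration_K2 = 0.36, titration_K1 = 0.18, titration_break = 0.5,
    titration_noise_sd = 0.02,
    seed = 1L,
    out_prefix = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read / write a flat key-value configuration file
#'
#' Plain-text `key = value` lines (or `key: value`); `#` starts a comment.
#' Values are parsed as numeric where possible, `TRUE`/`FALSE` as logical,
#' and comma-separated lists as vectors. Unknown keys are rejected, so a
#' config file round-trips losslessly through [write_config()].
#'
#' @param file Path to the config file.
#' @param config A `run_config` to write.
#' @return `read_config`: a `run_config`; `write_config`: `file`, invisibly.
#' @export
read_config <- function(file) {
  lines <- readLines(file)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parse_val <- function(v) {
    parts <- trimws(strsplit(v, ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) return(num)
    if (all(parts %in% c("TRUE", "FALSE"))) return(as.logical(parts))
    parts
  }
  kv <- strsplit(lines, "[=:]", fixed = FALSE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- lapply(kv, function(x) parse_val(paste(x[-1], collapse = ":")))
  names(vals) <- keys
  do.call(default_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, file) {
  stopifnot(inherits(config, "run_config"))
  fmt <- function(v) paste(vapply(v, format, character(1), digits = 17),
                           collapse = ", ")
  keep <- !vapply(config, is.null, logical(1))
  writeLines(sprintf("%s = %s", names(config)[keep],
                     vapply(config[keep], fmt, character(1))), file)
  invisible(file)
}

#' Run the full simulate-landscape-binding pipeline
#'
#' Executes, for each species in the config: model construction, Metropolis
#' sampling, the conditional free-energy landscape, and the binding constant;
#' then the between-species landscape difference and binding-constant ratio,
#' and a two-regime fit of a synthetic titration series. With `out_prefix`
#' set, writes the artifact bundle (landscape CSVs, a binding-summary JSON,
#' a titration CSV + fit JSON, XYZ snapshots, the config and a manifest) and
#' returns file paths alongside the results.
#'
#' @param config A [default_config()] list.
#' @return List of class `pipeline_result` with `trajectories`, `landscapes`,
#'   `delta_F` (first species minus second), `binding` (per species),
#'   `K_ratio` (second over first, i.e. NSPD/SPD under the default order),
#'   `titration` (dataset + fit), `config`, and `manifest` (paths, when
#'   written).
#' @export
run_pipeline <- function(config = default_config()) {
  stopifnot(inherits(config, "run_config"))
  dna <- build_dna(config$n_pairs, config$pair_spacing, config$R_DNA,
                   config$sigma, config$twist_per_pair)
  cell <- build_cell(config$R_cyl, config$H)
  epar <- energy_params(config$gamma, config$debye_length, config$soft_k,
                        config$hard_core)
  bpar <- binding_params(config$bind_cutoff, config$R_cut, config$mu_split)
  grid <- list(r_edges = seq(0, cell$R_cyl + config$dr, by = config$dr),
               mu_edges = seq(-1, 1, by = config$dmu))

  trajs <- lapply(config$species, function(sp) {
    pa <- build_polyamine(sp, config$bead_d)
    run_mc(pa, dna, cell, epar,
           n_equil = config$n_equil, n_prod = config$n_prod,
           stride = config$stride, seed = config$seed,
           max_trans = config$max_trans, max_rot = config$max_rot,
           bind_cutoff = config$bind_cutoff)
  })
  names(trajs) <- config$species

  lands <- lapply(trajs, accumulate_rho5, r_edges = grid$r_edges,
                  mu_edges = grid$mu_edges, cell = cell)
  dF <- if (length(lands) == 2) delta_F(lands[[1]], lands[[2]]) else NULL
  binding <- lapply(trajs, binding_K, params = bpar,
                    literal_eq4 = config$literal_eq4)
  K_ratio <- if (length(binding) == 2)
    binding[[2]]$K / binding[[1]]$K else NULL

  tit_data <- generate_titration(titration_spec(
    K2 = config$titration_K2, K1 = config$titration_K1,
    breakpoint = config$titration_break,
    noise_sd = config$titration_noise_sd, seed = config$seed))
  tit_fit <- fit_two_regime(invert_normalize(tit_data),
                            breakpoint = config$titration_break)

  manifest <- NULL
  if (!is.null(config$out_prefix)) {
    pre <- config$out_prefix
    dir.create(dirname(pre), recursive = TRUE, showWarnings = FALSE)
    paths <- c(config = paste0(pre, "_config.txt"))
    write_config(config, paths[["config"]])
    for (sp in config$species) {
      p <- paste0(pre, "_landscape_", sp, ".csv")
      write_landscape(lands[[sp]], p)
      paths[[paste0("landscape_", sp)]] <- p
      px <- paste0(pre, "_snapshot_", sp, ".xyz")
      s1 <- trajs[[sp]]$samples[1, ]
      write_xyz(px, dna, trajs[[sp]]$polyamine, s1[1:3], s1[4:6])
      paths[[paste0("snapshot_", sp)]] <- px
    }
    if (!is.null(dF)) {
      p <- paste0(pre, "_deltaF.csv")
      write_landscape(dF, p)
      paths[["delta_F"]] <- p
    }
    p <- paste0(pre, "_binding.json")
    jsonlite::write_json(list(
      seed = config$seed, gamma = config$gamma,
      binding = lapply(binding, unclass), K_ratio = K_ratio),
      p, auto_unbox = TRUE, digits = NA)
    paths[["binding"]] <- p
    p <- paste0(pre, "_titration.csv")
    write_titration(tit_data, p)
    paths[["titration"]] <- p
    p <- paste0(pre, "_titration_fit.json")
    jsonlite::write_json(unclass(tit_fit)[c("K2_low", "K1_high",
                                            "breakpoint", "rss")],
                         p, auto_unbox = TRUE, digits = NA)
    paths[["titration_fit"]] <- p
    manifest <- as.list(paths)
    jsonlite::write_json(manifest, paste0(pre, "_manifest.json"),
                         auto_unbox = TRUE)
  }

  structure(list(trajectories = trajs, landscapes = lands, delta_F = dF,
                 binding = binding, K_ratio = K_ratio,
                 titration = list(data = tit_data, fit = tit_fit),
                 config = config, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (sp in names(x$binding))
    cat(sprintf("  %s: N(binding) = %.4g, K = %.4g mM^-1\n", sp,
                x$binding[[sp]]$N_binding, x$binding[[sp]]$K))
  if (!is.null(x$K_ratio))
    cat(sprintf("  K ratio (%s/%s) = %.3g\n", names(x$binding)[2],
                names(x$binding)[1], x$K_ratio))
  cat(sprintf("  titration fit: K2 = %.3g, K1 = %.3g mM^-1\n",
              x$titration$fit$K2_low, x$titration$fit$K1_high))
  invisible(x)
}
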