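## End-to-end orchestration: morph -> per-frame CG folding energy ->
## per-(frame, offset) binding -> coupled landscape -> path/barriers ->
## per-residue decomposition, with a reproducibility manifest.

#' Default run configuration
#'
#' Nested list of every pipeline parameter with its default. Any subset
#' can be overridden through `override` (recursively merged).
#'
#' @param override named list merged over the defaults.
#' @return a list of class `flip_config`.
#' @export
default_config <- function(override = list()) {
  cfg <- list(
    seed = 1,
    fixture = list(n_helices = 4, helix_length = 20, channel_radius = 8,
                   rotation = 0),
    start_pdb = NULL,   # optional paths; fixture is used when NULL
    target_pdb = NULL,
    cg = list(shift_fraction = 0.5),
    membrane = list(z_lo = -15, z_hi = 15, spacing = 3, exclusion = 4),
    env = list(cutoff = 10),
    mcpt = list(ph = 7, temperature = 300, steps = 50000,
                u_p = -0.15, u_np = 0.35, eps_eff = 40),
    energy = list(k_hyd = 0.2, n_sat = 8, k_pol = 0.05, eps_ss = 0.10,
                  eps_ms = 0.05, e_hb = 1.0, k_solv = 0.05,
                  c1 = 0.10, c2 = 0.25, c3 = 0.15),
    morph = list(n_frames = 21, k = 100, relax_steps = 0),
    channel = list(res_a = "A:10", res_b = "C:10"),
    ligand = list(file = NULL, headgroup_charge = -1, tail_length = 6),
    binding = list(beta = 0.25, eps_p = 4, eps_w = 80, n_conf = 10,
                   jitter = 0.3),
    landscape = list(axis = c(0, 0, 1), offsets = seq(-15, 15, by = 5),
                     reference = NULL, start_offset = NULL,
                     end_offset = NULL),
    decompose = list(top_n = 10),
    out_dir = NULL)
  cfg <- utils::modifyList(cfg, override)
  class(cfg) <- c("flip_config", "list")
  cfg
}

.write_tsv <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  file
}

.stage_msg <- function(run_log, name, t0) {
  dt <- round(as.numeric(Sys.time()) - t0, 2)
  message(sprintf("[flipscape] stage %-12s %7.2f s", name, dt))
  c(run_log, stats::setNames(dt, name))
}

#' Run the full coupled-landscape pipeline
#'
#' Executes every stage on either a user-supplied structure pair or the
#' synthetic two-state fixture: conformational morphing, per-frame
#' folding free energy with sampled ionization states, per-(frame,
#' offset) ligand binding, the coupled two-dimensional landscape with
#' its least-energy path and barriers, and the per-residue energy
#' decomposition across the highest barrier. When `config$out_dir` is
#' set, all tables, frames, the landscape heat-map and a manifest (config
#' echo, seeds, file checksums) are written there.
#'
#' @param config a list from [default_config()] (or an override list).
#' @return invisibly, a list with `morph`, `channel_profile`, `ledgers`,
#'   `conf_g`, `profile`, `profile_barriers`, `bind_g`, `landscape`,
#'   `path`, `decomposition`, `manifest`.
#' @export
run_pipeline <- function(config = default_config()) {
  if (!inherits(config, "flip_config")) config <- default_config(config)
  cfg <- config
  log <- numeric(0)
  out <- cfg$out_dir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE,
                                recursive = TRUE)

  t0 <- as.numeric(Sys.time())
  if (!is.null(cfg$start_pdb) && !is.null(cfg$target_pdb)) {
    start <- read_structure(cfg$start_pdb)
    target <- read_structure(cfg$target_pdb)
  } else {
    spec <- fixture_spec(n_helices = cfg$fixture$n_helices,
                         helix_length = cfg$fixture$helix_length,
                         channel_radius = cfg$fixture$channel_radius,
                         rotation = cfg$fixture$rotation,
                         seed = cfg$seed)
    pair <- make_two_state_pair(spec)
    start <- pair$a
    target <- pair$b
  }
  log <- .stage_msg(log, "structures", t0)

  t0 <- as.numeric(Sys.time())
  mp <- morph(start, target, n_frames = cfg$morph$n_frames,
              relax_steps = cfg$morph$relax_steps, k = cfg$morph$k)
  chan <- channel_distance_profile(mp, cfg$channel$res_a,
                                   cfg$channel$res_b)
  log <- .stage_msg(log, "morph", t0)

  t0 <- as.numeric(Sys.time())
  nf <- mp$n_frames
  ledgers <- vector("list", nf)
  conf_g <- numeric(nf)
  for (f in seq_len(nf)) {
    cg <- coarse_grain(mp$frames[[f]],
                       shift_fraction = cfg$cg$shift_fraction)
    env <- build_membrane_grid(cg, z_lo = cfg$membrane$z_lo,
                               z_hi = cfg$membrane$z_hi,
                               spacing = cfg$membrane$spacing,
                               exclusion = cfg$membrane$exclusion)
    ion <- mcpt_sample(cg, env, ph = cfg$mcpt$ph,
                       temperature = cfg$mcpt$temperature,
                       steps = cfg$mcpt$steps,
                       seed = cfg$seed + f,
                       u_p = cfg$mcpt$u_p, u_np = cfg$mcpt$u_np,
                       eps_eff = cfg$mcpt$eps_eff,
                       cutoff = cfg$env$cutoff)
    ledgers[[f]] <- cg_folding_energy(cg, env, ion = ion,
                                      cutoff = cfg$env$cutoff,
                                      params = cfg$energy)
    conf_g[f] <- ledgers[[f]]$dg_fold
  }
  profile <- conf_g - conf_g[1]
  pb <- profile_barriers(profile)
  log <- .stage_msg(log, "cg_energy", t0)

  t0 <- as.numeric(Sys.time())
  lig <- if (!is.null(cfg$ligand$file)) read_ligand(cfg$ligand$file) else
    make_toy_lipid(headgroup_charge = cfg$ligand$headgroup_charge,
                   tail_length = cfg$ligand$tail_length)
  offsets <- cfg$landscape$offsets
  bind_g <- matrix(NA_real_, nf, length(offsets))
  for (f in seq_len(nf)) {
    poses <- place_ligand_ladder(mp$frames[[f]], lig,
                                 axis = cfg$landscape$axis,
                                 offsets = offsets)
    for (j in seq_along(poses)) {
      lra <- configuration_ensemble(mp$frames[[f]], poses[[j]],
                                    n_conf = cfg$binding$n_conf,
                                    jitter = cfg$binding$jitter,
                                    seed = cfg$seed + 1000 * f + j,
                                    beta = cfg$binding$beta,
                                    eps_p = cfg$binding$eps_p,
                                    eps_w = cfg$binding$eps_w)
      bind_g[f, j] <- lra$dg_bind
    }
  }
  log <- .stage_msg(log, "binding", t0)

  t0 <- as.numeric(Sys.time())
  land <- build_landscape(profile, bind_g,
                          reference = cfg$landscape$reference,
                          conf_labels = seq_len(nf) - 1L,
                          offsets = offsets)
  j_start <- cfg$landscape$start_offset %||% which.min(land$G[1, ])
  j_end <- cfg$landscape$end_offset %||% which.min(land$G[nf, ])
  path <- least_energy_path(land, c(1, j_start), c(nf, j_end))
  log <- .stage_msg(log, "landscape", t0)

  t0 <- as.numeric(Sys.time())
  f_peak <- if (nrow(pb) > 0) pb$peak_index[which.max(pb$barrier)] else nf
  f_base <- which.min(profile[1:f_peak])
  decomp <- decompose_difference(ledgers[[f_base]], ledgers[[f_peak]],
                                 top_n = cfg$decompose$top_n)
  log <- .stage_msg(log, "decompose", t0)

  result <- list(morph = mp, channel_profile = chan, ledgers = ledgers,
                 conf_g = conf_g, profile = profile,
                 profile_barriers = pb, bind_g = bind_g,
                 landscape = land, path = path, decomposition = decomp,
                 states = c(base = f_base, peak = f_peak))

  if (!is.null(out)) {
    files <- .write_pipeline_outputs(result, lig, cfg, out)
    manifest <- list(
      package_version = as.character(utils::packageVersion("flipscape")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = cfg$seed,
      config = unclass(cfg[setdiff(names(cfg), "out_dir")]),
      config_hash = .config_hash(cfg),
      files = files)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    result$manifest <- manifest
  }
  result$stage_seconds <- log
  invisible(result)
}

.config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg[setdiff(names(cfg),
                                                  "out_dir")]),
                              auto_unbox = TRUE, digits = NA), tmp)
  as.character(tools::md5sum(tmp))
}

.write_pipeline_outputs <- function(res, lig, cfg, out) {
  nf <- res$morph$n_frames
  write_morph_frames(res$morph, file.path(out, "frames"))
  files <- c(
    .write_tsv(data.frame(frame = seq_len(nf) - 1L,
                          rho = res$morph$rho,
                          rmsd_to_target = res$morph$rmsd_to_target,
                          restraint_energy = res$morph$restraint_energy,
                          channel_distance = res$channel_profile,
                          conf_g = res$conf_g,
                          profile = res$profile),
               file.path(out, "profile.tsv")),
    .write_tsv(do.call(rbind, lapply(seq_len(nf), function(f) {
      cbind(frame = f - 1L, res$ledgers[[f]]$per_residue)
    })), file.path(out, "ledger.tsv")),
    .write_tsv({
      bt <- expand.grid(frame = seq_len(nf) - 1L,
                        offset = cfg$landscape$offsets)
      bt$dg_bind <- as.numeric(res$bind_g)
      bt
    }, file.path(out, "binding.tsv")),
    .write_tsv(landscape_table(res$landscape),
               file.path(out, "landscape.tsv")),
    .write_tsv(data.frame(step = seq_len(nrow(res$path$cells)),
                          frame = res$path$cells[, 1] - 1L,
                          offset = res$landscape$offsets[
                            res$path$cells[, 2]],
                          G = res$landscape$G[res$path$cells]),
               file.path(out, "path.tsv")),
    .write_tsv(res$profile_barriers,
               file.path(out, "profile_barriers.tsv")),
    .write_tsv(res$decomposition, file.path(out, "decomposition.tsv")),
    write_ligand(lig, file.path(out, "ligand.tsv")))
  p <- plot_landscape(res$landscape, res$path)
  if (!is.null(p)) {
    try(suppressMessages(ggplot2::ggsave(file.path(out, "landscape.png"),
                                         p, width = 7, height = 5,
                                         dpi = 150)), silent = TRUE)
  }
  checks <- tools::md5sum(files)
  stats::setNames(as.character(checks), basename(names(checks)))
}
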