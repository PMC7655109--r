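# End-to-end pipeline runs from a JSON config: fingerprint, descriptors,
# pore. Every run writes a manifest (inputs, config, md5 checksums, seed,
# package version) sufficient to reproduce it bit-identically; outputs
# carry no timestamps.

.read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    cfg <- jsonlite::read_json(config, simplifyVector = TRUE)
    cfg$.config_path <- config
    cfg
  } else if (is.list(config)) {
    config
  } else {
    stop("config must be a path or a list")
  }
}

.validate_paths <- function(cfg, fields) {
  for (f in fields) {
    if (is.null(cfg[[f]])) {
      stop("config validation: missing required field '", f, "'",
           call. = FALSE)
    }
    if (!file.exists(cfg[[f]])) {
      stop("config validation: path for '", f, "' does not exist: ",
           cfg[[f]], call. = FALSE)
    }
  }
}

.fp_config_from <- function(cfg) {
  ov <- cfg$fingerprint %||% list()
  do.call(fingerprint_config, ov[names(ov) %in% names(formals(fingerprint_config))])
}

.write_manifest <- function(outdir, cfg, extra = list()) {
  inputs <- cfg[vapply(cfg, function(x) {
    is.character(x) && length(x) == 1L && file.exists(x) && !dir.exists(x)
  }, logical(1))]
  manifest <- c(
    list(
      package = "channelsift",
      version = as.character(utils::packageVersion("channelsift")),
      seed = cfg$seed %||% NA,
      config = cfg[setdiff(names(cfg), ".config_path")],
      input_md5 = lapply(inputs, function(p) unname(tools::md5sum(p)))
    ),
    extra
  )
  jsonlite::write_json(
    manifest, file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA
  )
}

.with_stage <- function(stage, outdir, written, expr) {
  tryCatch(expr, error = function(e) {
    # remove partial outputs so a failed run leaves nothing half-written
    for (f in written) {
      if (file.exists(f)) unlink(f)
    }
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the fingerprint pipeline
#'
#' Chains [fingerprint_trajectory()], [occupancy_probability()],
#' [markov_error()] and [stability_class()], writing the per-frame matrix,
#' the probability summary, and a reproducibility manifest.
#'
#' @param config path to a JSON config or an equivalent list. Required
#'   fields: `trajectory` (multi-model PDB), `ligand_spec` (JSON). Optional:
#'   `stride_ps`, `fingerprint` (threshold overrides), `residues`
#'   (data.frame-like with chain/resno), `prior_count`, `n_samples`,
#'   `ci_level`, `seed`, `outdir`.
#' @return invisibly, a list with `matrix`, `summary`, and output paths.
#' @export
run_fingerprint <- function(config) {
  cfg <- .read_run_config(config)
  .validate_paths(cfg, c("trajectory", "ligand_spec"))
  outdir <- cfg$outdir %||% "."
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(outdir, c("fingerprint_matrix.csv",
                               "fingerprint_summary.csv", "manifest.json"))
  res <- .with_stage("fingerprint", outdir, paths, {
    traj <- read_structure(cfg$trajectory)
    lig <- read_ligand_spec(cfg$ligand_spec)
    fpc <- .fp_config_from(cfg)
    residues <- if (!is.null(cfg$residues)) {
      as.data.frame(cfg$residues, stringsAsFactors = FALSE)
    }
    fp <- fingerprint_trajectory(
      traj, lig, fpc,
      stride_ps = cfg$stride_ps, residues = residues
    )
    smry <- fingerprint_summary(
      fp,
      prior_count = cfg$prior_count %||% 1,
      n_samples = cfg$n_samples %||% 10000,
      ci_level = cfg$ci_level %||% 0.95,
      seed = cfg$seed %||% 1
    )
    fingerprint_table(fp, paths[1L])
    utils::write.csv(smry, paths[2L], row.names = FALSE)
    list(matrix = fp, summary = smry)
  })
  .write_manifest(outdir, cfg, list(outputs = basename(paths[1:2])))
  invisible(c(res, list(paths = paths)))
}

#' Run the conformational-descriptor pipeline
#'
#' Chains [ligand_pose_rmsd()], [loopc_descriptors()], [gate_distance()],
#' [pocket_water_count()] and (given a second structure)
#' [residue_displacement_map()] over the sampled frames.
#'
#' @param config path to a JSON config or list. Required: `trajectory`,
#'   `reference` (single-model PDB), `ligand_spec`. Optional: `role_map`
#'   (JSON), `stride_ps`, `gate_threshold`, `water_cutoff`, `compare_to`
#'   (second structure for the displacement map), `outdir`, `seed`.
#' @return invisibly, a list with `descriptors` (tidy data.frame) and paths.
#' @export
run_descriptors <- function(config) {
  cfg <- .read_run_config(config)
  .validate_paths(cfg, c("trajectory", "reference", "ligand_spec"))
  outdir <- cfg$outdir %||% "."
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(outdir, c("descriptors.csv", "displacement.csv",
                               "manifest.json"))
  res <- .with_stage("descriptors", outdir, paths, {
    traj <- read_structure(cfg$trajectory)
    ref <- frame_structure(read_structure(cfg$reference), 1L)
    lig <- read_ligand_spec(cfg$ligand_spec)
    roles <- if (!is.null(cfg$role_map)) {
      read_role_map(cfg$role_map)
    } else {
      residue_role_map()
    }
    fidx <- .stride_frames(traj$times, cfg$stride_ps)
    parts <- list()
    parts$rmsd <- ligand_pose_rmsd(
      traj, ref, lig, roles,
      stride_ps = cfg$stride_ps
    )
    parts$loop <- tryCatch(
      loopc_descriptors(traj, ref, roles, stride_ps = cfg$stride_ps),
      error = function(e) NULL
    )
    gate <- lapply(fidx, function(f) {
      g <- tryCatch(
        gate_distance(
          frame_structure(traj, f), roles,
          threshold = cfg$gate_threshold %||% 4.0
        ),
        error = function(e) NULL
      )
      if (is.null(g)) {
        return(NULL)
      }
      .descriptor_df("gate_distance", g$subunit, traj$times[f], g$distance,
                     "angstrom")
    })
    parts$gate <- do.call(rbind, gate)
    wat <- lapply(fidx, function(f) {
      w <- pocket_water_count(
        frame_structure(traj, f), lig,
        cutoff = cfg$water_cutoff %||% 3.0
      )
      .descriptor_df("pocket_waters", w$subunit, traj$times[f], w$n_waters,
                     "count")
    })
    parts$wat <- do.call(rbind, wat)
    desc <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
    rownames(desc) <- NULL
    utils::write.csv(desc, paths[1L], row.names = FALSE)
    disp <- NULL
    if (!is.null(cfg$compare_to)) {
      other <- frame_structure(read_structure(cfg$compare_to), 1L)
      disp <- residue_displacement_map(ref, other, roles)$displacements
      utils::write.csv(disp, paths[2L], row.names = FALSE)
    }
    list(descriptors = desc, displacement = disp)
  })
  .write_manifest(outdir, cfg, list(outputs = basename(paths[1:2])))
  invisible(c(res, list(paths = paths)))
}

#' Run the pore-profiling pipeline
#'
#' Strips waters/ligands/ions, profiles each sampled frame, and (with more
#' than one frame) reduces to per-z statistics.
#'
#' @param config path to a JSON config or list. Required: `trajectory`.
#'   Optional: `ligand_resnames` to strip, `stride_ps` (the 12.5 ns pore
#'   stride is 12500), `z_range`, `pore` (settings for [pore_config()]),
#'   `outdir`, `seed`.
#' @return invisibly, a list with `profiles`, `statistics`, and paths.
#' @export
run_pore <- function(config) {
  cfg <- .read_run_config(config)
  .validate_paths(cfg, "trajectory")
  outdir <- cfg$outdir %||% "."
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(outdir, c("pore_profile.csv", "pore_statistics.csv",
                               "manifest.json"))
  res <- .with_stage("pore", outdir, paths, {
    traj <- read_structure(cfg$trajectory)
    fidx <- .stride_frames(traj$times, cfg$stride_ps)
    pc <- do.call(
      pore_config,
      (cfg$pore %||% list())[
        names(cfg$pore %||% list()) %in% names(formals(pore_config))
      ]
    )
    z_range <- if (!is.null(cfg$z_range)) as.numeric(cfg$z_range)
    profiles <- lapply(fidx, function(f) {
      st <- strip_for_pore(
        frame_structure(traj, f),
        ligand_resnames = cfg$ligand_resnames %||% character(0)
      )
      pore_profile(st, z_range = z_range, config = pc)
    })
    tab <- do.call(rbind, lapply(seq_along(profiles), function(i) {
      s <- profiles[[i]]$samples
      s$time_ps <- traj$times[fidx[i]]
      s
    }))
    utils::write.csv(tab, paths[1L], row.names = FALSE)
    stats_tab <- NULL
    if (length(profiles) > 1L) {
      stats_tab <- profile_statistics(profiles)
      utils::write.csv(stats_tab, paths[2L], row.names = FALSE)
    } else {
      message("single structure input: statistics stage skipped")
    }
    list(profiles = profiles, statistics = stats_tab)
  })
  .write_manifest(outdir, cfg, list(outputs = basename(paths[1:2])))
  invisible(c(res, list(paths = paths)))
}
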