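#' Default pipeline configuration
#'
#' Every parameter of the end-to-end pipeline with its default; a user
#' config (list or YAML file) is validated against this structure and
#' unknown keys are rejected, so typos fail loudly instead of silently
#' falling back to defaults. Stage randomness derives from the single global
#' `seed` by a fixed per-stage offset, so toggling one stage does not shift
#' another stage's draws.
#'
#' @return nested named list of defaults.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 7L,
    out_dir = NULL,
    stages = list(synth = TRUE, preprocess = TRUE, correspond = TRUE,
                  shape = TRUE, density = TRUE, probe = TRUE),
    synth = list(n_specimens = 10L, n_theta = 32L, n_rings = 40L, voxel_size = 0.3,
                 noise_sd = 60, units = "HU",
                 mode_sds = list(length = 5, proximal_radius = 0.6,
                                 distal_radius = 0.6, waist_radius = 0.5,
                                 waist_axial_position = 0.04,
                                 dorsal_width = 1.25, bend_angle = 4)),
    preprocess = list(handedness = "right", threshold = "auto",
                      resegment = FALSE),
    correspond = list(points_per_segment = 10L, reference = "auto",
                      lambda = 0),
    shape = list(n_modes = 10L, waist_band = 0.6, waist_stations = 100L),
    density = list(grid_spacing = 0.3, n_controls = 300L,
                   peripheral_depth = 1.0, centre_start_depth = 3.0),
    probe = list(diameter = 3.0, n_stations = 100L, margin_depth = 0.5)
  )
}

# recursive merge of user config into defaults; unknown keys rejected
merge_config <- function(defaults, user, path = "") {
  if (!length(user)) return(defaults)
  if (is.null(names(user)) || any(names(user) == ""))
    stop("config entries must be named (at ", ifelse(path == "", "top level", path), ")")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(sub("^/", "", paste0(path, "/", unknown)), collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, "/", k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' @param config a named list of overrides, or the path to a YAML file
#'   containing them. The configuration round-trips losslessly through YAML.
#' @return the merged, validated configuration list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)
  if (is.null(cfg$out_dir)) stop("config needs out_dir")
  cfg
}

stage_seed <- function(cfg, stage) {
  offs <- c(synth = 11L, preprocess = 23L, correspond = 37L, shape = 53L,
            density = 71L, probe = 89L)
  as.integer(cfg$seed) + offs[[stage]]
}

spec_id <- function(i) sprintf("%02d", i)

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in acquisition order -- phantom synthesis,
#' image preprocessing (HU clamping, mirroring, vBMD calibration),
#' thin-plate-spline correspondence, statistical surface model (GPA + PCA +
#' morphometrics), averaged bone-density model with concentric zones, and
#' virtual pathway probing -- writing each stage's artifacts under
#' `out_dir/<stage>/` and a run manifest (`manifest.json`) listing every
#' output file with its MD5 hash and the per-stage logs. Identical
#' config + seed produce identical manifests. Each stage reads its inputs
#' from the previous stage's serialized outputs, so stages can be re-run in
#' isolation.
#'
#' @param config list of overrides or YAML path (see [pipeline_config]).
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- pipeline_config(config)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  stages <- c("synth", "preprocess", "correspond", "shape", "density", "probe")
  for (st in stages) {
    if (!isTRUE(cfg$stages[[st]])) next
    fn <- get(paste0("stage_", st), mode = "function")
    log[[st]] <- tryCatch(fn(cfg),
                          error = function(e)
                            stop("stage '", st, "' failed: ", conditionMessage(e),
                                 call. = FALSE))
  }
  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out, "manifest.json"))
  manifest <- list(config = cfg, stages_run = names(log), log = log,
                   files = data.frame(
                     path = sub(paste0("^", out, "/?"), "", files),
                     md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

stage_synth <- function(cfg) {
  d <- file.path(cfg$out_dir, "synth")
  dir.create(d, showWarnings = FALSE)
  sc <- cfg$synth
  zones <- zone_profile(noise_sd = sc$noise_sd)
  pop <- generate_population(sc$n_specimens, mode_sds = unlist(sc$mode_sds),
                             seed = stage_seed(cfg, "synth"), zones = zones,
                             n_theta = sc$n_theta, n_rings = sc$n_rings,
                             voxel_size = sc$voxel_size, units = sc$units)
  for (i in seq_along(pop$specimens)) {
    sp <- pop$specimens[[i]]
    write_ply(sp$mesh, file.path(d, paste0("mesh_", spec_id(i), ".ply")))
    write_landmarks(sp$landmarks,
                    file.path(d, paste0("landmarks_", spec_id(i), ".json")))
    write_volume(sp$volume, file.path(d, paste0("volume_", spec_id(i), ".mhd")))
  }
  write.csv(pop$params_table, file.path(d, "params.csv"), row.names = FALSE)
  list(n = sc$n_specimens, files = 3L * sc$n_specimens + 1L)
}

stage_preprocess <- function(cfg) {
  sdir <- file.path(cfg$out_dir, "synth")
  d <- file.path(cfg$out_dir, "preprocess")
  dir.create(d, showWarnings = FALSE)
  vols <- sort(list.files(sdir, pattern = "^volume_.*\\.mhd$"))
  if (!length(vols)) stop("no synth volumes found; run the synth stage first")
  warn <- character(0)
  for (vf in vols) {
    vol <- read_volume(file.path(sdir, vf))
    vol <- mirror_to_right(vol, cfg$preprocess$handedness)
    if (vol$units == "HU") {
      vol <- clamp_nonosseous(vol)
      vol <- hu_to_vbmd(vol)
    }
    write_volume(vol, file.path(d, sub("^volume", "vbmd", vf)))
    id <- sub("^volume_(\\d+)\\.mhd$", "\\1", vf)
    mesh <- if (isTRUE(cfg$preprocess$resegment)) {
      segment_to_mesh(vol, threshold = cfg$preprocess$threshold)
    } else {
      mirror_to_right(read_ply(file.path(sdir, paste0("mesh_", id, ".ply"))),
                      cfg$preprocess$handedness)
    }
    write_ply(mesh, file.path(d, paste0("mesh_", id, ".ply")))
  }
  list(n = length(vols), resegment = isTRUE(cfg$preprocess$resegment))
}

stage_correspond <- function(cfg) {
  sdir <- file.path(cfg$out_dir, "synth")
  pdir <- file.path(cfg$out_dir, "preprocess")
  d <- file.path(cfg$out_dir, "correspond")
  dir.create(d, showWarnings = FALSE)
  ids <- sub("^mesh_(\\d+)\\.ply$", "\\1",
             sort(list.files(pdir, pattern = "^mesh_.*\\.ply$")))
  if (!length(ids)) stop("no preprocessed meshes found")
  specs <- lapply(ids, function(id)
    list(mesh = read_ply(file.path(pdir, paste0("mesh_", id, ".ply"))),
         landmarks = read_landmarks(file.path(sdir, paste0("landmarks_", id, ".json")))))
  pps <- cfg$correspond$points_per_segment
  ref_idx <- if (identical(cfg$correspond$reference, "auto")) {
    select_reference(lapply(specs, function(s) resample_segments(s$landmarks, pps)))
  } else as.integer(cfg$correspond$reference)
  hom <- establish_homology(specs[[ref_idx]], specs, points_per_segment = pps,
                            lambda = cfg$correspond$lambda)
  hom <- transfer_cartilage_regions(specs[[ref_idx]]$mesh$region, hom)
  for (i in seq_along(ids))
    write_ply(homologous_mesh(hom, i),
              file.path(d, paste0("corresponded_", ids[i], ".ply")))
  write.csv(hom$residuals, file.path(d, "residuals.csv"), row.names = FALSE)
  write.csv(hom$region_area_table, file.path(d, "region_areas.csv"),
            row.names = FALSE)
  tri_hash <- tools::md5sum(file.path(d, paste0("corresponded_", ids[1], ".ply")))
  jsonlite::write_json(list(reference = ref_idx,
                            n_vertices = nrow(hom$vertices[[1]]),
                            n_triangles = nrow(hom$triangulation),
                            triangulation_hash = unname(tri_hash),
                            flagged = which(hom$flagged)),
                       file.path(d, "correspondence.json"),
                       digits = NA, auto_unbox = TRUE)
  list(reference = ref_idx, mean_residual = mean(hom$residuals$mean_residual),
       flagged = sum(hom$flagged))
}

# read the corresponded meshes back into a homologous set
read_homology <- function(cdir) {
  files <- sort(list.files(cdir, pattern = "^corresponded_.*\\.ply$",
                           full.names = TRUE))
  meshes <- lapply(files, read_ply)
  for (m in meshes[-1])
    if (!identical(m$triangles, meshes[[1]]$triangles))
      stop("corresponded meshes do not share one triangulation")
  structure(list(triangulation = meshes[[1]]$triangles,
                 region = meshes[[1]]$region,
                 vertices = lapply(meshes, `[[`, "vertices"),
                 residuals = NULL, flagged = NULL),
            class = "homologous_mesh_set")
}

stage_shape <- function(cfg) {
  cdir <- file.path(cfg$out_dir, "correspond")
  d <- file.path(cfg$out_dir, "shape")
  dir.create(d, showWarnings = FALSE)
  hom <- read_homology(cdir)
  aligned <- procrustes_align(hom)
  model <- fit_shape_pca(aligned, n_modes = cfg$shape$n_modes)
  write.csv(data.frame(mode = seq_along(model$mode_variances),
                       variance = model$mode_variances,
                       fraction = model$variance_fractions),
            file.path(d, "variance_fractions.csv"), row.names = FALSE)
  write.csv(data.frame(specimen = seq_len(nrow(model$scores)), model$scores),
            file.path(d, "scores.csv"), row.names = FALSE)
  write.csv(as.data.frame(model$modes), file.path(d, "modes.csv"),
            row.names = FALSE)
  mean_mesh <- synthesize_shape(model, 1, 0)
  write_ply(mean_mesh, file.path(d, "mean_model.ply"))
  for (k in c(-2, 2))
    write_ply(synthesize_shape(model, 1, k),
              file.path(d, sprintf("pc1_%+dsd.ply", k)))
  # morphometrics: mean model and per-specimen (two distinct code paths:
  # one measurement of the mean mesh vs the population statistics of the
  # per-specimen measurements)
  measure1 <- function(mesh) {
    mm <- measure_morphometrics(mesh, waist_band = cfg$shape$waist_band,
                                n_stations = cfg$shape$waist_stations)
    c(length = mm$length, waist_d1 = mm$waist_diameters[1],
      waist_d2 = mm$waist_diameters[2], dorsal_width = mm$dorsal_width,
      total_area = mm$total_area, mm$region_areas)
  }
  mean_desc <- measure1(mean_mesh)
  per_spec <- t(vapply(seq_along(aligned$vertices), function(i)
    measure1(homologous_mesh(aligned, i)), mean_desc))
  stats_tab <- population_stats(as.data.frame(per_spec))
  stats_tab$mean_model <- mean_desc[stats_tab$descriptor]
  write.csv(stats_tab, file.path(d, "morphometrics.csv"), row.names = FALSE)
  write.csv(data.frame(specimen = seq_len(nrow(per_spec)), per_spec,
                       check.names = FALSE),
            file.path(d, "morphometrics_per_specimen.csv"), row.names = FALSE)
  list(n_modes = ncol(model$modes),
       pc1_fraction = model$variance_fractions[1],
       procrustes_iterations = aligned$iterations)
}

stage_density <- function(cfg) {
  pdir <- file.path(cfg$out_dir, "preprocess")
  cdir <- file.path(cfg$out_dir, "correspond")
  sdir <- file.path(cfg$out_dir, "shape")
  d <- file.path(cfg$out_dir, "density")
  dir.create(d, showWarnings = FALSE)
  hom <- read_homology(cdir)
  mean_mesh <- read_ply(file.path(sdir, "mean_model.ply"))
  vols <- lapply(sort(list.files(pdir, pattern = "^vbmd_.*\\.mhd$",
                                 full.names = TRUE)), read_volume)
  grid <- build_reference_grid(mean_mesh, cfg$density$grid_spacing)
  model <- build_averaged_model(grid, hom, vols,
                                mean_vertices = mean_mesh$vertices,
                                n_controls = cfg$density$n_controls)
  model <- segment_zones(model, mean_mesh,
                         peripheral_depth = cfg$density$peripheral_depth,
                         centre_start_depth = cfg$density$centre_start_depth)
  zs <- zone_stats(model)
  write.csv(zs, file.path(d, "zone_stats.csv"), row.names = FALSE)
  mv <- model$mean_vbmd
  mv[is.na(mv)] <- 0
  write_volume(density_volume(mv, model$spacing, origin = model$origin,
                              units = "vBMD"),
               file.path(d, "mean_vbmd.mhd"))
  write_volume(density_volume(array(as.numeric(model$zone_labels), model$dim),
                              model$spacing, origin = model$origin,
                              units = "vBMD"),
               file.path(d, "zone_labels.mhd"))
  jsonlite::write_json(list(n_inside = sum(grid$inside),
                            spacing = grid$spacing,
                            unmappable = model$unmappable),
                       file.path(d, "density.json"), digits = NA,
                       auto_unbox = TRUE)
  list(n_inside = sum(grid$inside),
       zone_means = stats::setNames(zs$mean, zs$zone))
}

# default probe endpoints on the mean model: a central pathway along the
# long axis and a peripheral pathway running beneath the dorsal surface
default_probe_paths <- function(mean_mesh, margin_depth = 0.5,
                                span = 0.6) {
  ax <- principal_axes(mean_mesh$vertices)
  a <- ax$axes[, 1]
  proj <- as.vector(sweep(mean_mesh$vertices, 2, ax$centre) %*% a)
  half <- span * (max(proj) - min(proj)) / 2
  central <- list(entry = ax$centre - half * a, exit = ax$centre + half * a)
  # dorsal direction: the side of the third axis with the smaller extent
  # (the flattened dorsal surface)
  d3 <- as.vector(sweep(mean_mesh$vertices, 2, ax$centre) %*% ax$axes[, 3])
  dorsal <- if (max(d3) < -min(d3)) ax$axes[, 3] else -ax$axes[, 3]
  # largest dorsal offset keeping the mid-span chord inside the mesh
  offset_ok <- function(t) {
    pts <- rbind(central$entry + t * dorsal, ax$centre + t * dorsal,
                 central$exit + t * dorsal)
    all(points_in_mesh(mean_mesh, pts))
  }
  lo <- 0; hi <- max(abs(d3))
  for (it in 1:30) {
    mid <- (lo + hi) / 2
    if (offset_ok(mid)) lo <- mid else hi <- mid
  }
  t_per <- max(lo - margin_depth, 0)
  list(central = central,
       peripheral = list(entry = central$entry + t_per * dorsal,
                         exit = central$exit + t_per * dorsal))
}

stage_probe <- function(cfg) {
  ddir <- file.path(cfg$out_dir, "density")
  sdir <- file.path(cfg$out_dir, "shape")
  d <- file.path(cfg$out_dir, "probes")
  dir.create(d, showWarnings = FALSE)
  mean_mesh <- read_ply(file.path(sdir, "mean_model.ply"))
  vol <- read_volume(file.path(ddir, "mean_vbmd.mhd"))
  attr(vol, "inside") <- vol$values > 0
  paths <- default_probe_paths(mean_mesh, cfg$probe$margin_depth)
  profs <- lapply(names(paths), function(nm) {
    pr <- probe_pathway(vol, paths[[nm]]$entry, paths[[nm]]$exit,
                        diameter = cfg$probe$diameter,
                        n_stations = cfg$probe$n_stations)
    cbind(pathway = nm, pr$profile)
  })
  write.csv(do.call(rbind, profs), file.path(d, "probe_profiles.csv"),
            row.names = FALSE)
  summ <- do.call(rbind, lapply(names(paths), function(nm) {
    pr <- probe_pathway(vol, paths[[nm]]$entry, paths[[nm]]$exit,
                        diameter = cfg$probe$diameter,
                        n_stations = cfg$probe$n_stations)
    data.frame(pathway = nm, mean = pr$summary$mean, min = pr$summary$min,
               max = pr$summary$max)
  }))
  write.csv(summ, file.path(d, "probe_summary.csv"), row.names = FALSE)
  list(path_means = stats::setNames(summ$mean, summ$pathway))
}

#' Render a human-readable pipeline report
#'
#' Summarizes a completed run from its manifest: principal-component
#' variance fractions, the +/- 2 SD morphometric contrasts of the first
#' mode, the zone statistics table and the probe-profile summary. Sections
#' whose stage outputs are missing are omitted with a notice.
#'
#' @param manifest a manifest list from [run_pipeline] or the path to a
#'   `manifest.json`.
#' @return character vector of report lines, invisibly; also written to
#'   `report/report.txt` under the run's output directory.
#' @export
pipeline_report <- function(manifest) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  out <- manifest$config$out_dir
  lines <- c("carposhape pipeline report", "==========================", "")
  vf_path <- file.path(out, "shape", "variance_fractions.csv")
  if (file.exists(vf_path)) {
    vf <- read.csv(vf_path)
    lines <- c(lines, "Principal component variance fractions:",
               sprintf("  PC%d: %.1f%%", vf$mode, 100 * vf$fraction), "")
    mm_path <- file.path(out, "shape", "morphometrics.csv")
    if (file.exists(mm_path)) {
      mm <- read.csv(mm_path)
      lines <- c(lines, "Morphometrics, mean +/- SD (min-max) over specimens:",
                 sprintf("  %-28s %s  [mean model: %.1f]", mm$descriptor,
                         mm$formatted, mm$mean_model), "")
    }
  } else lines <- c(lines, "[shape stage outputs missing: section omitted]", "")
  zs_path <- file.path(out, "density", "zone_stats.csv")
  if (file.exists(zs_path)) {
    zs <- read.csv(zs_path)
    lines <- c(lines, "Density zones (volume mm^3; vBMD mg HA/cm^3):",
               sprintf("  %-24s %9.1f  %s", zs$zone, zs$volume_mm3,
                       zs$formatted), "")
  } else lines <- c(lines, "[density stage outputs missing: section omitted]", "")
  ps_path <- file.path(out, "probes", "probe_summary.csv")
  if (file.exists(ps_path)) {
    ps <- read.csv(ps_path)
    lines <- c(lines, "Virtual probe pathways (path mean vBMD):",
               sprintf("  %-12s mean %.1f (min %.1f, max %.1f)", ps$pathway,
                       ps$mean, ps$min, ps$max), "")
  } else lines <- c(lines, "[probe stage outputs missing: section omitted]", "")
  rd <- file.path(out, "report")
  dir.create(rd, showWarnings = FALSE, recursive = TRUE)
  writeLines(lines, file.path(rd, "report.txt"))
  invisible(lines)
}
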