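#' Pipeline configuration
#'
#' Single configuration object driving [run_pipeline]: calibration, substrate
#' elasticity, analysis parameters, the stage list, the per-condition
#' synthetic scene parameters, and the master seed.  Round-trips through
#' YAML unchanged ([read_pipeline_config] / [write_pipeline_config]).
#'
#' @param seed master seed; every stochastic stage derives its own stream
#'   from it.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "piv", "tfm", "msm", "corr", "fa", "speed", "report")`,
#'   executed in dependency order.
#' @param calibration list: `px_size` (um/px), `dt_min` (frame interval,
#'   min).
#' @param substrate list: `youngs_modulus` (Pa), `poisson_ratio`.
#' @param analysis list: `window_px`, `overlap`, `threshold` (correlation
#'   crossing, default 0.01), `k_neighbors` (k-NN spacing, default 6),
#'   `correlation_mode` (`"scalar"` or `"nematic"`), `reg_lambda` (FTTC;
#'   default 0 since the simulated displacement stage is noise-free --
#'   use `"auto"` (L-curve) for measured bead displacements).
#' @param conditions list of per-condition lists: `name`, plus the
#'   [field_spec] fluctuation parameters (`kernel_scale`, `fluctuation_sd`,
#'   `drift_speed`) and optional scene overrides.
#' @param simulate list: `image_shape` (px), `n_frames`, `grid_shape`,
#'   `node_spacing` (um), `front_x0_um`, and the [fa_scene_spec] /
#'   [stress_scene_spec] overrides used when the `fa` / `tfm` stages run.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            stages = c("simulate", "piv", "corr", "speed",
                                       "report"),
                            calibration = list(px_size = 2, dt_min = 10),
                            substrate = list(youngs_modulus = 23e3,
                                             poisson_ratio = 0.5),
                            analysis = list(window_px = 32L, overlap = 0.5,
                                            threshold = 0.01,
                                            k_neighbors = 6L,
                                            correlation_mode = "scalar",
                                            reg_lambda = 0),
                            conditions = list(list(name = "demo",
                                                   kernel_scale = 40,
                                                   fluctuation_sd = 6,
                                                   drift_speed = 15)),
                            simulate = list(image_shape = c(256L, 256L),
                                            n_frames = 3L,
                                            grid_shape = 64L,
                                            node_spacing = 8,
                                            front_x0_um = NULL)) {
  known <- c("simulate", "piv", "tfm", "msm", "corr", "fa", "speed", "report")
  if (!all(stages %in% known))
    stop_invalid("unknown stage(s): ",
                 paste(setdiff(stages, known), collapse = ", "))
  cfg <- structure(list(seed = as.integer(seed), stages = stages,
                        calibration = calibration, substrate = substrate,
                        analysis = analysis, conditions = conditions,
                        simulate = simulate),
                   class = "pipeline_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  deps <- list(piv = "simulate", tfm = "simulate", msm = "tfm",
               corr = "piv", fa = "simulate", speed = "simulate")
  for (s in cfg$stages) {
    need <- deps[[s]]
    if (!is.null(need) && !(need %in% cfg$stages))
      stop_data("dependency error: stage '", s, "' requires stage '", need,
                "' (not scheduled and no stored output)")
  }
  if (is.null(cfg$calibration$px_size) || cfg$calibration$px_size <= 0)
    stop_invalid("calibration$px_size must be > 0")
  if (length(cfg$conditions) == 0) stop_invalid("at least one condition")
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config> seed %d; stages: %s\n", x$seed,
              paste(x$stages, collapse = " -> ")))
  cat(sprintf("  %d condition(s): %s\n", length(x$conditions),
              paste(vapply(x$conditions, `[[`, "", "name"), collapse = ", ")))
  invisible(x)
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return `read_pipeline_config` returns a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the simulate-then-analyze pipeline
#'
#' Executes the scheduled stages for every condition, writing artifacts
#' (TIFF movies, CSV fields and curves, JSON summaries) under `out_dir`, and
#' returns a run record with the config hash, per-stage status and a
#' checksummed output manifest.  Identical config and seed give identical
#' outputs.
#'
#' @param config a `pipeline_config` (or path to its YAML).
#' @param out_dir output directory (created if missing).
#' @return object of class `run_record`: `config_hash`, `version`,
#'   `stage_status`, `warnings`, `manifest` (data.frame path/md5),
#'   `results` (per-condition list of in-memory results).
#' @export
run_pipeline <- function(config, out_dir = tempfile("sheetmech_run_")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfgfile <- file.path(out_dir, "config.yaml")
  write_pipeline_config(config, cfgfile)
  order_all <- c("simulate", "piv", "tfm", "msm", "corr", "fa", "speed",
                 "report")
  stages <- order_all[order_all %in% config$stages]
  status <- stats::setNames(rep("pending", length(stages)), stages)
  warns <- character(0)
  results <- list()
  for (ci in seq_along(config$conditions)) {
    cond <- config$conditions[[ci]]
    cname <- cond$name %||% paste0("condition", ci)
    st <- list(name = cname)
    cseed <- derive_seed(config$seed, paste0("condition/", cname))
    for (s in stages) {
      res <- withCallingHandlers(
        run_stage(s, st, cond, config, cseed, out_dir),
        warning = function(w) {
          warns <<- c(warns, paste0(cname, "/", s, ": ", conditionMessage(w)))
          invokeRestart("muffleWarning")
        })
      st <- res
      status[s] <- "ok"
    }
    results[[cname]] <- st
  }
  manifest_paths <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  manifest <- data.frame(path = sub(paste0("^", out_dir, "/?"), "",
                                    manifest_paths),
                         md5 = unname(tools::md5sum(manifest_paths)))
  structure(list(config_hash = unname(tools::md5sum(cfgfile)),
                 version = as.character(utils::packageVersion("sheetmech")),
                 stage_status = status, warnings = warns,
                 manifest = manifest, results = results, out_dir = out_dir,
                 config = config),
            class = "run_record")
}

run_stage <- function(stage, st, cond, config, cseed, out_dir) {
  cal <- config$calibration
  ana <- config$analysis
  sim <- config$simulate
  pfx <- function(x) file.path(out_dir, paste0(st$name, "_", x))
  switch(stage,
    simulate = {
      np <- sim$n_positions %||% 1L
      st$positions <- lapply(seq_len(np), function(p) {
        fs <- field_spec(grid_shape = sim$grid_shape %||% 64L,
                         node_spacing = sim$node_spacing %||% 8,
                         drift_speed = cond$drift_speed %||% 15,
                         fluctuation_sd = cond$fluctuation_sd %||% 6,
                         kernel_scale = cond$kernel_scale %||% 40,
                         seed = derive_seed(cseed, paste0("field/", p)))
        tf <- gen_velocity_field(fs)
        mv <- gen_texture_movie(tf,
                                n_frames = sim$n_frames %||% 3L,
                                dt_min = cal$dt_min %||% 10,
                                px_size = cal$px_size,
                                image_shape = sim$image_shape %||% c(256L, 256L),
                                front_x0_um = sim$front_x0_um,
                                front_speed_um_hr = cond$drift_speed %||% 15,
                                seed = derive_seed(cseed, paste0("movie/", p)))
        mv$true_field <- tf
        mv
      })
      st$movie <- st$positions[[1]]
      write_movie_tiff(st$movie$frames, pfx("movie.tif"))
      st
    },
    piv = {
      if (is.null(st$positions))
        stop_data("dependency error: stage 'piv' needs 'simulate' output")
      st$fields_list <- lapply(st$positions, function(mv)
        piv_movie(mv$frames,
                  window_px = ana$window_px %||% 32L,
                  overlap = ana$overlap %||% 0.5,
                  dt = cal$dt_min %||% 10,
                  px_size = cal$px_size))
      st$fields <- st$fields_list[[1]]
      write_field_csv(st$fields[[length(st$fields)]], pfx("piv_field.csv"))
      st
    },
    tfm = {
      ss <- stress_scene_spec(grid_shape = sim$grid_shape %||% 64L,
                              node_spacing = sim$node_spacing %||% 8,
                              n_modes = sim$n_modes %||% 4L,
                              amplitude = cond$stress_amplitude %||% 2e-3,
                              substrate_modulus =
                                config$substrate$youngs_modulus,
                              substrate_poisson =
                                config$substrate$poisson_ratio,
                              seed = derive_seed(cseed, "scene"))
      st$scene <- gen_equilibrium_scene(ss)
      sub <- elastic_substrate(config$substrate$youngs_modulus,
                               config$substrate$poisson_ratio)
      # gel sees the reaction of the scene traction
      gel_load <- st$scene$traction
      gel_load$u <- -gel_load$u; gel_load$v <- -gel_load$v
      st$displacement <- forward_boussinesq(gel_load, sub)
      st$traction <- fttc(st$displacement, sub,
                          reg_lambda = ana$reg_lambda %||% 0, pad = FALSE)
      write_field_csv(st$traction, pfx("traction.csv"))
      st
    },
    msm = {
      if (is.null(st$traction))
        stop_data("dependency error: stage 'msm' needs 'tfm' output")
      st$stress <- msm_solve(st$traction, boundary = "periodic",
                             flip_sign = TRUE)
      write_stress_csv(st$stress, pfx("stress.csv"))
      st
    },
    corr = {
      if (is.null(st$fields_list))
        stop_data("dependency error: stage 'corr' needs 'piv' output")
      curves <- list()
      for (p in seq_along(st$fields_list)) {
        mv <- st$positions[[p]]
        for (t in seq_along(st$fields_list[[p]])) {
          f <- st$fields_list[[p]][[t]]
          if (!is.null(mv$masks)) {
            # correlation is a bulk-monolayer statistic: keep only nodes
            # whose whole interrogation window lies inside the monolayer
            # (windows straddling the front carry corrupted vectors)
            m <- mv$masks[[t]] & mv$masks[[t + 1]]
            w2 <- ceiling((ana$window_px %||% 32L) / 2)
            at <- function(dx, dy) {
              ix <- pmin(pmax(round(f$x / mv$px_size) + 1 + dx, 1), nrow(m))
              iy <- pmin(pmax(round(f$y / mv$px_size) + 1 + dy, 1), ncol(m))
              m[ix, iy]
            }
            inside <- at(-w2, -w2) & at(-w2, w2) & at(w2, -w2) & at(w2, w2)
            f$u[!inside] <- NA; f$v[!inside] <- NA
          }
          dec <- decompose_velocity(f, migration_direction = c(1, 0))
          curves <- c(curves, list(
            velocity_correlation(dec, threshold = ana$threshold %||% 0.01)))
        }
      }
      cv <- average_correlation(curves)
      # the deep 0.01 crossing is noise-sensitive: restrict to separations
      # the view supports and enforce the monotone decay before crossing.
      # No plateau correction here: at the small view-to-scale ratios of
      # routine movies the finite-view deficit is r-dependent, and
      # correcting mid-range bins by the far-tail estimate overshoots
      # (plateau_correct is for the matched large-view calibration studies)
      keep <- cv$r <= 0.5 * max(cv$r)
      iso <- -stats::isoreg(cv$r[keep], -cv$C[keep])$yf
      st$velocity_corr <- correlation_curve(cv$r[keep], iso,
                                            cv$n_pairs[keep],
                                            ana$threshold %||% 0.01)
      write_correlation(st$velocity_corr, pfx("velocity_corr.csv"),
                        mode = "velocity")
      if (!is.null(st$stress)) {
        st$stress_corr <- stress_correlation(
          st$stress, mode = ana$correlation_mode %||% "scalar",
          threshold = ana$threshold %||% 0.01)
        write_correlation(st$stress_corr, pfx("stress_corr.csv"),
                          mode = paste0("stress-",
                                        ana$correlation_mode %||% "scalar"))
      }
      st
    },
    fa = {
      fa <- fa_scene_spec(n_adhesions = sim$fa_n %||% 60L,
                          lifetime_mean = cond$fa_lifetime_mean %||% 14,
                          frame_interval = sim$fa_dt %||% 2,
                          n_frames = sim$fa_frames %||% 60L,
                          appearance_rate = sim$fa_rate %||% 2,
                          seed = derive_seed(cseed, "fa"))
      mv <- gen_fa_movie(fa)
      dets <- lapply(mv$frames, segment_adhesions,
                     px_size = fa$px_size)
      st$fa_tracks <- track_adhesions(dets,
                                      frame_interval = fa$frame_interval)
      st$fa_summary <- lifetime_summary(st$fa_tracks)
      st
    },
    speed = {
      if (is.null(st$positions))
        stop_data("dependency error: stage 'speed' needs 'simulate' output")
      profiles <- lapply(seq_along(st$positions), function(p) {
        mv <- st$positions[[p]]
        if (!is.null(mv$masks)) {
          sheet_speed(NULL, method = "front-edge", dt = mv$dt_min,
                      px_size = mv$px_size, masks = mv$masks)
        } else {
          flds <- st$fields_list[[p]]
          if (is.null(flds))
            stop_data("dependency error: 'speed' (piv-mean) needs 'piv' output")
          sheet_speed(mv$frames, method = "piv-mean", dt = mv$dt_min,
                      px_size = mv$px_size,
                      window_px = config$analysis$window_px %||% 32L)
        }
      })
      st$speed <- profiles[[1]]
      st$speed$speed_um_hr <- mean(vapply(profiles, `[[`, 0, "speed_um_hr"))
      st
    },
    report = st)
}

#' Per-condition summary report of a pipeline run
#'
#' One row per condition with sheet speed, velocity and stress correlation
#' lengths, mean traction, and focal-adhesion lifetime / area / density --
#' the per-condition readouts of the quantification chain.  Condition
#' ordering is preserved.
#'
#' @param run a `run_record` from [run_pipeline].
#' @return data.frame, also written to `report.csv` under the run's output
#'   directory.
#' @export
pipeline_report <- function(run) {
  stopifnot(inherits(run, "run_record"))
  if (length(run$results) == 0) stop_data("empty run")
  rows <- lapply(run$results, function(st) {
    data.frame(
      condition = st$name,
      speed_um_hr = if (!is.null(st$speed)) st$speed$speed_um_hr else NA_real_,
      velocity_corr_len_um = if (!is.null(st$velocity_corr))
        st$velocity_corr$correlation_length else NA_real_,
      stress_corr_len_um = if (!is.null(st$stress_corr))
        st$stress_corr$correlation_length else NA_real_,
      mean_traction_pa = if (!is.null(st$traction))
        traction_summary(st$traction)$mean_pa else NA_real_,
      fa_lifetime_min = if (!is.null(st$fa_summary))
        st$fa_summary$mean_min else NA_real_,
      fa_n = if (!is.null(st$fa_summary)) st$fa_summary$n else NA_integer_)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  utils::write.csv(tab, file.path(run$out_dir, "report.csv"),
                   row.names = FALSE)
  tab
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("<run_record> sheetmech %s, config %s\n", x$version,
              substr(x$config_hash, 1, 8)))
  for (s in names(x$stage_status))
    cat(sprintf("  %-9s %s\n", s, x$stage_status[s]))
  cat(sprintf("  %d output file(s), %d warning(s)\n", nrow(x$manifest),
              length(x$warnings)))
  invisible(x)
}
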