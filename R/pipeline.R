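## Config-driven orchestration of the analysis battery: validates a config,
## runs the enabled stages in dependency order, writes per-stage TSV/OpenDX
## outputs plus a JSON summary of all scalar results, and logs the effective
## parameter set.  Re-running an identical config reproduces the summary.

#' Validate an analysis configuration
#'
#' The config is a named list (or YAML file path) with sections:
#' `input` (`topology`, `trajectory` (vector of files), `species_config` or
#' `species_rules`, optional `dt`), `output_dir`, optional `seed`, and one
#' section per stage to enable: `pcf` (`ref`, `target`, `bin_width`,
#' `r_max`), `hbond` (`d_cut`, `angle_cut`, `local_cutoff`, `solute`),
#' `shells` (`solute`, `cutoff`), `residence` (`solute`, `cutoff`), `gist`
#' (`spacing`, `margin`, `rho0`, `eww0`, `temperature`), `chc` (`ions`,
#' `r_max`, `d_range`, `a_minor`), `dna` (`metrics`).
#'
#' @param config named list or path to a YAML file.
#' @return the validated config (with defaults filled); all validation
#'   failures are reported together.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errs <- character()
  need_file <- function(p, what) {
    if (is.null(p)) errs <<- c(errs, paste0(what, ": missing"))
    else for (f in p) if (!file.exists(f))
      errs <<- c(errs, paste0(what, ": file not found: ", f))
  }
  if (is.null(config$input)) errs <- c(errs, "input: section missing")
  else {
    need_file(config$input$topology, "input$topology")
    need_file(config$input$trajectory, "input$trajectory")
  }
  if (is.null(config$output_dir)) errs <- c(errs, "output_dir: missing")
  pos_par <- function(stage, par, default) {
    v <- config[[stage]][[par]]
    if (is.null(v)) v <- default
    if (!is.numeric(v) || any(v <= 0))
      errs <<- c(errs, sprintf("%s$%s: must be positive", stage, par))
    config[[stage]][[par]] <<- v
  }
  if (!is.null(config$pcf)) {
    pos_par("pcf", "bin_width", 0.1)
    if (is.null(config$pcf$ref) || is.null(config$pcf$target))
      errs <- c(errs, "pcf: ref and target selections required")
  }
  if (!is.null(config$hbond)) {
    pos_par("hbond", "d_cut", 3.5)
    pos_par("hbond", "angle_cut", 135)
    pos_par("hbond", "local_cutoff", 7)
  }
  if (!is.null(config$shells)) pos_par("shells", "cutoff", 3.5)
  if (!is.null(config$residence)) pos_par("residence", "cutoff", 3.5)
  if (!is.null(config$gist)) {
    pos_par("gist", "spacing", 0.5)
    pos_par("gist", "rho0", 0.0334)
    pos_par("gist", "temperature", 300)
    if (is.null(config$gist$eww0)) config$gist$eww0 <- -9.565
  }
  if (!is.null(config$chc)) {
    pos_par("chc", "r_max", 10.25)
    if (is.null(config$chc$ions)) errs <- c(errs, "chc: ions selection required")
  }
  if (is.null(config$seed)) config$seed <- 1L
  if (length(errs))
    stop("config validation failed:\n  ", paste(errs, collapse = "\n  "))
  config
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the configured analysis battery
#'
#' Stages run in dependency order (core input, then pcf / hbond / shells /
#' residence, then gist / chc / dna); a stage failure aborts its dependents
#' but not independent stages.  Writes per-stage TSV (and OpenDX) files, a
#' `summary.json` of every scalar result, and `run.log` with the effective
#' parameters.
#'
#' @param config see [validate_config()].
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$output_dir, "run.log")
  logcon <- file(logf, "w")
  on.exit(close(logcon))
  say <- function(...) writeLines(paste0(...), logcon)
  say("crowdsolv ", as.character(utils::packageVersion("crowdsolv")),
      "; R ", R.version.string)
  say("seed: ", config$seed)
  say("effective config:")
  say(yaml::as.yaml(config))

  sp <- if (!is.null(config$input$species_config))
    read_species_config(config$input$species_config)
  else list(species_rules = unlist(config$input$species_rules), params = NULL)
  top <- read_topology(config$input$topology, sp$species_rules, sp$params)
  traj <- read_trajectory(config$input$trajectory, top,
                          dt = config$input$dt %||% 1)
  say("loaded ", n_frames(traj), " frames x ", top$n_atoms, " atoms")

  summary <- list(n_frames = n_frames(traj), n_atoms = top$n_atoms,
                  seed = config$seed)
  run_stage <- function(name, fun) {
    if (is.null(config[[name]])) return(invisible(NULL))
    res <- tryCatch(fun(), error = function(e) {
      say("stage ", name, " FAILED: ", conditionMessage(e))
      warning("stage ", name, " failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      summary[[name]] <<- res
      say("stage ", name, " ok")
    }
  }

  run_stage("pcf", function() {
    cf <- config$pcf
    p <- compute_pcf(traj, select_atoms(top, cf$ref),
                     select_atoms(top, cf$target),
                     bin_width = cf$bin_width, r_max = cf$r_max)
    .write_tsv(data.frame(r = p$r, g = p$g),
               file.path(config$output_dir, "pcf.tsv"))
    out <- list(mean_g = mean(p$g), rho_bulk = p$rho_bulk)
    ext <- tryCatch(find_first_extrema(p), error = function(e) NULL)
    if (!is.null(ext)) {
      out$r_peak <- ext$r_peak
      out$r_min <- ext$r_min
      out$coordination_number <- coordination_number(p, ext$r_min)
    }
    out
  })

  run_stage("hbond", function() {
    cf <- config$hbond
    sol <- if (!is.null(cf$solute)) select_atoms(top, cf$solute)
    ser <- hbond_class_series(traj, solute_sel = sol, d_cut = cf$d_cut,
                              angle_cut = cf$angle_cut,
                              local_cutoff = cf$local_cutoff)
    .write_tsv(ser, file.path(config$output_dir, "hbond_classes.tsv"))
    life <- hbond_max_lifetime(traj, d_cut = cf$d_cut,
                               angle_cut = cf$angle_cut)
    .write_tsv(life, file.path(config$output_dir, "hbond_lifetimes.tsv"))
    as.list(colMeans(ser[setdiff(names(ser), "frame")]))
  })

  run_stage("shells", function() {
    cf <- config$shells
    sol <- select_atoms(top, cf$solute %||% "species SOLUTE")
    ss <- shell_series(traj, sol, cutoff = cf$cutoff)
    .write_tsv(cbind(frame = ss$frames, as.data.frame(ss$counts)),
               file.path(config$output_dir, "shell_counts.tsv"))
    c(as.list(ss$mean), list(cutoff = cf$cutoff))
  })

  run_stage("residence", function() {
    cf <- config$residence
    sol <- select_atoms(top, cf$solute %||% "species SOLUTE")
    occ <- occupancy_matrix(traj, sol, cutoff = cf$cutoff)
    res <- residence_times(occ, traj$dt)
    if (!is.null(res$records))
      .write_tsv(res$records, file.path(config$output_dir, "residence.tsv"))
    list(mrt = res$mrt, n_stays = res$n_stays)
  })

  run_stage("gist", function() {
    cf <- config$gist
    wtraj <- strip_species(traj, keep = c("SOLUTE", "WATER"))
    sol <- which(wtraj$topology$atoms$species == "SOLUTE")
    pts <- if (length(sol)) frame_coords(wtraj, 1)[sol, , drop = FALSE]
           else frame_coords(wtraj, 1)
    grid <- grid_around(pts, spacing = cf$spacing, margin = cf$margin %||% 4)
    grid <- gist_accumulate(wtraj, grid)
    gs <- gist_region_summary(grid, rho0 = cf$rho0, eww0 = cf$eww0,
                              temperature = cf$temperature)
    export_density(grid, file.path(config$output_dir, "water_g.dx"),
                   quantity = "g", rho0 = cf$rho0)
    list(de_sw = gs$de_sw, de_ww = gs$de_ww, tds_trans = gs$tds_trans,
         dg_norm = gs$dg_norm, mean_water_count = gs$mean_water_count)
  })

  run_stage("chc", function() {
    cf <- config$chc
    hf <- build_helical_frames(traj)
    ions <- select_atoms(top, cf$ions)
    co <- chc_coords(traj, ions, hf)
    occ <- groove_occupancy(co, a_minor = cf$a_minor %||% c(33, 147),
                            r_max = cf$r_max,
                            d_range = cf$d_range %||% c(2, hf$n_levels - 1))
    .write_tsv(occ, file.path(config$output_dir, "groove_occupancy.tsv"))
    list(minor_mean = mean(occ$minor), major_mean = mean(occ$major))
  })

  run_stage("dna", function() {
    sol <- which(top$atoms$species == "SOLUTE")
    out <- list()
    out$rmsd_mean <- mean(superpose_rmsd(traj, fit_sel = sol))
    if (n_frames(traj) >= 2) {
      rf <- rmsf(traj, sol)
      .write_tsv(rf, file.path(config$output_dir, "rmsf.tsv"))
      out$rmsf_mean <- mean(rf$rmsf)
    }
    eb <- tryCatch(end_to_end_bend(traj, 1), error = function(e) NULL)
    if (!is.null(eb)) {
      out$end_to_end <- eb$end_to_end
      out$bend_angle <- eb$bend_angle
    }
    out
  })

  jpath <- file.path(config$output_dir, "summary.json")
  jsonlite::write_json(summary, jpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  say("summary written to ", jpath)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
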