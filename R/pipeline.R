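#' Trailing rolling mean with a shrinking start-up window
#'
#' The smoothing used for all time-series figures: entry i is the mean
#' of the last `window` values up to and including i; the first
#' window - 1 entries average all available preceding points, so the
#' output has the same length as the input.
#'
#' @param x numeric series.
#' @param window window length in frames (default 200).
#' @return numeric vector, `length(x)`.
#' @export
rolling_mean <- function(x, window = 200) {
  if (!length(x)) stop("empty series")
  if (window < 1) stop("window must be >= 1")
  window <- as.integer(window)
  if (window == 1L) return(x)
  cs <- cumsum(x)
  n <- length(x)
  i <- seq_len(n)
  lo <- pmax(i - window, 0L)
  (cs - c(0, cs)[lo + 1L]) / (i - lo)
}

#' Default analysis configuration
#'
#' All the standard parameter defaults in one place: 10 Angstrom contact
#' cutoff, DBSCAN eps 28 Angstrom with minimum 5 molecules, 18 Angstrom
#' correlation grid, 200-frame rolling window.  Any field can be
#' overridden from a YAML config file or an R list.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    subsample = 1,                      # analyse every k-th frame
    stages = list(curvature = TRUE, contacts = TRUE, clusters = TRUE,
                  correlation = TRUE, orientation = TRUE),
    input = list(topology = NULL, trajectory = NULL, format = NULL),
    synth = list(n_per_leaflet = 150, n_frames = 5, box = c(300, 300, 300),
                 dimple_A = -30, dimple_s = 60, capsid = TRUE,
                 rotation_per_frame = 5),
    curvature = list(form = "gauss_dimple"),
    contacts = list(cutoff = 10, convention = "min_image",
                    species_a = "CAPS"),
    clusters = list(species = "DPG3", leaflet = "upper", eps = 28,
                    min_pts = 5),
    correlation = list(species = c("DPG3", "CHOL"), edge = 18,
                       leaflet = "upper"),
    orientation = list(residue_a = 1, residue_b = NULL),
    rolling_window = 200,
    out_dir = "memcurv_out")
}

#' Read an analysis configuration from YAML
#'
#' @param path YAML file; missing fields fall back to
#'   [default_config()].
#' @return configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  user <- yaml::read_yaml(path)
  utils::modifyList(default_config(), user)
}

# Build the built-in synthetic scene a config describes: membrane with a
# capsid resting above a Gaussian dimple, rotating at a fixed rate.
.config_scene <- function(cfg) {
  s <- cfg$synth
  box <- as.numeric(s$box)
  surf <- surface_params("gauss_dimple", c0 = box[3] / 2,
                         A = s$dimple_A, x0 = box[1] / 2, y0 = box[2] / 2,
                         sx = s$dimple_s, sy = s$dimple_s)
  mem <- make_membrane_frame(surf, n_per_leaflet = s$n_per_leaflet,
                             box = box, seed = cfg$seed)
  base <- mem
  if (isTRUE(s$capsid)) {
    cap <- make_capsid_shell(center = c(box[1] / 2, box[2] / 2,
                                        box[3] / 2 + 100),
                             radius = 80, beads_per_face = 6,
                             seed = cfg$seed, box = box)
    truth <- attr(mem, "truth")
    base <- merge_frames(mem, cap)
    attr(base, "truth") <- truth
  }
  make_trajectory(base, s$n_frames,
                  angles = (seq_len(s$n_frames) - 1) * s$rotation_per_frame,
                  axis = c(1, 0, 0),
                  dimple_schedule = replicate(s$n_frames, surf,
                                              simplify = FALSE),
                  seed = cfg$seed)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order (input, leaflet
#' assignment, then curvature / contacts / clusters / correlation /
#' orientation), writes one CSV per stage plus a JSON run manifest
#' (config echo, package version, seed) into the output directory.
#' Rerunning with an identical config and inputs is bit-identical.
#'
#' @param config a configuration list (see [default_config()]) or the
#'   path to a YAML config file.
#' @return named character vector of output paths, invisibly.
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- if (is.character(config)) read_config(config) else
    utils::modifyList(default_config(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  frames <- run_stage("io", {
    if (!is.null(cfg$input$topology))
      as_trajectory(read_frames(cfg$input$topology, cfg$input$trajectory,
                                cfg$input$format))
    else .config_scene(cfg)
  })
  if (cfg$subsample > 1) {
    keep <- seq(1, length(frames), by = cfg$subsample)
    frames <- bead_trajectory(unclass(frames)[keep])
  }
  leaflets <- run_stage("leaflets", assign_leaflets(frames[[1]],
                                                    quiet = TRUE))
  paths <- c()
  emit <- function(name, df) {
    p <- file.path(cfg$out_dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths[name] <<- p
  }
  st <- cfg$stages
  if (isTRUE(st$curvature))
    run_stage("curvature", {
      cs <- curvature_series(frames, form = cfg$curvature$form,
                             leaflets = leaflets)
      cs$mean_abs_K_smoothed <- rolling_mean(cs$mean_abs_K,
                                             min(cfg$rolling_window,
                                                 nrow(cs)))
      emit("curvature", cs)
    })
  if (isTRUE(st$contacts))
    run_stage("contacts", {
      spec <- contact_spec(cfg$contacts$cutoff, cfg$contacts$convention)
      mats <- contact_trajectory(frames, species_a = cfg$contacts$species_a,
                                 spec = spec)
      fq <- contact_frequency(mats)
      occ <- vapply(names(fq$residue), function(r)
        occupancy(mats, as.integer(r)), numeric(1))
      emit("contacts", data.frame(resid = as.integer(names(fq$residue)),
                                  contact_count = as.integer(fq$residue),
                                  occupancy = occ))
    })
  if (isTRUE(st$clusters))
    run_stage("clusters", {
      spec <- cluster_spec(cfg$clusters$eps, cfg$clusters$min_pts)
      emit("clusters", cluster_series(frames, cfg$clusters$species,
                                      cfg$clusters$leaflet, spec,
                                      leaflets = leaflets))
    })
  if (isTRUE(st$correlation))
    run_stage("correlation",
              emit("correlation",
                   correlation_series(frames, cfg$correlation$species,
                                      edge = cfg$correlation$edge,
                                      leaflet = cfg$correlation$leaflet)))
  if (isTRUE(st$orientation))
    run_stage("orientation", {
      rb <- cfg$orientation$residue_b %||%
        (max(frames[[1]]$beads$resid[
          species_matches(frames[[1]]$beads$species, "CAPS")]))
      emit("orientation", orientation_angles(frames,
                                             cfg$orientation$residue_a, rb))
    })
  manifest <- list(package = "memcurv",
                   version = as.character(utils::packageVersion("memcurv")),
                   seed = cfg$seed, config = cfg,
                   outputs = as.list(paths))
  mp <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths["manifest"] <- mp
  invisible(paths)
}
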