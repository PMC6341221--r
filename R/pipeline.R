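# Configuration-driven orchestration: simulate -> import/edit -> metrics ->
# report, with deterministic per-stage seeds and machine-readable
# provenance. Config is YAML or JSON; unknown keys are rejected before any
# compute; every intermediate is written to the output directory.

STAGE_KEYS <- list(
  simulate = c("stage", "what", "kind", "density", "parent_density",
               "mean_offspring", "cluster_sd", "jitter_sd", "l_p", "step",
               "n_steps", "components", "n", "frame_interval", "window",
               "D", "n_tracks", "n_frames", "loc_noise_sd", "foci",
               "background", "out"),
  import_soax = c("stage", "path", "pixel_size", "fuse", "fuse_factor",
                  "min_length", "min_mean_intensity", "c_sample", "out"),
  analyze_network = c("stage", "input", "delta_s", "area_mode",
                      "edge_margin", "background", "out"),
  analyze_foci = c("stage", "input", "intensity_threshold", "min_area",
                   "connectivity", "times", "out"),
  analyze_tracks = c("stage", "input", "threshold_frames", "model",
                     "max_lag", "fit_lags", "out")
)

TOP_KEYS <- c("seed", "output_dir", "field", "stages", "log_level")

#' Read and validate a run configuration
#'
#' @param config Path to a YAML or JSON file, or a list with the same
#'   structure: top-level keys `seed`, `output_dir`, `field`
#'   (width/height/pixel_size) and `stages` (list of stage blocks, each
#'   with a `stage` name and that stage's parameters).
#' @return The validated config list (class `run_config`) with attribute
#'   `config_hash` (md5 of the canonical JSON serialization).
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    } else {
      yaml::read_yaml(config)
    }
  }
  unknown <- setdiff(names(config), TOP_KEYS)
  if (length(unknown)) stop_param("unknown config keys: %s", paste(unknown, collapse = ", "))
  if (is.null(config$stages) || !length(config$stages)) {
    stop_param("config must declare at least one stage")
  }
  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    nm <- st$stage
    if (is.null(nm) || !nm %in% names(STAGE_KEYS)) {
      stop_param("stage %d: unknown or missing stage name '%s'", i, nm %||% "<none>")
    }
    bad <- setdiff(names(st), STAGE_KEYS[[nm]])
    if (length(bad)) stop_param("stage %d (%s): unknown keys: %s",
                                i, nm, paste(bad, collapse = ", "))
  }
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  structure(config, config_hash = unname(tools::md5sum(tmp)),
            class = c("run_config", class(config)))
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in order. A single root seed is expanded
#' into deterministic per-stage child seeds, so any stage can be re-run in
#' isolation; every stage writes its outputs under `output_dir` and logs
#' input/output counts. Re-running with the same config and seed reproduces
#' the report byte-for-byte (the report carries no timestamps).
#'
#' @param config Path or list accepted by [read_run_config()].
#' @param output_dir Override for the configured output directory.
#' @param quiet Suppress stage logging.
#' @return A `run_report`: list(version, config_hash, seed, stages =
#'   per-stage summaries); also written to `output_dir/report.json`.
#' @export
run_pipeline <- function(config, output_dir = NULL, quiet = FALSE) {
  cfg <- read_run_config(config)
  out_dir <- output_dir %||% cfg$output_dir %||% stop_param("no output_dir configured")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  field <- if (!is.null(cfg$field)) {
    field_spec(cfg$field$width, cfg$field$height,
               cfg$field$pixel_size %||% 0.078)
  } else field_spec(50, 50)
  root_seed <- cfg$seed %||% 1L
  say <- function(...) if (!quiet) message(sprintf(...))
  state <- new.env(parent = emptyenv())  # objects passed between stages
  summaries <- list()
  for (i in seq_along(cfg$stages)) {
    st <- cfg$stages[[i]]
    seed_i <- child_seed(root_seed, i)
    say("[stage %d] %s (seed %d)", i, st$stage, seed_i)
    res <- tryCatch(
      switch(st$stage,
        simulate = stage_simulate(st, field, seed_i, out_dir, say),
        import_soax = stage_import(st, field, out_dir, say),
        analyze_network = stage_analyze_network(st, state, out_dir, say),
        analyze_foci = stage_analyze_foci(st, state, field, out_dir, say),
        analyze_tracks = stage_analyze_tracks(st, state, out_dir, say)),
      error = function(e) stop_param("stage %d (%s) failed: %s",
                                     i, st$stage, conditionMessage(e)))
    for (nm in names(res$state)) assign(nm, res$state[[nm]], envir = state)
    summaries[[i]] <- c(list(stage = st$stage, seed = seed_i), res$summary)
  }
  report <- list(tool = "netarch",
                 version = as.character(utils::packageVersion("netarch")),
                 config_hash = attr(cfg, "config_hash"),
                 seed = root_seed,
                 stages = summaries)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> netarch %s, %d stages, config %s\n",
              x$version, length(x$stages), substr(x$config_hash, 1, 8)))
  invisible(x)
}

stage_simulate <- function(st, field, seed, out_dir, say) {
  what <- st$what %||% "pattern"
  if (what == "pattern") {
    kind <- st$kind %||% "poisson"
    pat <- switch(kind,
      poisson = gen_poisson_pattern(st$density %||% 0.25, field, seed),
      clustered = gen_clustered_pattern(st$parent_density %||% 0.02,
                                        st$mean_offspring %||% 10,
                                        st$cluster_sd %||% 1, field, seed),
      hexagonal = gen_hexagonal_pattern(st$density %||% 0.25,
                                        st$jitter_sd %||% 0, field, seed),
      stop_param("unknown pattern kind '%s'", kind))
    path <- file.path(out_dir, st$out %||% "pattern.csv")
    write_pattern_csv(pat, path)
    say("  %d points -> %s", n_points(pat), path)
    list(state = list(pattern = pat),
         summary = list(what = "pattern", kind = kind, n_points = n_points(pat),
                        out = basename(path)))
  } else if (what == "dwells") {
    comp <- do.call(rbind, lapply(st$components, unlist))
    d <- gen_dwell_times(comp, st$n %||% 1000,
                         st$frame_interval %||% 0.05, st$window %||% 60, seed)
    path <- file.path(out_dir, st$out %||% "dwells.csv")
    write_dwells_csv(d, path)
    say("  %d dwells (%d censored) -> %s", nrow(d), sum(d$censored), path)
    list(state = list(dwells = d),
         summary = list(what = "dwells", n = nrow(d),
                        n_censored = sum(d$censored), out = basename(path)))
  } else if (what == "tracks") {
    tr <- gen_tracks(st$D %||% 0.1, st$n_tracks %||% 100,
                     st$n_frames %||% 50, st$frame_interval %||% 0.05,
                     st$loc_noise_sd %||% 0, field, seed)
    path <- file.path(out_dir, st$out %||% "tracks.csv")
    write_tracks_csv(tr, path)
    say("  %d tracks -> %s", length(unique(tr$track_id)), path)
    list(state = list(tracks = tr),
         summary = list(what = "tracks", n_tracks = length(unique(tr$track_id)),
                        out = basename(path)))
  } else if (what == "foci") {
    foci <- as.data.frame(do.call(rbind, lapply(st$foci, unlist)))
    img <- gen_foci_image(foci, st$background %||% 50, field, noise = FALSE,
                          seed = seed)
    path <- file.path(out_dir, st$out %||% "foci.tif")
    write_image(img, path)
    say("  %d foci -> %s", nrow(foci), path)
    list(state = list(image = img),
         summary = list(what = "foci", n_foci = nrow(foci), out = basename(path)))
  } else {
    stop_param("unknown simulate target '%s'", what)
  }
}

stage_import <- function(st, field, out_dir, say) {
  if (is.null(st$path) || !file.exists(st$path)) {
    stop_param("input file missing: %s", st$path %||% "<none>")
  }
  net <- parse_soax(st$path, pixel_size = st$pixel_size %||% 0.078,
                    c_sample = st$c_sample %||% 0.625)
  n0 <- nrow(net$junctions)
  if (isTRUE(st$fuse)) net <- fuse_junctions(net, st$fuse_factor %||% 1.2)
  if (!is.null(st$min_length) || !is.null(st$min_mean_intensity)) {
    net <- prune_snakes(net, st$min_length %||% 0, st$min_mean_intensity %||% 0)
  }
  path <- file.path(out_dir, st$out %||% "network.json")
  write_network_json(net, path)
  say("  %d snakes, %d junctions (%d before fusion) -> %s",
      length(net$snakes), nrow(net$junctions), n0, path)
  list(state = list(network = net),
       summary = list(n_snakes = length(net$snakes),
                      n_junctions = nrow(net$junctions),
                      n_junctions_raw = n0, out = basename(path)))
}

stage_analyze_network <- function(st, state, out_dir, say) {
  if (!is.null(st$input)) {
    obj <- if (grepl("\\.json$", st$input)) read_network_json(st$input)
           else read_pattern_csv(st$input)
  } else if (exists("network", envir = state)) {
    obj <- get("network", envir = state)
  } else if (exists("pattern", envir = state)) {
    obj <- get("pattern", envir = state)
  } else stop_param("no network or pattern available; add an input or a simulate stage")
  if (inherits(obj, "point_pattern")) {
    R <- randomness_index(obj, area_mode = st$area_mode %||% "field",
                          edge_margin = st$edge_margin %||% 0)
    prov <- attr(R, "provenance")
    summ <- list(R = as.numeric(R), R_NN = prov$R_NN, r_rand = prov$r_rand,
                 sigma = prov$sigma, n_points = n_points(obj))
  } else {
    s <- summarize_architecture(obj, background = st$background %||% 0,
                                delta_s = st$delta_s %||% obj$c_sample,
                                area_mode = st$area_mode %||% "field",
                                edge_margin = st$edge_margin %||% 0)
    summ <- unclass(s)
  }
  path <- file.path(out_dir, st$out %||% "architecture.json")
  jsonlite::write_json(summ, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("  R = %.4g -> %s", summ$R, path)
  list(state = list(), summary = summ)
}

stage_analyze_foci <- function(st, state, field, out_dir, say) {
  img <- if (!is.null(st$input)) read_image(st$input)
         else if (exists("image", envir = state)) get("image", envir = state)
         else stop_param("no image available for foci analysis")
  frames <- if (is.list(img)) img else list(img)
  tabs <- lapply(frames, function(f) {
    detect_foci(f, intensity_threshold = st$intensity_threshold %||% "otsu",
                min_area = st$min_area %||% 50,
                connectivity = st$connectivity %||% 8L)
  })
  sq <- vapply(tabs, sum_Q_foci, numeric(1))
  nf <- vapply(tabs, nrow, integer(1))
  per_frame <- file.path(out_dir, sprintf("foci_frame%03d.csv", seq_along(tabs)))
  for (i in seq_along(tabs)) utils::write.csv(tabs[[i]], per_frame[i], row.names = FALSE)
  summ <- list(n_frames = length(tabs), n_foci = nf, sum_Q_foci = sq)
  if (length(tabs) >= 3 && !is.null(st$times)) {
    fit <- fit_timecourses(unlist(st$times), Q = sq)
    summ$Q_inf <- fit$Q_fit$Q_inf; summ$tau <- fit$Q_fit$tau
  }
  say("  %s foci per frame, sum Q = %s", paste(nf, collapse = "/"),
      paste(signif(sq, 4), collapse = "/"))
  list(state = list(foci_tables = tabs), summary = summ)
}

stage_analyze_tracks <- function(st, state, out_dir, say) {
  tr <- if (!is.null(st$input)) read_tracks_csv(st$input)
        else if (exists("tracks", envir = state)) get("tracks", envir = state)
        else stop_param("no tracks available")
  dw <- if (exists("dwells", envir = state)) get("dwells", envir = state) else NULL
  summ <- list()
  if (!is.null(dw)) {
    mod <- st$model %||% "mono"
    fit <- fit_survival(dw, model = mod,
                        threshold_frames = st$threshold_frames %||% 6L)
    summ$k_off <- fit$rates; summ$amplitudes <- fit$amplitudes
    summ$survival_model <- mod
  }
  if (!is.null(tr)) {
    curve <- msd_curve(tr, max_lag = st$max_lag %||% 10L)
    dl <- fit_dlat(curve, fit_lags = st$fit_lags %||% 4L)
    utils::write.csv(as.data.frame(curve), file.path(out_dir, "msd.csv"),
                     row.names = FALSE)
    summ$D_lat <- dl$D_lat; summ$msd_offset <- dl$offset
    ed <- extract_dwells(tr, threshold_frames = st$threshold_frames %||% 6L)
    summ$bound_fraction <- ed$bound_fraction
  }
  path <- file.path(out_dir, st$out %||% "kinetics.json")
  jsonlite::write_json(summ, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("  kinetics -> %s", path)
  list(state = list(), summary = summ)
}
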