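# YAML run configuration.  Every default equals the protocol value the
# analysis was designed around: 1 A voxels, 5 A surface shell, theta 0.2,
# 4 A environment cutoff, 500 ps / 3 A stability filter, 10 ps snapshots in
# the 20-40 ns window, 20 independent runs.

#' Default run configuration
#'
#' @return A nested list of class `run_config` holding all pipeline
#'   parameters at their default values.
#' @export
default_config <- function() {
  structure(list(
    probe = list(
      resname = "PRB",
      alignment_atoms = c("C1", "O1", "O2"),
      symmetry_mappings = list(c("C1", "O1", "O2"), c("C1", "O2", "O1")),
      preset = NULL
    ),
    grid = list(spacing = 1.0, margin = 8.0, snap = TRUE),
    thresholds = list(surface_theta = 0.2, environment_cutoff = 4.0,
                      shell_cutoff = 5.0, stability_lag = 500.0,
                      stability_cutoff = 3.0),
    schedule = list(t_start = 20000.0, t_end = 40000.0, interval = 10.0),
    profile = list(half_extent = 8.0, atom_selector = "CB"),
    runs = list(count = 20L, paths = character(0)),
    synthetic = list(n_residues = 30L, n_frames = 200L, n_probes = 5L,
                     occupancy = 0.5, box = c(40, 40, 40)),
    detection_rule = "any",
    stability_filter = FALSE,
    canonical_frame = FALSE,
    seed = 1L
  ), class = "run_config")
}

merge_validate <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user))
    stop_config("config key '%s' must be a mapping", path)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop_config("unknown config key(s): %s",
                paste0(sub("^\\.", "", paste0(path, ".", unknown)),
                       collapse = ", "))
  for (k in names(user)) {
    v <- user[[k]]
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      defaults[[k]] <- merge_validate(defaults[[k]], v, paste0(path, ".", k))
    else if (is.null(v)) defaults[k] <- list(NULL)  # keep explicit nulls
    else defaults[[k]] <- v
  }
  defaults
}

validate_config <- function(cfg) {
  pos_keys <- list(
    c("grid", "spacing"), c("thresholds", "environment_cutoff"),
    c("thresholds", "shell_cutoff"), c("thresholds", "stability_lag"),
    c("thresholds", "stability_cutoff"), c("schedule", "interval"),
    c("profile", "half_extent")
  )
  for (k in pos_keys) {
    v <- cfg[[k[1]]][[k[2]]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop_config("config key '%s.%s' must be a positive number (got %s)",
                  k[1], k[2], paste(v, collapse = ","))
  }
  if (!is.numeric(cfg$thresholds$surface_theta) ||
      !is.finite(cfg$thresholds$surface_theta))
    stop_config("config key 'thresholds.surface_theta' must be finite")
  if (cfg$schedule$t_end < cfg$schedule$t_start)
    stop_config("config key 'schedule.t_end' must be >= 'schedule.t_start'")
  if (!is.numeric(cfg$runs$count) || cfg$runs$count < 1)
    stop_config("config key 'runs.count' must be >= 1")
  if (!cfg$detection_rule %in% c("any", "centroid", "all"))
    stop_config("config key 'detection_rule' must be any/centroid/all")
  box <- as.numeric(cfg$synthetic$box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop_config("config key 'synthetic.box' must be 3 positive lengths")
  cfg$synthetic$box <- box
  cfg$runs$count <- as.integer(cfg$runs$count)
  cfg$runs$paths <- as.character(cfg$runs$paths %||% character(0))
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Load and validate a YAML run configuration
#'
#' Missing keys take their defaults; unknown keys are rejected with an
#' error naming the key.  An empty file yields the all-defaults
#' configuration.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A validated `run_config`.
#' @export
load_validate_config <- function(path = NULL) {
  user <- NULL
  if (!is.null(path)) {
    if (!file.exists(path)) stop_config("config file not found: %s", path)
    user <- yaml::read_yaml(path)
  }
  cfg <- merge_validate(unclass(default_config()), user)
  cfg <- validate_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Write a run configuration as YAML
#'
#' Round-trips through [load_validate_config()] unchanged.
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# probe_definition from the config's probe block (preset wins when named)
config_probe <- function(cfg, coords = NULL) {
  if (!is.null(cfg$probe$preset)) return(probe_preset(cfg$probe$preset))
  if (identical(toupper(cfg$probe$resname), "PRB") &&
      setequal(cfg$probe$alignment_atoms, c("C1", "O1", "O2")))
    return(toy_probe_template())
  probe_definition(cfg$probe$resname, cfg$probe$alignment_atoms,
                   cfg$probe$symmetry_mappings, coords = coords)
}
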