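#' Run the analysis chain on one B-scan
#'
#' Segmentation, Snell dewarping, apex detection, perpendicular thickness and
#' 0.5-mm binning with left-eye mirroring, in one call.
#'
#' @param bscan An `oct_bscan`.
#' @param seg A [seg_params()].
#' @param refr A [refraction_params()].
#' @param anchor `"apex"` (default) anchors the lateral grid at the detected
#'   apex; `"center"` uses the scan centre.
#' @return A `thickness_profile`, with the detected apex position in
#'   attribute `apex_x_mm`.
#' @export
profile_bscan <- function(bscan, seg = seg_params(), refr = refraction_params(),
                          anchor = c("apex", "center")) {
  anchor <- match.arg(anchor)
  tr <- trace_boundaries(bscan, seg)
  surf <- dewarp_back_surface(tr$front, tr$back, refr)
  apex <- if (anchor == "apex") find_apex(surf$front) else 0
  samples <- perpendicular_thickness(surf$front, surf$back)
  prof <- bin_profile(samples, meridian = bscan$meridian, eye = bscan$eye,
                      test_index = bscan$test_index, apex_x_mm = apex)
  prof <- mirror_profile(prof)
  attr(prof, "apex_x_mm") <- as.numeric(apex)
  prof
}

known_config_keys <- c(
  "out_dir", "scan_dir", "profile_dir", "report_dir",
  "n_subjects", "seed", "meridians", "eyes", "tests",
  "geometry", "cornea", "noise", "population",
  "segmentation", "refraction", "anchor", "design", "verbosity"
)

#' Build a validated pipeline run configuration
#'
#' Unknown keys are rejected; every `cmd_*` run writes the fully resolved
#' configuration as YAML beside its outputs.
#'
#' @param ... Named configuration entries; see `epiOCT:::known_config_keys`.
#'   Component specs (`geometry`, `cornea`, `noise`, `population`,
#'   `segmentation`, `refraction`) may be given as objects or as named lists
#'   of arguments to the respective constructors.
#' @return A list of class `run_config` with all defaults resolved.
#' @export
run_config <- function(...) {
  user <- list(...)
  if (length(user) && (is.null(names(user)) || any(names(user) == "")))
    stop("all configuration entries must be named")
  unknown <- setdiff(names(user), known_config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  build <- function(key, ctor, class_name) {
    v <- user[[key]]
    if (is.null(v)) return(ctor())
    if (inherits(v, class_name)) return(v)
    do.call(ctor, as.list(v))
  }
  cfg <- list(
    out_dir = if (is.null(user$out_dir)) "epioct_run" else user$out_dir,
    scan_dir = user$scan_dir,
    profile_dir = user$profile_dir,
    report_dir = user$report_dir,
    n_subjects = if (is.null(user$n_subjects)) 21L else as.integer(user$n_subjects),
    seed = if (is.null(user$seed)) 1L else as.integer(user$seed),
    meridians = if (is.null(user$meridians)) c("horizontal", "vertical") else user$meridians,
    eyes = if (is.null(user$eyes)) c("OD", "OS") else user$eyes,
    tests = if (is.null(user$tests)) 1:2 else as.integer(user$tests),
    geometry = build("geometry", reduced_geometry_default, "oct_geometry"),
    cornea = build("cornea", cornea_model, "cornea_model"),
    noise = build("noise", noise_model, "oct_noise_model"),
    population = build("population", cohort_population, "cohort_population"),
    segmentation = build("segmentation", seg_params, "seg_params"),
    refraction = build("refraction", refraction_params, "refraction_params"),
    anchor = if (is.null(user$anchor)) "apex" else match.arg(user$anchor, c("apex", "center")),
    design = if (is.null(user$design)) "test_retest"
             else match.arg(user$design, c("test_retest", "interobserver")),
    verbosity = if (is.null(user$verbosity)) 1L else as.integer(user$verbosity)
  )
  if (is.null(cfg$scan_dir)) cfg$scan_dir <- file.path(cfg$out_dir, "scans")
  if (is.null(cfg$profile_dir)) cfg$profile_dir <- file.path(cfg$out_dir, "profiles")
  if (is.null(cfg$report_dir)) cfg$report_dir <- file.path(cfg$out_dir, "report")
  structure(cfg, class = "run_config")
}

# simulated cohorts default to the reduced 512 x 1024 grid
reduced_geometry_default <- function(...) {
  if (...length() == 0) reduced_geometry() else scan_geometry(...)
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file; top-level keys as in [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(run_config, vals)
}

write_resolved_config <- function(cfg, dir) {
  plain <- lapply(unclass(cfg), function(v) if (is.list(v)) unclass(v) else v)
  yaml::write_yaml(plain, file.path(dir, "resolved_config.yaml"))
}

say <- function(cfg, fmt, ...) {
  if (cfg$verbosity > 0) message(sprintf(fmt, ...))
}

#' Simulate a cohort to disk
#'
#' Renders the configured cohort (see [simulate_cohort()]) and writes every
#' B-scan as TIFF + JSON sidecar plus `manifest.csv` under the configured
#' scan directory.
#'
#' @param cfg A [run_config()].
#' @return The manifest data frame, invisibly.
#' @export
cmd_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$scan_dir, recursive = TRUE, showWarnings = FALSE)
  write_resolved_config(cfg, cfg$scan_dir)
  say(cfg, "simulating %d subjects -> %s", cfg$n_subjects, cfg$scan_dir)
  res <- simulate_cohort(
    n_subjects = cfg$n_subjects,
    spec = phantom_spec(cfg$geometry, cfg$cornea, cfg$noise),
    population = cfg$population,
    seed = cfg$seed,
    meridians = cfg$meridians, eyes = cfg$eyes, tests = cfg$tests,
    out_dir = cfg$scan_dir
  )
  say(cfg, "wrote %d scans", nrow(res$manifest))
  invisible(res$manifest)
}

#' Profile every simulated scan
#'
#' Runs segmentation, dewarping, thickness measurement, binning and mirroring
#' on every scan listed in the manifest and writes `profiles.csv` (long
#' format) under the configured profile directory.
#'
#' @param cfg A [run_config()].
#' @return The long profiles data frame, invisibly.
#' @export
cmd_profile <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  manifest_path <- file.path(cfg$scan_dir, "manifest.csv")
  if (!file.exists(manifest_path)) stop("no manifest at ", manifest_path)
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  dir.create(cfg$profile_dir, recursive = TRUE, showWarnings = FALSE)
  write_resolved_config(cfg, cfg$profile_dir)
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, ]
    if (is.na(r$file) || !file.exists(r$file))
      stop(sprintf("missing scan file for subject %s %s %s test %d",
                   r$subject, r$eye, r$meridian, r$test))
    bscan <- read_bscan(r$file)
    prof <- profile_bscan(bscan, cfg$segmentation, cfg$refraction,
                          anchor = cfg$anchor)
    df <- as.data.frame(prof)
    df$subject <- r$subject
    df$eye <- r$eye
    df$meridian <- r$meridian
    df$test <- r$test
    df$apex_x_mm <- attr(prof, "apex_x_mm")
    rows[[i]] <- df
  }
  profiles <- do.call(rbind, rows)
  utils::write.csv(profiles, file.path(cfg$profile_dir, "profiles.csv"),
                   row.names = FALSE)
  say(cfg, "profiled %d scans -> %s", nrow(manifest), cfg$profile_dir)
  invisible(profiles)
}

#' Compute the repeatability report from written profiles
#'
#' Pairs the two tests (or two observers) of every subject-eye, computes the
#' per-location and zonal repeatability statistics, and writes
#' `report_locations.csv` and `report_zones.csv`.
#'
#' @param cfg A [run_config()].
#' @return The `repeatability_report`, invisibly.
#' @export
cmd_repeat <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  profile_path <- file.path(cfg$profile_dir, "profiles.csv")
  if (!file.exists(profile_path)) stop("no profiles at ", profile_path)
  profiles <- utils::read.csv(profile_path, stringsAsFactors = FALSE)
  units <- unique(profiles[, c("subject", "eye", "meridian")])
  for (i in seq_len(nrow(units))) {
    u <- units[i, ]
    sel <- profiles$subject == u$subject & profiles$eye == u$eye &
      profiles$meridian == u$meridian
    have <- unique(profiles$test[sel])
    if (!all(1:2 %in% have))
      stop(sprintf("subject %s %s %s: missing test %d profile",
                   u$subject, u$eye, u$meridian, setdiff(1:2, have)[1]))
  }
  profiles$thickness_um[profiles$missing] <- NA_real_
  report <- repeatability_report(profiles, design = cfg$design)
  dir.create(cfg$report_dir, recursive = TRUE, showWarnings = FALSE)
  write_resolved_config(cfg, cfg$report_dir)
  write_report_csv(report,
                   file.path(cfg$report_dir, "report_locations.csv"),
                   file.path(cfg$report_dir, "report_zones.csv"))
  say(cfg, "central 6-mm CoR %.2f um, peripheral 4-mm CoR %.2f um",
      report$zones$mean_cor_um[1], report$zones$mean_cor_um[2])
  invisible(report)
}
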