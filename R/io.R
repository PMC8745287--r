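#' Lazy frame source
#'
#' A minimal abstraction over frame sequences so long recordings never have
#' to be held in memory: a frame count, a frame rate, and a function
#' returning the i-th frame (1-based) as a grayscale matrix or RGB array.
#'
#' @param n_frames Number of frames.
#' @param frame_rate Frames per second.
#' @param get_frame Function of one index returning a frame.
#' @return An object of class `frame_source`.
#' @export
frame_source <- function(n_frames, frame_rate, get_frame) {
  stopifnot(is.function(get_frame), n_frames >= 0, frame_rate > 0)
  structure(list(n_frames = as.integer(n_frames),
                 frame_rate = as.numeric(frame_rate),
                 get_frame = get_frame),
            class = "frame_source")
}

#' @export
print.frame_source <- function(x, ...) {
  cat(sprintf("Frame source: %d frames at %g fps (%.1f s)\n",
              x$n_frames, x$frame_rate, x$n_frames / x$frame_rate))
  invisible(x)
}

#' Coerce frames to a frame source
#'
#' Accepts an existing [frame_source], a list of frames, or an H x W x N
#' array.
#'
#' @param frames Frames in any accepted form.
#' @param frame_rate Frames per second, used when `frames` carries none.
#' @return A [frame_source].
#' @export
as_frame_source <- function(frames, frame_rate = 30) {
  if (inherits(frames, "frame_source")) return(frames)
  if (is.list(frames))
    return(frame_source(length(frames), frame_rate,
                        function(i) frames[[i]]))
  if (is.array(frames) && length(dim(frames)) == 3L)
    return(frame_source(dim(frames)[3], frame_rate,
                        function(i) frames[, , i]))
  stop("frames must be a frame_source, a list of frames, or an HxWxN array",
       call. = FALSE)
}

#' Read a recording from a directory of still frames
#'
#' Reads a directory of numbered PNG or TIFF frames (sorted by file name)
#' as a lazy [frame_source] on the 8-bit intensity scale. Lossless frame
#' sequences are the package's on-disk recording format: they round-trip
#' pixel-exactly and carry no codec dependencies.
#'
#' @param path Directory containing `.png`, `.tif` or `.tiff` files.
#' @param frame_range Optional half-open 0-based range `c(first, last)`:
#'   frames `first` to `last - 1` are read.
#' @param frame_rate Frames per second to attach (stills carry no timing
#'   metadata).
#' @return A [frame_source].
#' @export
read_frames <- function(path, frame_range = NULL, frame_rate = 30) {
  if (!dir.exists(path))
    stop(sprintf("cannot read frames: '%s' is not a directory", path),
         call. = FALSE)
  files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (!length(files))
    stop(sprintf("no PNG/TIFF frames found in '%s'", path), call. = FALSE)
  if (!is.null(frame_range)) {
    if (length(frame_range) != 2L || frame_range[1] < 0 ||
        frame_range[2] <= frame_range[1])
      stop("frame_range must be a half-open 0-based pair c(first, last)",
           call. = FALSE)
    keep <- seq.int(frame_range[1] + 1L, min(frame_range[2], length(files)))
    files <- files[keep]
  }
  read_one <- function(i) {
    f <- files[i]
    img <- switch(tolower(tools::file_ext(f)),
                  png = png::readPNG(f),
                  tif = ,
                  tiff = tiff::readTIFF(f),
                  stop(sprintf("unsupported frame format: %s", f), call. = FALSE))
    if (length(dim(img)) == 3L && dim(img)[3] > 3L)
      img <- img[, , 1:3]                      # drop alpha
    img * 255
  }
  frame_source(length(files), frame_rate, read_one)
}

# ---- configuration ---------------------------------------------------------

# Parse a JSON or YAML file into a named list.
read_config_file <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  switch(tolower(tools::file_ext(path)),
         json = jsonlite::read_json(path, simplifyVector = TRUE),
         yml = ,
         yaml = yaml::read_yaml(path),
         stop(sprintf("config file must be .json or .yaml: %s", path),
              call. = FALSE))
}

reject_unknown_keys <- function(given, allowed, where) {
  bad <- setdiff(names(given), allowed)
  if (length(bad))
    stop(sprintf("unknown %s key(s): %s", where, paste(bad, collapse = ", ")),
         call. = FALSE)
  invisible(given)
}

#' Load an arena configuration from JSON or YAML
#'
#' Keys match the [arena_config()] arguments exactly; unknown keys are
#' rejected by name, and every invariant violation is reported with the
#' offending field.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return An [arena_config()].
#' @export
load_arena_config <- function(path) {
  vals <- read_config_file(path)
  reject_unknown_keys(vals, names(formals(arena_config)), "arena config")
  do.call(arena_config, vals)
}

#' Load an arena geometry from JSON or YAML
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file with keys matching
#'   the [arena_geometry()] arguments.
#' @return An [arena_geometry()].
#' @export
load_arena_geometry <- function(path) {
  vals <- read_config_file(path)
  reject_unknown_keys(vals, names(formals(arena_geometry)), "arena geometry")
  if (!is.null(vals$stripe_roi)) vals$stripe_roi <- lapply(vals$stripe_roi, as.integer)
  do.call(arena_geometry, vals)
}

run_config_defaults <- function() {
  list(
    arena = arena_config(),
    geometry = arena_geometry(),
    segmentation = list(threshold = 128, min_foreground = 50,
                        largest_component = FALSE),
    direction = list(window = 15, max_shift = NULL, min_shift = 1,
                     min_confidence = 0.6, smooth_window = 5,
                     invert_stimulus_sign = FALSE),
    kinematics = list(dead_band = 2, smooth = FALSE),
    io = list(input = NULL, output_dir = NULL, frame_range = NULL)
  )
}

#' Assemble a full pipeline run configuration
#'
#' Collects every tunable of the pipeline in one validated object. Any
#' subset of fields may be supplied; the rest take the package defaults.
#'
#' @param arena An [arena_config()].
#' @param geometry An [arena_geometry()].
#' @param segmentation List: `threshold`, `min_foreground`,
#'   `largest_component`.
#' @param direction List: `window`, `max_shift`, `min_shift`,
#'   `min_confidence`, `smooth_window`, `invert_stimulus_sign`.
#' @param kinematics List: `dead_band`, `smooth`.
#' @param io List: `input` (frame directory), `output_dir`, `frame_range`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(arena = NULL, geometry = NULL, segmentation = list(),
                       kinematics = list(), direction = list(), io = list()) {
  def <- run_config_defaults()
  cfg <- list(
    arena = if (is.null(arena)) def$arena else arena,
    geometry = if (is.null(geometry)) def$geometry else geometry,
    segmentation = utils::modifyList(def$segmentation,
      reject_unknown_keys(segmentation, names(def$segmentation), "segmentation")),
    direction = utils::modifyList(def$direction,
      reject_unknown_keys(direction, names(def$direction), "direction"),
      keep.null = TRUE),
    kinematics = utils::modifyList(def$kinematics,
      reject_unknown_keys(kinematics, names(def$kinematics), "kinematics")),
    io = utils::modifyList(def$io,
      reject_unknown_keys(io, names(def$io), "io"), keep.null = TRUE)
  )
  stopifnot(inherits(cfg$arena, "arena_config"),
            inherits(cfg$geometry, "arena_geometry"))
  validate_arena_config(cfg$arena)
  validate_arena_geometry(cfg$geometry)
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from JSON or YAML
#'
#' Top-level sections `arena`, `geometry`, `segmentation`, `direction`,
#' `kinematics`, `io`, each with keys named exactly as in [run_config()];
#' unknown keys at any level are rejected by name.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A [run_config()].
#' @export
load_run_config <- function(path) {
  vals <- read_config_file(path)
  reject_unknown_keys(vals, c("arena", "geometry", "segmentation",
                              "direction", "kinematics", "io"), "run config")
  arena <- if (is.null(vals$arena)) NULL else {
    reject_unknown_keys(vals$arena, names(formals(arena_config)), "arena config")
    do.call(arena_config, vals$arena)
  }
  geometry <- if (is.null(vals$geometry)) NULL else {
    reject_unknown_keys(vals$geometry, names(formals(arena_geometry)), "arena geometry")
    vg <- vals$geometry
    if (!is.null(vg$stripe_roi)) vg$stripe_roi <- lapply(vg$stripe_roi, as.integer)
    do.call(arena_geometry, vg)
  }
  run_config(arena = arena, geometry = geometry,
             segmentation = as_plain_list(vals$segmentation),
             direction = as_plain_list(vals$direction),
             kinematics = as_plain_list(vals$kinematics),
             io = as_plain_list(vals$io))
}

as_plain_list <- function(x) if (is.null(x)) list() else as.list(x)

#' Write a run configuration (all effective values) to JSON
#'
#' The written file includes every default so that
#' `load_run_config(save_run_config(cfg, f))` reproduces `cfg` exactly.
#'
#' @param config A [run_config()].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
save_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- list(
    arena = unclass(config$arena),
    geometry = unclass(config$geometry),
    segmentation = config$segmentation,
    direction = config$direction,
    kinematics = config$kinematics,
    io = config$io
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# ---- pipeline --------------------------------------------------------------

#' Analyze a frame sequence into an optomotor trial
#'
#' Single-pass driver over the full measurement chain: per frame, the stripe
#' strip is read and the drum direction inferred against the previous frame,
#' and the mouse is segmented and its position/orientation angles measured;
#' the angle series are then differentiated into angular velocities, gated by
#' agreement with the stimulus direction, and summarized into the two
#' endpoints.
#'
#' @param frames A [frame_source], list of frames, or H x W x N array.
#' @param config A [run_config()] (the `io` section is ignored here).
#' @param verbose Emit QC messages.
#' @return An `optomotor_trial` (see [summarize_trial()]) whose `samples`
#'   table carries the frame-level columns of every stage.
#' @export
analyze_frames <- function(frames, config = run_config(), verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  src <- as_frame_source(frames, frame_rate = config$arena$frame_rate)
  n <- src$n_frames
  if (n < 2L) stop("at least two frames are required", call. = FALSE)
  geo <- config$geometry
  seg <- config$segmentation
  dpar <- config$direction

  pos <- ori <- shift <- conf <- rep(NA_real_, n)
  fg <- integer(n)
  stim <- rep("UNKNOWN", n)
  out_idx <- NULL
  prev_prof <- NULL
  for (i in seq_len(n)) {
    f <- to_grayscale(src$get_frame(i))
    prof <- binarize_adaptive(extract_stripe_strip(f, geo), window = dpar$window)
    if (!is.null(prev_prof)) {
      est <- infer_direction(prof, prev_prof, max_shift = dpar$max_shift,
                             min_shift = dpar$min_shift,
                             min_confidence = dpar$min_confidence,
                             invert = dpar$invert_stimulus_sign)
      stim[i] <- est$direction
      shift[i] <- est$phase_shift
      conf[i] <- est$confidence
    }
    prev_prof <- prof
    if (is.null(out_idx)) out_idx <- mask_outside_index(geo, nrow(f), ncol(f))
    f[out_idx] <- 255
    m <- segment_mouse(f, seg$threshold)
    if (isTRUE(seg$largest_component)) m <- largest_component(m)
    fg[i] <- sum(m)
    pos[i] <- position_angle(m, geo, min_foreground = seg$min_foreground)
    ori[i] <- orientation_angle(m, min_foreground = seg$min_foreground)
  }
  valid <- !is.na(pos) & !is.na(ori)
  pos[!valid] <- NA_real_
  ori[!valid] <- NA_real_
  poses <- data.frame(frame = seq_len(n) - 1L,
                      time_s = (seq_len(n) - 1L) / src$frame_rate,
                      position_angle_deg = pos,
                      orientation_angle_deg = ori,
                      foreground_px = fg,
                      valid = valid)
  stimulus <- data.frame(frame = poses$frame, time_s = poses$time_s,
                         direction = smooth_directions(stim, dpar$smooth_window),
                         phase_shift_px = shift, confidence = conf)
  kin <- velocities(poses, src$frame_rate, smooth = config$kinematics$smooth)
  kin <- direction_match(kin, stimulus, dead_band = config$kinematics$dead_band)
  trial <- summarize_trial(kin)
  if (verbose)
    message(sprintf("analyze_frames: %d frames, %d valid pose, %d matched (position)",
                    n, trial$qc$frames_valid, trial$matched_frame_counts["position"]))
  trial
}

#' Run the full pipeline from a configuration
#'
#' Reads the recording named in `config$io$input` (a directory of PNG/TIFF
#' frames), analyzes it with [analyze_frames()], and, when
#' `config$io$output_dir` is set, writes the frame-level CSV
#' (`frames.csv`), the trial summary JSON (`summary.json`, including the
#' package version and a hash of the effective configuration) and the
#' effective configuration (`config.json`). Outputs are deterministic:
#' identical input and configuration give byte-identical files.
#'
#' @param config A [run_config()] with `io$input` set.
#' @param verbose Emit QC messages.
#' @return The `optomotor_trial`, invisibly.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$io$input))
    stop("config$io$input must name a frame directory", call. = FALSE)
  src <- read_frames(config$io$input,
                     frame_range = config$io$frame_range,
                     frame_rate = config$arena$frame_rate)
  trial <- analyze_frames(src, config, verbose = verbose)
  outdir <- config$io$output_dir
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    cfg_path <- file.path(outdir, "config.json")
    save_run_config(config, cfg_path)
    write_frame_csv(trial, file.path(outdir, "frames.csv"))
    write_summary_json(trial, file.path(outdir, "summary.json"),
                       config_hash = unname(tools::md5sum(cfg_path)))
    if (verbose)
      message(sprintf("run_pipeline: wrote frames.csv, summary.json, config.json to %s",
                      outdir))
  }
  invisible(trial)
}

#' Write the frame-level table of a trial as CSV
#'
#' Comma-separated, UTF-8, header row, missing values as empty fields;
#' angles with 3 decimals, velocities with 2.
#'
#' @param trial An `optomotor_trial`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frame_csv <- function(trial, path) {
  s <- trial$samples
  fmt <- function(x, d) ifelse(is.na(x), "", formatC(x, format = "f", digits = d))
  out <- data.frame(
    frame = s$frame,
    time_s = fmt(s$time_s, 3),
    position_angle_deg = fmt(s$position_angle_deg, 3),
    orientation_angle_deg = fmt(s$orientation_angle_deg, 3),
    foreground_px = s$foreground_px,
    valid = s$valid,
    stim_direction = s$stim_direction,
    stim_phase_shift_px = fmt(s$stim_phase_shift_px, 0),
    stim_confidence = fmt(s$stim_confidence, 3),
    position_velocity_degps = fmt(s$position_velocity_degps, 2),
    orientation_velocity_degps = fmt(s$orientation_velocity_degps, 2),
    position_matched = s$position_matched,
    orientation_matched = s$orientation_matched,
    check.names = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write the trial summary as JSON
#'
#' @param trial An `optomotor_trial`.
#' @param path Output path.
#' @param config_hash Optional MD5 of the effective configuration file.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(trial, path, config_hash = NULL) {
  out <- list(
    angular_orientation_speed_degps = trial$angular_orientation_speed,
    angular_running_speed_degps = trial$angular_running_speed,
    matched_orient_frames = unname(trial$matched_frame_counts["orientation"]),
    matched_pos_frames = unname(trial$matched_frame_counts["position"]),
    frames_total = trial$qc$frames_total,
    frames_valid = trial$qc$frames_valid,
    frames_unknown_stimulus = trial$qc$frames_unknown_stimulus,
    package_version = as.character(utils::packageVersion("optodrum")),
    config_md5 = config_hash
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}
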