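#' Acquisition settings for a rotating-analyzer image sequence
#'
#' Describes how an analyzer stack is (or was) acquired: the analyzer
#' orientations, the sensor dark level, optional read and shot noise, an
#' optional per-frame integer translation jitter (camera/subject drift),
#' and the sensor bit depth. The default emulates the study protocol:
#' seven frames with the polarizer rotated in 20 degree increments
#' (0-120 degrees) plus one dark frame.
#'
#' @param analyzer_angles_deg analyzer orientations in degrees; at least 3
#'   distinct modulo 180.
#' @param dark_level sensor offset added to every frame, counts.
#' @param read_noise_sd Gaussian read noise SD, counts; 0 disables.
#' @param shot_noise logical; Poisson photon noise with `gain` counts per
#'   photoelectron.
#' @param gain counts per photoelectron when `shot_noise = TRUE`.
#' @param frame_jitter_px integer matrix (n frames x 2, row/col offsets)
#'   or NULL for no jitter.
#' @param bit_depth sensor bit depth; frames are clipped to
#'   `[0, 2^bit_depth - 1]`.
#' @param seed integer seed for all stochastic parts of the render.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(analyzer_angles_deg = seq(0, 120, by = 20),
                               dark_level = 100, read_noise_sd = 0,
                               shot_noise = FALSE, gain = 1,
                               frame_jitter_px = NULL, bit_depth = 16L,
                               seed = NULL) {
  n <- length(analyzer_angles_deg)
  if (length(unique(round(analyzer_angles_deg %% 180, 9))) < 3L)
    stop("need at least 3 analyzer angles distinct modulo 180 degrees")
  stopifnot(dark_level >= 0, read_noise_sd >= 0, gain > 0, bit_depth >= 1)
  if (!is.null(frame_jitter_px)) {
    frame_jitter_px <- matrix(as.integer(frame_jitter_px), ncol = 2)
    stopifnot(nrow(frame_jitter_px) == n)
  }
  structure(list(analyzer_angles_deg = as.numeric(analyzer_angles_deg),
                 dark_level = dark_level, read_noise_sd = read_noise_sd,
                 shot_noise = isTRUE(shot_noise), gain = gain,
                 frame_jitter_px = frame_jitter_px,
                 bit_depth = as.integer(bit_depth), seed = seed),
            class = "acquisition_config")
}

#' Construct an analyzer frame stack
#'
#' The container shared by the renderer and the ingest pipeline: a list of
#' same-shaped single-channel frames in linear counts, the analyzer angle
#' of each frame, an optional dark frame, and an optional list of
#' per-frame saturation/validity masks (`TRUE` = unusable pixel).
#'
#' @param frames list of numeric matrices, identical dimensions.
#' @param angles_deg numeric, one analyzer angle per frame.
#' @param dark optional dark frame (same dimensions).
#' @param invalid optional list of logical matrices, per-frame invalid
#'   pixels.
#' @param bit_depth sensor bit depth (full scale `2^bit_depth - 1`).
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, angles_deg, dark = NULL, invalid = NULL,
                        bit_depth = 16L) {
  stopifnot(is.list(frames), length(frames) >= 1L,
            length(angles_deg) == length(frames))
  d <- dim(frames[[1]])
  ok <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(ok)) stop("all frames must share the same dimensions")
  if (!is.null(dark) && !identical(dim(dark), d))
    stop("dark frame dimensions differ from the stack")
  if (length(unique(round(angles_deg %% 180, 9))) < 3L)
    stop("need at least 3 analyzer angles distinct modulo 180 degrees")
  structure(list(frames = frames, angles_deg = as.numeric(angles_deg),
                 dark = dark, invalid = invalid,
                 bit_depth = as.integer(bit_depth)),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("Analyzer frame stack: %d frames of %d x %d px (%d-bit)\n",
              length(x$frames), d[1], d[2], x$bit_depth))
  cat("  analyzer angles (deg):", paste(x$angles_deg, collapse = ", "), "\n")
  cat("  dark frame:", if (is.null(x$dark)) "absent" else "present", "\n")
  invisible(x)
}

#' Render an analyzer stack of a bull's-eye target
#'
#' Forward model for rotating-analyzer polarimetry of a partially
#' linearly polarized scene: the expected count at a pixel with radiance
#' R, degree of linear polarization d and angle of polarization phi,
#' viewed through an ideal linear analyzer at angle theta, is
#' \deqn{I(\theta) = \tfrac12 R (1 + d \cos 2(\theta - \phi)) + dark}
#' The one-half factor is the transmission of an ideal polarizer for
#' unpolarized light; the recovered Stokes S0 therefore equals R. Optional
#' Poisson shot noise and Gaussian read noise are applied per pixel, and a
#' per-frame integer translation jitter moves the whole scene. Frames are
#' clipped to the sensor range but kept as floating point; quantization
#' happens only on TIFF export ([write_stack()]).
#'
#' @param pattern a [scene_pattern()].
#' @param config an [acquisition_config()].
#' @return A [frame_stack()] with one frame per analyzer angle plus the
#'   dark frame.
#' @examples
#' stack <- render_stack(make_target_pattern("contrast"),
#'                       acquisition_config())
#' stack
#' @export
render_stack <- function(pattern, config = acquisition_config()) {
  validate_scene_pattern(pattern)
  stopifnot(inherits(config, "acquisition_config"))
  h <- pattern$image_size[1]; w <- pattern$image_size[2]
  full <- 2^config$bit_depth - 1
  region_fields <- function(center) {
    m <- region_masks(pattern, center = center)
    R <- matrix(pattern$background$radiance, h, w)
    d <- matrix(0, h, w); phi <- matrix(0, h, w)
    fo <- pattern$intensity_factors[["outer"]]
    fi <- pattern$intensity_factors[["inner"]]
    R[m$outer] <- pattern$outer_ring$radiance * fo
    d[m$outer] <- pattern$outer_ring$dolp
    phi[m$outer] <- pattern$outer_ring$aop_deg * pi / 180
    R[m$inner] <- pattern$inner_ring$radiance * fi
    d[m$inner] <- pattern$inner_ring$dolp
    phi[m$inner] <- pattern$inner_ring$aop_deg * pi / 180
    list(R = R, d = d, phi = phi)
  }
  base <- region_fields(pattern$center)
  render1 <- function(k) {
    jit <- if (is.null(config$frame_jitter_px)) c(0L, 0L)
           else config$frame_jitter_px[k, ]
    f <- if (all(jit == 0L)) base
         else region_fields(pattern$center + jit)
    th <- config$analyzer_angles_deg[k] * pi / 180
    I <- 0.5 * f$R * (1 + f$d * cos(2 * (th - f$phi))) + config$dark_level
    if (config$shot_noise) {
      photons <- pmax(I - config$dark_level, 0) / config$gain
      I <- rpois(length(photons), photons) * config$gain + config$dark_level
      dim(I) <- c(h, w)
    }
    if (config$read_noise_sd > 0)
      I <- I + matrix(rnorm(h * w, 0, config$read_noise_sd), h, w)
    pmin(pmax(I, 0), full)
  }
  with_seed(config$seed, {
    frames <- lapply(seq_along(config$analyzer_angles_deg), render1)
    dark <- matrix(config$dark_level, h, w)
    if (config$read_noise_sd > 0)
      dark <- dark + matrix(rnorm(h * w, 0, config$read_noise_sd), h, w)
    dark <- pmin(pmax(dark, 0), full)
    frame_stack(frames, config$analyzer_angles_deg, dark = dark,
                bit_depth = config$bit_depth)
  })
}

#' Write / read an analyzer stack as 16-bit TIFF files plus a manifest
#'
#' `write_stack()` stores each frame as an uncompressed 16-bit grayscale
#' TIFF (counts quantized to the sensor's integer range) and writes an
#' `angles.csv` manifest with columns `filename`, `angle_deg`, `is_dark`.
#' `read_stack()` reconstructs the `frame_stack` from such a directory.
#'
#' @param stack a [frame_stack()].
#' @param dir directory to write into (created if needed).
#' @param prefix filename prefix for the frame TIFFs.
#' @return `write_stack()`: the manifest data frame, invisibly.
#'   `read_stack()`: a `frame_stack`.
#' @export
write_stack <- function(stack, dir, prefix = "frame") {
  stopifnot(inherits(stack, "frame_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  full <- 2^stack$bit_depth - 1
  rows <- list()
  put <- function(img, fn, angle, is_dark) {
    tiff::writeTIFF(pmin(pmax(round(img) / full, 0), 1),
                    file.path(dir, fn), bits.per.sample = 16L,
                    compression = "none")
    rows[[length(rows) + 1L]] <<- data.frame(filename = fn,
                                             angle_deg = angle,
                                             is_dark = is_dark)
  }
  for (k in seq_along(stack$frames))
    put(stack$frames[[k]], sprintf("%s_%02d.tif", prefix, k),
        stack$angles_deg[k], FALSE)
  if (!is.null(stack$dark))
    put(stack$dark, sprintf("%s_dark.tif", prefix), NA_real_, TRUE)
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "angles.csv"), row.names = FALSE)
  invisible(manifest)
}

#' @rdname write_stack
#' @param bit_depth bit depth to restore counts at (TIFFs are stored
#'   16-bit).
#' @export
read_stack <- function(dir, bit_depth = 16L) {
  manifest <- read.csv(file.path(dir, "angles.csv"),
                       stringsAsFactors = FALSE)
  full <- 2^bit_depth - 1
  load1 <- function(fn) tiff::readTIFF(file.path(dir, fn)) * full
  lit <- manifest[!manifest$is_dark, , drop = FALSE]
  frames <- lapply(lit$filename, load1)
  dark <- if (any(manifest$is_dark))
    load1(manifest$filename[manifest$is_dark][1]) else NULL
  frame_stack(frames, lit$angle_deg, dark = dark,
              bit_depth = as.integer(bit_depth))
}
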