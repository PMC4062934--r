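#' Estimate per-pixel Stokes parameters from an analyzer stack
#'
#' An ideal linear analyzer at orientation theta transmits
#' \deqn{I(\theta) = \tfrac12 (S_0 + S_1 \cos 2\theta + S_2 \sin 2\theta)}
#' of a beam with linear Stokes parameters (S0, S1, S2). With N >= 3
#' frames at angles spanning at least three distinct orientations modulo
#' 180 degrees, the three parameters are estimated per pixel by ordinary
#' least squares against this model. One QR factorization of the shared
#' N x 3 design matrix is reused for every pixel, so the whole image is a
#' single matrix solve. The estimator is exact (zero residual) for
#' noiseless data that follow the model, and the per-pixel RMS residual
#' is returned as a model-fit diagnostic.
#'
#' @param stack a [frame_stack()], normally dark-subtracted
#'   ([dark_subtract()]) and registered ([register_stack()]) first.
#' @return An object of class `stokes_image` with per-pixel matrices
#'   `s0`, `s1`, `s2`, `residual_rms`, and logical `valid` (FALSE where
#'   any contributing frame pixel was saturated/shifted in, or where the
#'   fitted S0 is negative).
#' @export
estimate_stokes <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  th <- stack$angles_deg * pi / 180
  if (length(unique(round(stack$angles_deg %% 180, 9))) < 3L)
    stop("rank-deficient angle set: need >= 3 distinct angles mod 180 deg")
  A <- 0.5 * cbind(1, cos(2 * th), sin(2 * th))
  d <- dim(stack$frames[[1]])
  Y <- vapply(stack$frames, as.vector, numeric(prod(d)))  # npix x N
  qa <- qr(A)
  B <- qr.coef(qa, t(Y))                                   # 3 x npix
  fitted <- A %*% B
  rms <- sqrt(colMeans((t(Y) - fitted)^2))
  shape <- function(v) matrix(v, d[1], d[2])
  s0 <- shape(B[1, ])
  valid <- s0 >= 0
  if (!is.null(stack$invalid))
    valid <- valid & !Reduce(`|`, stack$invalid)
  structure(list(s0 = s0, s1 = shape(B[2, ]), s2 = shape(B[3, ]),
                 residual_rms = shape(rms), valid = valid,
                 angles_deg = stack$angles_deg),
            class = "stokes_image")
}

#' @export
print.stokes_image <- function(x, ...) {
  cat(sprintf("Stokes image %d x %d px (%d analyzer angles)\n",
              nrow(x$s0), ncol(x$s0), length(x$angles_deg)))
  cat(sprintf("  S0 range [%.3g, %.3g]; %.1f%% valid; max residual RMS %.3g\n",
              min(x$s0), max(x$s0), 100 * mean(x$valid),
              max(x$residual_rms)))
  invisible(x)
}

new_polarization_maps <- function(aop_deg, dolp, valid) {
  structure(list(aop_deg = aop_deg, dolp = dolp, valid = valid),
            class = "polarization_maps")
}

#' Angle and degree of linear polarization maps
#'
#' Converts per-pixel Stokes parameters into the two quantities of
#' interest: the angle of polarization
#' \eqn{\phi = \tfrac12 \mathrm{atan2}(S_2, S_1)} mapped into
#' \[0, 180) degrees, and the degree of linear polarization
#' \eqn{d = \sqrt{S_1^2 + S_2^2} / S_0}, clipped to \[0, 1\]. The AoP is
#' numerically meaningless where little polarized signal exists, so the
#' validity mask additionally excludes pixels with \eqn{S_0 \le}
#' `s0_min` or \eqn{d <} `dolp_min`. Degenerate pixels are flagged, never
#' NaN-propagated.
#'
#' @param stokes a `stokes_image` from [estimate_stokes()].
#' @param dolp_min minimum DoLP for a pixel's AoP to count as defined
#'   (default 0.05).
#' @param s0_min minimum total intensity, counts (default 0; a sensible
#'   field choice is ~5x the dark-noise SD).
#' @return A `polarization_maps` object: matrices `aop_deg` (degrees in
#'   \[0, 180), NA where invalid), `dolp` (in \[0, 1\]), logical `valid`.
#' @export
compute_maps <- function(stokes, dolp_min = 0.05, s0_min = 0) {
  stopifnot(inherits(stokes, "stokes_image"))
  s0 <- stokes$s0
  pos <- s0 > max(s0_min, 0)
  dolp <- matrix(0, nrow(s0), ncol(s0))
  dolp[pos] <- sqrt(stokes$s1[pos]^2 + stokes$s2[pos]^2) / s0[pos]
  dolp <- pmin(pmax(dolp, 0), 1)
  valid <- stokes$valid & pos & dolp >= dolp_min
  aop <- (atan2(stokes$s2, stokes$s1) / 2 * 180 / pi) %% 180
  aop[!valid] <- NA_real_
  new_polarization_maps(aop, dolp, valid)
}

#' @export
print.polarization_maps <- function(x, ...) {
  cat(sprintf("Polarization maps %d x %d px: %.1f%% valid\n",
              nrow(x$dolp), ncol(x$dolp), 100 * mean(x$valid)))
  if (any(x$valid))
    cat(sprintf("  DoLP on valid pixels: mean %.3f, max %.3f\n",
                mean(x$dolp[x$valid]), max(x$dolp[x$valid])))
  invisible(x)
}

# axial circular mean of angles in degrees (period 180): angles are
# doubled, vector-averaged, halved
axial_mean_deg <- function(a) {
  r <- a * pi / 90                      # 2 * angle in radians
  (atan2(mean(sin(r)), mean(cos(r))) * 90 / pi) %% 180
}

# axial distance between two orientations, in [0, 90] degrees
axial_diff_deg <- function(a, b) {
  d <- abs(a - b) %% 180
  min(d, 180 - d)
}

#' Ring-wise summary of a polarization map
#'
#' Reduces the per-pixel maps over the inner-disc and outer-annulus
#' regions of a bull's-eye target: the axial circular mean AoP (angles
#' doubled, averaged, halved -- orientations have period 180 degrees),
#' the mean DoLP, the number of valid pixels, and the inter-ring AoP
#' difference as an axial distance in \[0, 90\] degrees. A difference of
#' 90 degrees is the "contrast" (perpendicular-rings) configuration; 0
#' the "plain" (parallel) one.
#'
#' @param maps a `polarization_maps` object.
#' @param pattern the [scene_pattern()] defining the ring geometry.
#' @return list with data frame `rings` (ring, aop_deg, dolp, n_pixels)
#'   and scalar `aop_difference_deg`.
#' @export
ring_summary <- function(maps, pattern) {
  stopifnot(inherits(maps, "polarization_maps"))
  m <- region_masks(pattern, dim(maps$dolp))
  one <- function(mask, name) {
    use <- mask & maps$valid
    if (!any(use)) stop("empty ring mask for ", name,
                        " ring (no valid pixels)")
    data.frame(ring = name,
               aop_deg = axial_mean_deg(maps$aop_deg[use]),
               dolp = mean(maps$dolp[use]),
               n_pixels = sum(use))
  }
  rings <- rbind(one(m$inner, "inner"), one(m$outer, "outer"))
  list(rings = rings,
       aop_difference_deg = axial_diff_deg(rings$aop_deg[1],
                                           rings$aop_deg[2]))
}

#' False-colour rendering of polarization maps
#'
#' Renders the maps the way polarization-imaging figures are usually
#' shown: `"aop"` maps the axial angle onto a cyclic hue wheel (0 and 180
#' degrees share a hue), `"dolp"` is a grayscale percentage-polarization
#' image, and `"aop_weighted"` colours by AoP with pixel brightness
#' weighted by DoLP, so unpolarized regions fade to black. Invalid pixels
#' are rendered black in all modes.
#'
#' @param maps a `polarization_maps` object.
#' @param mode `"aop_weighted"` (default), `"aop"`, or `"dolp"`.
#' @return numeric array height x width x 3, RGB in \[0, 1\].
#' @export
false_color <- function(maps, mode = c("aop_weighted", "aop", "dolp")) {
  mode <- match.arg(mode)
  h <- nrow(maps$dolp); w <- ncol(maps$dolp)
  valid <- maps$valid
  out <- array(0, c(h, w, 3))
  if (mode == "dolp") {
    for (k in 1:3) { p <- maps$dolp; p[!valid] <- 0; out[, , k] <- p }
    return(out)
  }
  hue <- (maps$aop_deg %% 180) / 180
  hue[!valid | is.na(hue)] <- 0
  val <- if (mode == "aop_weighted") maps$dolp else matrix(1, h, w)
  val[!valid] <- 0
  cols <- col2rgb(hsv(h = as.vector(hue), s = 1, v = as.vector(val))) / 255
  out[, , 1] <- cols[1, ]; out[, , 2] <- cols[2, ]; out[, , 3] <- cols[3, ]
  out
}

#' Colour-bar legend data for the AoP hue wheel
#'
#' @param n number of legend entries.
#' @return data frame with `aop_deg` and hex `color`, e.g. for drawing a
#'   colour scale next to a false-colour image.
#' @export
aop_color_legend <- function(n = 64) {
  a <- seq(0, 180, length.out = n + 1)[seq_len(n)]
  data.frame(aop_deg = a, color = hsv(a / 180, 1, 1))
}

#' @export
plot.polarization_maps <- function(x, mode = "aop_weighted", ...) {
  rgbimg <- false_color(x, mode)
  op <- par(mar = c(1, 1, 2, 1)); on.exit(par(op))
  plot(0, 0, type = "n", xlim = c(0, ncol(x$dolp)),
       ylim = c(0, nrow(x$dolp)), asp = 1, axes = FALSE, xlab = "",
       ylab = "", main = paste("polarization map:", mode), ...)
  graphics::rasterImage(grDevices::as.raster(rgbimg), 0, 0,
                        ncol(x$dolp), nrow(x$dolp))
  invisible(x)
}

#' Write Stokes and polarization maps as 32-bit TIFFs
#'
#' Each channel is affinely mapped into \[0, 1\] before writing (TIFF
#' float storage in the `tiff` package is defined only on that range);
#' the per-channel `offset` and `scale` needed to recover physical
#' values (`value = offset + scale * stored`) are written alongside as
#' `scales.csv`. `read_maps()` undoes the mapping.
#'
#' @param stokes a `stokes_image`.
#' @param maps a `polarization_maps`.
#' @param dir output directory.
#' @return invisibly, the vector of files written.
#' @export
write_maps <- function(stokes, maps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0); scales <- list()
  put <- function(img, name) {
    img[is.na(img)] <- 0
    lo <- min(img); hi <- max(img)
    scale <- if (hi > lo) hi - lo else 1
    f <- file.path(dir, paste0(name, ".tif"))
    tiff::writeTIFF((img - lo) / scale, f, bits.per.sample = 32L)
    scales[[length(scales) + 1L]] <<-
      data.frame(name = name, offset = lo, scale = scale)
    files <<- c(files, f)
  }
  put(stokes$s0, "s0"); put(stokes$s1, "s1"); put(stokes$s2, "s2")
  put(maps$aop_deg, "aop_deg"); put(maps$dolp, "dolp")
  write.csv(do.call(rbind, scales), file.path(dir, "scales.csv"),
            row.names = FALSE)
  invisible(files)
}

#' @rdname write_maps
#' @return `read_maps()`: named list of numeric matrices in physical
#'   units.
#' @export
read_maps <- function(dir) {
  sc <- read.csv(file.path(dir, "scales.csv"), stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(sc)), function(i)
    sc$offset[i] + sc$scale[i] *
      tiff::readTIFF(file.path(dir, paste0(sc$name[i], ".tif"))))
  names(out) <- sc$name
  out
}
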