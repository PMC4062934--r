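#' Describe a bull's-eye polarizer target
#'
#' A scene pattern is the ground-truth description of one artificial-flower
#' target: a polarizing inner disc and a concentric polarizing outer
#' annulus on an unpolarized background. Each region carries an angle of
#' polarization (AoP, degrees in \[0, 180)), a degree of linear
#' polarization (DoLP in \[0, 1\]) and a radiance in linear camera counts.
#' Optional per-ring intensity factors emulate neutral-density overlays
#' (the intensity-contrast target variants).
#'
#' The default geometry uses a 10 px/mm scale: the inner polarizer disc has
#' a 24 mm outer diameter (radius 120 px) and the outer polarizer annulus a
#' 38 mm outer diameter (radius 190 px), with a 1 px unpolarized gap
#' between the rings so the regions are disjoint.
#'
#' @param image_size integer length-2, image height and width in pixels.
#' @param center numeric length-2 pixel coordinates (row, col) of the
#'   bull's-eye center; default image center.
#' @param outer_ring list with `inner_radius_px`, `outer_radius_px`,
#'   `aop_deg`, `dolp`, `radiance`.
#' @param inner_ring list with `outer_radius_px`, `aop_deg`, `dolp`,
#'   `radiance`.
#' @param background list with `dolp` (must be 0) and `radiance`.
#' @param intensity_factors named numeric, multiplicative radiance factors
#'   for `outer` and `inner` rings (neutral-density emulation); default 1.
#' @return An object of class `scene_pattern`.
#' @seealso [make_target_pattern()] for the study's two target types.
#' @export
scene_pattern <- function(image_size = c(420L, 420L),
                          center = (image_size + 1) / 2,
                          outer_ring = list(inner_radius_px = 121,
                                            outer_radius_px = 190,
                                            aop_deg = 0, dolp = 1,
                                            radiance = 40000),
                          inner_ring = list(outer_radius_px = 120,
                                            aop_deg = 90, dolp = 1,
                                            radiance = 40000),
                          background = list(dolp = 0, radiance = 8000),
                          intensity_factors = c(outer = 1, inner = 1)) {
  p <- structure(list(image_size = as.integer(image_size),
                      center = as.numeric(center),
                      outer_ring = outer_ring, inner_ring = inner_ring,
                      background = background,
                      intensity_factors = intensity_factors),
                 class = "scene_pattern")
  validate_scene_pattern(p)
}

validate_scene_pattern <- function(p) {
  stopifnot(length(p$image_size) == 2L, all(p$image_size >= 1L),
            length(p$center) == 2L)
  ir <- p$inner_ring; or <- p$outer_ring
  if (!(ir$outer_radius_px > 0 && or$inner_radius_px > 0 &&
        or$outer_radius_px > 0))
    stop("ring radii must be positive")
  if (!(ir$outer_radius_px < or$inner_radius_px &&
        or$inner_radius_px <= or$outer_radius_px))
    stop("degenerate radii: rings must be nested (inner disc < outer annulus)")
  for (reg in list(ir, or)) {
    if (reg$dolp < 0 || reg$dolp > 1) stop("dolp must lie in [0, 1]")
    if (reg$aop_deg < 0 || reg$aop_deg >= 180)
      stop("aop_deg must lie in [0, 180)")
    if (reg$radiance <= 0) stop("radiance must be positive")
  }
  if (p$background$dolp != 0) stop("background must be unpolarized (dolp 0)")
  if (p$background$radiance <= 0) stop("radiance must be positive")
  if (any(p$intensity_factors <= 0)) stop("intensity factors must be positive")
  p
}

#' Build the study's "contrast" or "plain" bull's-eye target
#'
#' The behavioural experiments used two target types: "contrast" targets,
#' whose inner and outer polarizer rings transmit perpendicular angles of
#' polarization (inner AoP = outer AoP + 90 degrees, axially), and "plain"
#' targets, whose rings are oriented in the same direction. Contrast
#' targets were the rewarding stimulus, plain the aversive one.
#'
#' @param kind `"contrast"` or `"plain"`.
#' @param outer_aop_deg AoP of the outer ring in degrees; inner follows
#'   from `kind`. Default 0.
#' @param dolp degree of linear polarization of both rings; default 1
#'   (ideal polarizer film).
#' @param intensity_factors passed to [scene_pattern()]; use e.g.
#'   `dfic_intensity_factors()` for the intensity-contrast variants.
#' @param ... further arguments passed to [scene_pattern()]
#'   (geometry, radiances, image size).
#' @return A `scene_pattern`.
#' @examples
#' pat <- make_target_pattern("contrast")
#' pat$inner_ring$aop_deg  # 90: perpendicular to the outer ring
#' @export
make_target_pattern <- function(kind = c("contrast", "plain"),
                                outer_aop_deg = 0, dolp = 1,
                                intensity_factors = c(outer = 1, inner = 1),
                                ...) {
  kind <- match.arg(kind)
  outer_aop_deg <- outer_aop_deg %% 180
  inner_aop <- if (kind == "contrast") (outer_aop_deg + 90) %% 180
               else outer_aop_deg
  args <- list(...)
  or <- args$outer_ring %||% list(inner_radius_px = 121, outer_radius_px = 190,
                                  aop_deg = 0, dolp = 1, radiance = 40000)
  ir <- args$inner_ring %||% list(outer_radius_px = 120, aop_deg = 0,
                                  dolp = 1, radiance = 40000)
  or$aop_deg <- outer_aop_deg; or$dolp <- dolp
  ir$aop_deg <- inner_aop;     ir$dolp <- dolp
  args$outer_ring <- or; args$inner_ring <- ir
  args$intensity_factors <- intensity_factors
  pat <- do.call(scene_pattern, args)
  attr(pat, "kind") <- kind
  pat
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Neutral-density intensity factors for the four intensity-contrast
#' target conditions
#'
#' The intensity-contrast (DFIC) experiment overlaid 0.3 and 0.9
#' neutral-density rings on the polarizers, giving four conditions:
#' 1 contrast/darker outer, 2 contrast/lighter outer, 3 plain/darker
#' outer, 4 plain/lighter outer. A ND of density D transmits 10^-D.
#'
#' @param condition integer 1-4.
#' @return list with `kind` ("contrast" or "plain") and `intensity_factors`
#'   suitable for [make_target_pattern()].
#' @export
dfic_condition <- function(condition) {
  stopifnot(condition %in% 1:4)
  dark <- 10^-0.9; light <- 10^-0.3
  list(kind = if (condition <= 2) "contrast" else "plain",
       intensity_factors =
         if (condition %% 2 == 1) c(outer = dark, inner = light)
         else c(outer = light, inner = dark))
}

# Region membership by pixel-center distance from the bull's-eye center.
# The same rule is used by the renderer, the ground-truth maps and the
# ring summaries, so region definitions can never drift apart.
region_masks <- function(pattern, image_size = pattern$image_size,
                         center = pattern$center) {
  h <- image_size[1]; w <- image_size[2]
  r <- sqrt(outer((seq_len(h) - center[1])^2, (seq_len(w) - center[2])^2, "+"))
  inner <- r <= pattern$inner_ring$outer_radius_px
  outer_m <- r >= pattern$outer_ring$inner_radius_px &
             r <= pattern$outer_ring$outer_radius_px
  list(inner = inner, outer = outer_m, background = !(inner | outer_m))
}

#' Ground-truth polarization maps for a scene pattern
#'
#' Emits the per-pixel true AoP/DoLP implied by a [scene_pattern()], in
#' the same `polarization_maps` container the estimation pipeline
#' produces, for end-to-end accuracy checks. Background pixels carry
#' DoLP 0 and are flagged invalid for AoP (the angle is undefined for
#' unpolarized light).
#'
#' @param pattern a `scene_pattern`.
#' @param image_size optional override of the pattern's image size.
#' @return A `polarization_maps` object (fields `aop_deg`, `dolp`,
#'   `valid`).
#' @export
ground_truth_maps <- function(pattern, image_size = pattern$image_size) {
  m <- region_masks(pattern, image_size)
  h <- image_size[1]; w <- image_size[2]
  aop <- matrix(NA_real_, h, w); dolp <- matrix(0, h, w)
  aop[m$inner] <- pattern$inner_ring$aop_deg
  dolp[m$inner] <- pattern$inner_ring$dolp
  aop[m$outer] <- pattern$outer_ring$aop_deg
  dolp[m$outer] <- pattern$outer_ring$dolp
  new_polarization_maps(aop, dolp, valid = !m$background)
}

#' @export
print.scene_pattern <- function(x, ...) {
  kind <- attr(x, "kind")
  cat("Bull's-eye scene pattern",
      if (!is.null(kind)) sprintf("(%s target)", kind), "\n")
  cat(sprintf("  image %d x %d px, center (%.1f, %.1f)\n",
              x$image_size[1], x$image_size[2], x$center[1], x$center[2]))
  cat(sprintf("  inner disc:   r <= %g px, AoP %g deg, DoLP %g, radiance %g\n",
              x$inner_ring$outer_radius_px, x$inner_ring$aop_deg,
              x$inner_ring$dolp, x$inner_ring$radiance))
  cat(sprintf("  outer annulus: %g <= r <= %g px, AoP %g deg, DoLP %g, radiance %g\n",
              x$outer_ring$inner_radius_px, x$outer_ring$outer_radius_px,
              x$outer_ring$aop_deg, x$outer_ring$dolp, x$outer_ring$radiance))
  invisible(x)
}
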