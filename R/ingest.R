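#' Separate the four Bayer channels of a colour-filter-array mosaic
#'
#' A single-sensor colour camera samples colours through a 2x2 Bayer
#' colour-filter tile; the four sub-grids can be pulled apart into
#' half-resolution channels without any interpolation, preserving the raw
#' linear counts exactly. `split_bayer()` does that; `interleave_bayer()`
#' is its exact inverse.
#'
#' @param mosaic numeric matrix with even dimensions, linear counts.
#' @param layout Bayer tile order, one of `"RGGB"`, `"BGGR"`, `"GRBG"`,
#'   `"GBRG"`: the colours at tile positions (1,1), (1,2), (2,1), (2,2).
#' @return `split_bayer()`: a named list of four half-resolution matrices
#'   `R`, `G1`, `G2`, `B` (`G1` is the green sample earlier in
#'   reading order). `interleave_bayer()`: the re-assembled mosaic.
#' @export
split_bayer <- function(mosaic, layout = c("RGGB", "BGGR", "GRBG", "GBRG")) {
  layout <- match.arg(layout)
  d <- dim(mosaic)
  if (is.null(d) || d[1] %% 2L != 0L || d[2] %% 2L != 0L)
    stop("mosaic must be a matrix with even height and width")
  tiles <- list(mosaic[seq(1, d[1], 2), seq(1, d[2], 2), drop = FALSE],
                mosaic[seq(1, d[1], 2), seq(2, d[2], 2), drop = FALSE],
                mosaic[seq(2, d[1], 2), seq(1, d[2], 2), drop = FALSE],
                mosaic[seq(2, d[1], 2), seq(2, d[2], 2), drop = FALSE])
  names(tiles) <- bayer_channel_order(layout)
  tiles[c("R", "G1", "G2", "B")]
}

# channel name at tile positions (1,1),(1,2),(2,1),(2,2) for each layout;
# G1 is always the first green in reading order
bayer_channel_order <- function(layout) {
  switch(layout,
         RGGB = c("R", "G1", "G2", "B"),
         BGGR = c("B", "G1", "G2", "R"),
         GRBG = c("G1", "R", "B", "G2"),
         GBRG = c("G1", "B", "R", "G2"))
}

#' @rdname split_bayer
#' @param channels named list as returned by `split_bayer()`.
#' @export
interleave_bayer <- function(channels,
                             layout = c("RGGB", "BGGR", "GRBG", "GBRG")) {
  layout <- match.arg(layout)
  ord <- bayer_channel_order(layout)
  d <- dim(channels[[1]])
  mosaic <- matrix(0, 2L * d[1], 2L * d[2])
  idx <- list(c(1, 1), c(1, 2), c(2, 1), c(2, 2))
  for (k in 1:4) {
    off <- idx[[k]]
    mosaic[seq(off[1], 2 * d[1], 2), seq(off[2], 2 * d[2], 2)] <-
      channels[[ord[k]]]
  }
  mosaic
}

#' Select the working channel from a Bayer split
#'
#' Polarimetry proceeds on a single colour channel. `Gmean` averages the
#' two green samples of the tile.
#'
#' @param channels named list from [split_bayer()].
#' @param which one of `"R"`, `"G1"`, `"G2"`, `"B"`, `"Gmean"`.
#' @return The selected half-resolution image.
#' @export
select_channel <- function(channels,
                           which = c("G1", "R", "G2", "B", "Gmean")) {
  which <- match.arg(which)
  if (which == "Gmean") (channels$G1 + channels$G2) / 2
  else channels[[which]]
}

#' Subtract the dark frame from every frame of a stack
#'
#' Removes the sensor offset/thermal signal recorded with the lens capped.
#' Results are clamped at zero; pixels at full scale in the *raw* frame
#' are marked invalid (saturated counts carry no polarization
#' information and would bias the sinusoid fit).
#'
#' @param stack a [frame_stack()] with a dark frame.
#' @param no_dark set `TRUE` to explicitly process a stack without a dark
#'   frame (no implicit pass-through is allowed).
#' @return A `frame_stack` without dark frame and with per-frame invalid
#'   masks populated.
#' @export
dark_subtract <- function(stack, no_dark = FALSE) {
  stopifnot(inherits(stack, "frame_stack"))
  if (is.null(stack$dark) && !no_dark)
    stop("stack has no dark frame; pass no_dark = TRUE to skip subtraction")
  full <- 2^stack$bit_depth - 1
  invalid <- lapply(stack$frames, function(f) f >= full)
  frames <- if (is.null(stack$dark)) stack$frames
            else lapply(stack$frames, function(f) pmax(f - stack$dark, 0))
  if (!is.null(stack$invalid))
    invalid <- Map(`|`, invalid, stack$invalid)
  frame_stack(frames, stack$angles_deg, dark = NULL, invalid = invalid,
              bit_depth = stack$bit_depth)
}

# integer-pixel translation; exposed pixels become `fill`
translate_image <- function(img, dy, dx, fill = NA_real_) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(fill, h, w)
  sr <- max(1, 1 + dy):min(h, h + dy)   # destination rows
  sc <- max(1, 1 + dx):min(w, w + dx)
  if (length(sr) > 0 && length(sc) > 0)
    out[sr, sc] <- img[sr - dy, sc - dx]
  out
}

# cyclic gradient magnitude (wrap-around differences): exactly
# equivariant under cyclic translation, and insensitive to per-region
# brightness reversals between analyzer frames (region edges persist
# even when ring contrast flips as the analyzer rotates)
gradient_magnitude <- function(img) {
  h <- nrow(img); w <- ncol(img)
  # centred differences keep the edge response on the boundary pixel for
  # rising and falling edges alike
  gy <- (img[c(2:h, 1), ] - img[c(h, 1:(h - 1)), ]) / 2
  gx <- (img[, c(2:w, 1)] - img[, c(w, 1:(w - 1))]) / 2
  sqrt(gy^2 + gx^2)
}

# whole-pixel translation estimate by FFT cross-correlation of
# mean-subtracted cyclic gradient magnitudes; returns (dy, dx) such that
# translate_image(img, dy, dx) aligns img onto ref. Correlating edge
# strength rather than raw intensity keeps the peak at the true shift
# even when the analyzer rotation reverses ring contrast between frames;
# exact for integer shifts of content clear of the frame border.
cross_correlation_shift <- function(ref, img) {
  if (stats::sd(img) == 0 || stats::sd(ref) == 0)
    return(structure(c(0L, 0L), flagged = TRUE))
  gr <- gradient_magnitude(ref); gi <- gradient_magnitude(img)
  gr <- gr - mean(gr); gi <- gi - mean(gi)
  corr <- Re(stats::fft(stats::fft(gr) * Conj(stats::fft(gi)),
                        inverse = TRUE))
  pk <- arrayInd(which.max(corr), dim(corr))
  wrap <- function(k, n) { k <- k - 1L; if (k > n %/% 2) k - n else k }
  structure(c(wrap(pk[1], nrow(gr)), wrap(pk[2], ncol(gr))),
            flagged = FALSE)
}

#' Register an analyzer stack by translation
#'
#' Frames of a tripod-mounted sequence can drift by small translations
#' between exposures. Each non-reference frame's shift to the reference is
#' estimated by whole-pixel gradient cross-correlation and undone; pixels shifted
#' in from outside the field of view are marked invalid. All-constant
#' frames (undefined correlation) are flagged and left unshifted.
#'
#' @param stack a [frame_stack()].
#' @param reference_index frame used as the alignment reference.
#' @return list with `stack` (aligned `frame_stack`) and `shifts`
#'   (n x 2 integer matrix of applied (row, col) translations, reference
#'   row zero).
#' @export
register_stack <- function(stack, reference_index = 1L) {
  stopifnot(inherits(stack, "frame_stack"),
            length(stack$frames) >= 2L,
            reference_index %in% seq_along(stack$frames))
  ref <- stack$frames[[reference_index]]
  n <- length(stack$frames)
  shifts <- matrix(0L, n, 2, dimnames = list(NULL, c("dy", "dx")))
  frames <- stack$frames
  invalid <- stack$invalid %||%
    rep(list(matrix(FALSE, nrow(ref), ncol(ref))), n)
  flagged <- logical(n)
  for (k in seq_len(n)) {
    if (k == reference_index) next
    s <- cross_correlation_shift(ref, frames[[k]])
    flagged[k] <- attr(s, "flagged")
    shifts[k, ] <- s
    if (any(s != 0L)) {
      frames[[k]] <- translate_image(frames[[k]], s[1], s[2], fill = 0)
      moved <- translate_image(invalid[[k]] * 1, s[1], s[2], fill = 1)
      invalid[[k]] <- moved > 0
    }
  }
  out <- frame_stack(frames, stack$angles_deg, dark = stack$dark,
                     invalid = invalid, bit_depth = stack$bit_depth)
  list(stack = out, shifts = shifts, flagged = flagged)
}
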