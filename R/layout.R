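#' Trial layouts: 4x4 Latin squares of target conditions
#'
#' In the intensity-contrast experiment, sixteen targets -- four of each
#' of four conditions -- are arranged on a 4x4 grid forming a Latin
#' square (each condition exactly once per row and per column).
#'
#' @param grid 4x4 integer matrix of condition labels 1-4.
#' @return An object of class `trial_layout`.
#' @export
trial_layout <- function(grid) {
  grid <- matrix(as.integer(grid), 4, 4)
  if (!is_latin_square(grid))
    stop("grid is not a 4x4 Latin square of conditions 1-4")
  structure(grid, class = c("trial_layout", "matrix", "array"))
}

#' @rdname trial_layout
#' @export
is_latin_square <- function(grid) {
  if (!all(dim(grid) == c(4L, 4L)) || !all(grid %in% 1:4)) return(FALSE)
  all(apply(grid, 1, function(r) length(unique(r)) == 4L)) &&
    all(apply(grid, 2, function(c) length(unique(c)) == 4L))
}

# uniform-ish random 4x4 Latin square by row-wise rejection with restart
random_latin_square <- function() {
  repeat {
    g <- matrix(0L, 4, 4)
    g[1, ] <- sample.int(4)
    ok <- TRUE
    for (i in 2:4) {
      placed <- FALSE
      for (try in 1:50) {
        row <- sample.int(4)
        if (all(colSums(g[seq_len(i - 1), , drop = FALSE] ==
                        rep(row, each = i - 1)) == 0)) {
          g[i, ] <- row; placed <- TRUE; break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(g)
  }
}

#' Rearrange targets between foraging bouts under the study constraints
#'
#' While a forager is back at the nest the sixteen targets are shuffled
#' so that spatial learning of positions is disrupted: (1) no physical
#' target is in its previous place, (2) no place is occupied by a target
#' of the same condition as previously, and (3) the four conditions again
#' form a Latin square. The new layout is drawn by seeded rejection
#' sampling of random order-4 Latin squares until one is *discordant*
#' with the previous layout (different condition at every cell), which
#' enforces (2) and (3); each condition's four physical targets are then
#' assigned to that condition's four new cells by a random permutation.
#' Because the condition at every cell changed, no target can land on its
#' previous cell, so (1) holds for any such assignment. A discordant
#' Latin square always exists at order 4, so the sampler cannot stall.
#'
#' @param previous a [trial_layout()] (or 4x4 matrix) describing the
#'   current arrangement.
#' @param seed integer seed.
#' @return A `trial_layout` with attribute `assignments`: a data frame
#'   (condition, target, prev_row, prev_col, new_row, new_col) tracking
#'   each physical target, where `target` numbers the four targets of a
#'   condition in the previous layout's column-major cell order.
#' @export
shuffle_layout <- function(previous, seed = NULL) {
  if (!inherits(previous, "trial_layout")) previous <- trial_layout(previous)
  with_seed(seed, {
    repeat {
      g <- random_latin_square()
      if (all(g != unclass(previous))) break
    }
    rows <- lapply(1:4, function(cond) {
      prev_cells <- which(unclass(previous) == cond)   # column-major
      new_cells <- which(g == cond)[sample.int(4)]
      data.frame(condition = cond, target = 1:4,
                 prev_row = (prev_cells - 1L) %% 4L + 1L,
                 prev_col = (prev_cells - 1L) %/% 4L + 1L,
                 new_row = (new_cells - 1L) %% 4L + 1L,
                 new_col = (new_cells - 1L) %/% 4L + 1L)
    })
    out <- trial_layout(g)
    attr(out, "assignments") <- do.call(rbind, rows)
    out
  })
}

#' @export
print.trial_layout <- function(x, ...) {
  cat("4x4 trial layout (conditions 1-4, Latin square):\n")
  print(matrix(as.integer(x), 4, 4))
  invisible(x)
}

#' A default starting layout
#'
#' Cyclic order-4 Latin square used as the opening arrangement of an
#' intensity-contrast session; later arrangements come from
#' [shuffle_layout()].
#'
#' @return A `trial_layout`.
#' @export
default_layout <- function() {
  trial_layout(t(vapply(0:3, function(s) ((0:3 + s) %% 4L) + 1L,
                        integer(4))))
}
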