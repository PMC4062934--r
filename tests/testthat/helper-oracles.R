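# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: closed forms, brute-force search, exhaustive
# checking.

# Closed-form three-point Stokes solution from intensities at analyzer
# angles 0, 60, 120 degrees (rotating-analyzer textbook formulas).
three_point_stokes <- function(I0, I60, I120) {
  s0 <- 2 / 3 * (I0 + I60 + I120)
  s1 <- 2 * I0 - s0
  s2 <- 2 * (I60 - I120) / sqrt(3)
  list(s0 = s0, s1 = s1, s2 = s2)
}

# Exhaustive integer-shift search: the (dy, dx) within +/- `radius` whose
# application to `img` best matches `ref` (mean squared error on the
# overlap).
brute_force_shift <- function(ref, img, radius = 10) {
  best <- c(NA, NA); best_err <- Inf
  h <- nrow(ref); w <- ncol(ref)
  for (dy in -radius:radius) for (dx in -radius:radius) {
    rows <- max(1, 1 + dy):min(h, h + dy)
    cols <- max(1, 1 + dx):min(w, w + dx)
    err <- mean((img[rows - dy, cols - dx] - ref[rows, cols])^2)
    if (err < best_err) { best_err <- err; best <- c(dy, dx) }
  }
  best
}

# Brute-force axial (period-180) distance between two orientations.
axial_distance_oracle <- function(a, b) {
  d <- abs(a - b) %% 180
  min(d, 180 - d)
}

# Exhaustive checker of the three target-rearrangement constraints:
# (1) no physical target in its previous place, (2) no place holds the
# same condition as before, (3) the new grid is a Latin square.
check_shuffle_constraints <- function(previous, new) {
  prev <- matrix(as.integer(previous), 4, 4)
  grid <- matrix(as.integer(new), 4, 4)
  asg <- attr(new, "assignments")
  latin <- all(apply(grid, 1, function(r) setequal(r, 1:4))) &&
    all(apply(grid, 2, function(c) setequal(c, 1:4)))
  no_same_condition <- all(grid != prev)
  no_same_place <- !any(asg$new_row == asg$prev_row &
                          asg$new_col == asg$prev_col)
  each_four <- all(tabulate(grid, 4) == 4L)
  consistent <- all(vapply(seq_len(nrow(asg)), function(i) {
    grid[asg$new_row[i], asg$new_col[i]] == asg$condition[i] &&
      prev[asg$prev_row[i], asg$prev_col[i]] == asg$condition[i]
  }, logical(1)))
  latin && no_same_condition && no_same_place && each_four && consistent
}

# Marginal probability of a correct choice at scaled experience x under
# the random-effects logistic model, by 2D Gauss-Hermite quadrature
# (independent of the package's simulator and fitter).
marginal_correct_prob <- function(x, beta0, beta1, sigma_b, sigma_s,
                                  n_nodes = 41) {
  gh <- function(n) { # Golub-Welsch via eigen of the Jacobi matrix
    i <- seq_len(n - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
    e <- eigen(J, symmetric = TRUE)
    list(nodes = e$values, weights = e$vectors[1, ]^2 * sqrt(pi))
  }
  g <- gh(n_nodes)
  b <- sqrt(2) * sigma_b * g$nodes
  s <- sqrt(2) * sigma_s * g$nodes
  wb <- g$weights / sqrt(pi); ws <- g$weights / sqrt(pi)
  p <- outer(beta0 + b, (beta1 + s) * x, "+")
  sum(wb * (plogis(p) %*% ws))
}

# A fixed non-trivial Latin square used as a shuffle starting point.
fixed_latin_square <- function() {
  petalpol::trial_layout(matrix(c(1, 2, 3, 4,
                                  2, 1, 4, 3,
                                  3, 4, 1, 2,
                                  4, 3, 2, 1), 4, 4, byrow = TRUE))
}
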