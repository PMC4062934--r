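#' Simulate differential-conditioning choice sequences
#'
#' Generates per-bee binary choice records under a random-effects
#' logistic learning model. Bee `i`'s probability of a correct choice at
#' trial `t` is
#' \deqn{P(y_{it} = 1) = \mathrm{logit}^{-1}\!\big((\beta_0 + b_i) +
#'   (\beta_1 + s_i)\, x_t\big)}
#' with independent subject effects \eqn{b_i \sim N(0, \sigma_b^2)}
#' (ability) and \eqn{s_i \sim N(0, \sigma_s^2)} (rate of acquisition),
#' and experience coded as \eqn{x_t = (t-1)/(T-1) \in [0,1]}. The
#' defaults describe a learnable task at chance-level start
#' (\eqn{\beta_0 = 0}) reaching ~75% end-of-session accuracy
#' (\eqn{\beta_1 = \mathrm{logit}(0.75)}) with moderate between-bee
#' heterogeneity, over the protocol's 100 recorded choices per bee.
#'
#' For intensity-contrast sessions (`conditions` given), each trial also
#' carries the condition label of the chosen flower. With four targets of
#' every condition present in each (Latin-square) arrangement and
#' correctness independent of the intensity overlay, the chosen flower's
#' label is uniform over the levels, which is how it is drawn.
#' `condition_beta` adds per-level experience-slope offsets to build
#' non-null interaction scenarios.
#'
#' @param n_bees number of foragers.
#' @param n_trials choices recorded per bee (default 100).
#' @param beta0 fixed intercept (log-odds of a correct first choice).
#' @param beta1 fixed experience slope (log-odds gain over the session).
#' @param sigma_b SD of the per-bee intercept deviation (>= 0).
#' @param sigma_s SD of the per-bee slope deviation (>= 0).
#' @param conditions optional character/integer vector of condition
#'   labels to draw per trial (e.g. `c("darker", "lighter")`).
#' @param condition_beta optional named numeric, per-condition offset
#'   added to the experience slope (names matching `conditions`);
#'   default all zero.
#' @param treatment tag stored on the table (e.g. "DF1", "DFIC",
#'   "synthetic").
#' @param seed integer seed.
#' @return A `choice_table`: data frame with columns `bee_id`, `trial`,
#'   `condition`, `correct`, plus attributes `treatment` and `truth`
#'   (the generating parameters).
#' @examples
#' tab <- simulate_choices(n_bees = 9, seed = 1)
#' head(tab)
#' @export
simulate_choices <- function(n_bees = 9, n_trials = 100,
                             beta0 = 0, beta1 = qlogis(0.75),
                             sigma_b = 0.5, sigma_s = 0.5,
                             conditions = NULL, condition_beta = NULL,
                             treatment = "synthetic", seed = NULL) {
  stopifnot(n_bees >= 1, n_trials >= 1)
  if (sigma_b < 0 || sigma_s < 0)
    stop("variance components must be non-negative")
  with_seed(seed, {
    xt <- if (n_trials == 1) 0 else (seq_len(n_trials) - 1) / (n_trials - 1)
    rows <- lapply(seq_len(n_bees), function(i) {
      b <- rnorm(1, 0, sigma_b); s <- rnorm(1, 0, sigma_s)
      cond <- if (is.null(conditions)) rep(NA_character_, n_trials)
              else as.character(sample(conditions, n_trials, replace = TRUE))
      slope_off <- if (is.null(condition_beta)) 0
                   else unname(condition_beta[cond])
      slope_off[is.na(slope_off)] <- 0
      p <- plogis((beta0 + b) + (beta1 + s + slope_off) * xt)
      data.frame(bee_id = sprintf("bee%02d", i), trial = seq_len(n_trials),
                 condition = cond, correct = rbinom(n_trials, 1, p))
    })
    out <- do.call(rbind, rows)
    structure(out, treatment = treatment,
              truth = list(beta0 = beta0, beta1 = beta1,
                           sigma_b = sigma_b, sigma_s = sigma_s),
              class = c("choice_table", "data.frame"))
  })
}

# validate the minimal choice-table contract shared by the fitting code
validate_choice_table <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("bee_id", "trial", "correct") %in% names(table)))
  if (!all(table$correct %in% c(0L, 1L)))
    stop("`correct` must be binary 0/1")
  split_trials <- split(table$trial, table$bee_id)
  contiguous <- vapply(split_trials, function(tr)
    all(sort(tr) == seq_along(tr)), logical(1))
  if (!all(contiguous))
    stop("trial indices must be contiguous 1..T within each bee")
  invisible(table)
}

#' Read / write choice tables as CSV
#'
#' The on-disk form has columns `bee_id`, `trial`, `condition`,
#' `correct` (0/1).
#'
#' @param table a choice table data frame.
#' @param file path to a CSV file.
#' @return `read_choices()`: a `choice_table` data frame.
#' @export
write_choices <- function(table, file) {
  validate_choice_table(table)
  cols <- intersect(c("bee_id", "trial", "condition", "correct"),
                    names(table))
  write.csv(table[, cols], file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_choices
#' @export
read_choices <- function(file) {
  out <- read.csv(file, stringsAsFactors = FALSE)
  validate_choice_table(out)
  class(out) <- c("choice_table", "data.frame")
  out
}

#' Binned learning curve with Wilson confidence intervals
#'
#' Pools choices across bees within consecutive trial bins and reports
#' the proportion correct with a 95% Wilson score interval per bin --
#' the standard display of acquisition over a conditioning session.
#'
#' @param table a choice table (see [simulate_choices()]).
#' @param bin_size trials per bin (the last bin may be partial).
#' @param conf confidence level (default 0.95).
#' @return data frame with `bin`, `trial_mid`, `n`, `k`, `proportion`,
#'   `lower`, `upper`.
#' @export
learning_curve <- function(table, bin_size = 10, conf = 0.95) {
  validate_choice_table(table)
  if (nrow(table) == 0) stop("empty choice table")
  stopifnot(bin_size >= 1)
  bin <- (table$trial - 1) %/% bin_size + 1
  k <- tapply(table$correct, bin, sum)
  n <- tapply(table$correct, bin, length)
  mid <- tapply(table$trial, bin, function(tr) mean(range(tr)))
  ci <- wilson_interval(as.numeric(k), as.numeric(n), conf)
  data.frame(bin = as.integer(names(k)), trial_mid = as.numeric(mid),
             n = as.numeric(n), k = as.numeric(k),
             proportion = as.numeric(k) / as.numeric(n),
             lower = ci$lower, upper = ci$upper, row.names = NULL)
}

# Wilson score interval for a binomial proportion
wilson_interval <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(lower = pmax(center - half, 0), upper = pmin(center + half, 1))
}
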