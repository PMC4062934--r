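#' Fit a random-effects logistic learning-curve model
#'
#' Models per-trial binary choices of freely foraging bees as
#' \deqn{\mathrm{logit}\, P(y_{it} = 1) = x_{it}'\beta + b_i + s_i t_{it}}
#' with independent per-bee deviations \eqn{b_i \sim N(0, \sigma_b^2)}
#' (ability) and, optionally, \eqn{s_i \sim N(0, \sigma_s^2)} (rate of
#' acquisition), capturing the strong between-subject heterogeneity of
#' conditioning data. Experience is coded \eqn{t_{it} = (trial-1)/(T-1)
#' \in [0,1]}.
#'
#' Because subjects are independent, the marginal likelihood factorizes
#' into one- or two-dimensional integrals per bee, each approximated by
#' Laplace's method at the per-bee posterior mode (damped Newton, in
#' compiled code); the approximate marginal likelihood is then maximized
#' over \eqn{(\beta, \log\sigma_b, \log\sigma_s)} with `L-BFGS-B`. The
#' fit is deterministic given the data and starting values (ordinary
#' logistic regression for \eqn{\beta}). Deviance is \eqn{-2} times the
#' maximized approximate log-likelihood, and
#' `AIC = deviance + 2 * n_params` where `n_params` counts fixed effects
#' plus variance components.
#'
#' @param table a choice table (see [simulate_choices()] /
#'   [read_choices()]): columns `bee_id`, `trial`, `correct`, and
#'   `condition` for the condition specs.
#' @param spec fixed-effects structure: `"experience"` (intercept +
#'   experience slope), `"null"` (intercept only; random effects are
#'   retained), `"experience_condition"` (+ condition main effect), or
#'   `"experience_x_condition"` (+ condition main effect and
#'   condition-by-experience interaction).
#' @param random `"intercept_slope"` (default) for independent random
#'   intercept and experience slope, `"intercept"` for random intercept
#'   only.
#' @param start optional starting values `c(beta, log sigma)`.
#' @param control list passed to [stats::optim()]'s `control`.
#' @return An object of class `learning_fit` with components
#'   `coefficients` (fixed effects), `sigma` (random-effect SDs),
#'   `deviance`, `aic`, `n_params`, `converged`, `vcov`
#'   (fixed+variance parameter covariance, log-sigma scale), `ranef`
#'   (per-bee posterior modes), `spec`, `random`, and the model frame.
#'   Methods: `print`, `summary`, `coef`, `logLik`, `predict`,
#'   `fitted`, `residuals`, `simulate`, `plot`, `anova`.
#' @seealso [compare_nested()], [experience_test()],
#'   [interaction_test()].
#' @examples
#' tab <- simulate_choices(n_bees = 9, seed = 42)
#' fit <- fit_learning_model(tab, "experience")
#' fit
#' @export
fit_learning_model <- function(table,
                               spec = c("experience", "null",
                                        "experience_condition",
                                        "experience_x_condition"),
                               random = c("intercept_slope", "intercept"),
                               start = NULL, control = list()) {
  spec <- match.arg(spec)
  random <- match.arg(random)
  validate_choice_table(table)
  if (length(unique(table$bee_id)) < 2L)
    stop("variance components need at least 2 bees")
  tab <- table[order(table$bee_id, table$trial), , drop = FALSE]
  tmax <- stats::ave(tab$trial, tab$bee_id, FUN = max)
  xt <- ifelse(tmax > 1, (tab$trial - 1) / (tmax - 1), 0)
  mf <- data.frame(y = as.integer(tab$correct), experience = xt,
                   bee = factor(tab$bee_id))
  if (spec %in% c("experience_condition", "experience_x_condition")) {
    if (!"condition" %in% names(tab) || all(is.na(tab$condition)))
      stop("spec '", spec, "' needs a condition column")
    mf$condition <- factor(tab$condition)
    if (nlevels(mf$condition) < 2L)
      stop("condition must have at least 2 levels")
  }
  X <- switch(spec,
    null = matrix(1, nrow(mf), 1, dimnames = list(NULL, "(Intercept)")),
    experience = stats::model.matrix(~ experience, mf),
    experience_condition = stats::model.matrix(~ experience + condition, mf),
    experience_x_condition =
      stats::model.matrix(~ experience * condition, mf))
  q <- if (random == "intercept_slope") 2L else 1L
  p <- ncol(X)
  bee0 <- as.integer(mf$bee) - 1L
  if (is.null(start)) {
    g0 <- suppressWarnings(stats::glm.fit(X, mf$y, family = binomial()))
    start <- c(coef(g0), rep(log(0.5), q))
  }
  fn <- function(par) laplace_nll_cpp(par, X, mf$y, bee0, mf$experience, q)
  ctrl <- utils::modifyList(list(maxit = 500L), control)
  opt <- optim(start, fn, method = "L-BFGS-B",
               lower = c(rep(-Inf, p), rep(log(1e-3), q)),
               upper = c(rep(Inf, p), rep(log(20), q)), control = ctrl)
  if (opt$convergence != 0L)
    warning("learning model did not converge (optim code ",
            opt$convergence, "): ", opt$message)
  est <- opt$par
  vc <- tryCatch({
    H <- stats::optimHess(est, fn)
    solve(H)
  }, error = function(e) matrix(NA_real_, p + q, p + q))
  sig <- exp(est[(p + 1):(p + q)])
  names(sig) <- c("intercept", "slope")[seq_len(q)]
  deviance <- 2 * opt$value
  n_params <- p + q
  modes <- laplace_modes_cpp(est, X, mf$y, bee0, mf$experience, q)
  rownames(modes) <- levels(mf$bee)
  colnames(modes) <- c("intercept", "slope")[seq_len(q)]
  beta <- est[seq_len(p)]
  names(beta) <- colnames(X)
  pn <- c(colnames(X), paste0("log_sigma_", names(sig)))
  dimnames(vc) <- list(pn, pn)
  structure(list(coefficients = beta, sigma = sig, deviance = deviance,
                 aic = deviance + 2 * n_params, n_params = n_params,
                 converged = opt$convergence == 0L, vcov = vc,
                 ranef = modes, spec = spec, random = random,
                 model = mf, X = X, nobs = nrow(mf),
                 n_bees = nlevels(mf$bee), call = match.call()),
            class = "learning_fit")
}

#' @export
print.learning_fit <- function(x, ...) {
  cat("Random-effects logistic learning model (Laplace)\n")
  cat(sprintf("  spec: %s;  random: %s;  %d bees, %d choices\n",
              x$spec, x$random, x$n_bees, x$nobs))
  cat("  fixed effects:\n")
  print(round(x$coefficients, 4))
  cat("  random-effect SDs:",
      paste(sprintf("%s %.3f", names(x$sigma), x$sigma), collapse = ", "),
      "\n")
  cat(sprintf("  deviance %.2f, AIC %.2f (%d parameters)%s\n",
              x$deviance, x$aic, x$n_params,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
coef.learning_fit <- function(object, ...) object$coefficients

#' @export
logLik.learning_fit <- function(object, ...) {
  structure(-object$deviance / 2, df = object$n_params,
            nobs = object$nobs, class = "logLik")
}

#' @export
vcov.learning_fit <- function(object, ...) object$vcov

#' @export
summary.learning_fit <- function(object, ...) {
  p <- length(object$coefficients)
  se <- sqrt(diag(object$vcov))[seq_len(p)]
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(fit = object, coefficients = tab)
  class(out) <- "summary.learning_fit"
  out
}

#' @export
print.summary.learning_fit <- function(x, ...) {
  print(x$fit)
  cat("\nFixed-effect tests (Wald):\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
predict.learning_fit <- function(object, newdata = NULL,
                                 type = c("response", "link"),
                                 re.form = c("conditional", "population"),
                                 ...) {
  type <- match.arg(type)
  re.form <- match.arg(re.form)
  if (is.null(newdata)) {
    X <- object$X; mf <- object$model
  } else {
    mf <- newdata
    if (!"experience" %in% names(mf))
      stop("newdata needs an `experience` column in [0,1]")
    if ("condition" %in% names(object$model))
      mf$condition <- factor(mf$condition,
                             levels = levels(object$model$condition))
    X <- switch(object$spec,
      null = matrix(1, nrow(mf), 1),
      experience = stats::model.matrix(~ experience, mf),
      experience_condition =
        stats::model.matrix(~ experience + condition, mf),
      experience_x_condition =
        stats::model.matrix(~ experience * condition, mf))
  }
  eta <- drop(X %*% object$coefficients)
  if (re.form == "conditional") {
    if (!"bee" %in% names(mf))
      stop("conditional prediction needs a `bee` column")
    bi <- match(as.character(mf$bee), rownames(object$ranef))
    if (anyNA(bi)) stop("unknown bee in newdata; use re.form='population'")
    eta <- eta + object$ranef[bi, 1]
    if (ncol(object$ranef) == 2L)
      eta <- eta + object$ranef[bi, 2] * mf$experience
  }
  if (type == "response") plogis(eta) else eta
}

#' @export
fitted.learning_fit <- function(object, ...) predict(object)

#' @export
residuals.learning_fit <- function(object,
                                   type = c("deviance", "pearson",
                                            "response"), ...) {
  type <- match.arg(type)
  y <- object$model$y
  mu <- fitted(object)
  switch(type,
         response = y - mu,
         pearson = (y - mu) / sqrt(mu * (1 - mu)),
         deviance = sign(y - mu) *
           sqrt(-2 * (y * log(mu) + (1 - y) * log(1 - mu))))
}

#' @export
simulate.learning_fit <- function(object, nsim = 1, seed = NULL, ...) {
  n_trials <- max(table(object$model$bee))
  b0 <- unname(object$coefficients["(Intercept)"])
  b1 <- if ("experience" %in% names(object$coefficients))
    unname(object$coefficients["experience"]) else 0
  sb <- unname(object$sigma["intercept"])
  ss <- if ("slope" %in% names(object$sigma))
    unname(object$sigma["slope"]) else 0
  with_seed(seed, lapply(seq_len(nsim), function(k)
    simulate_choices(n_bees = object$n_bees, n_trials = n_trials,
                     beta0 = b0, beta1 = b1, sigma_b = sb, sigma_s = ss)))
}

#' @export
plot.learning_fit <- function(x, bin_size = 10, ...) {
  tab <- data.frame(bee_id = x$model$bee,
                    trial = stats::ave(seq_len(x$nobs), x$model$bee,
                                       FUN = seq_along),
                    correct = x$model$y)
  lc <- learning_curve(tab, bin_size)
  plot(lc$trial_mid, lc$proportion, ylim = c(0, 1), pch = 19,
       xlab = "trial", ylab = "proportion correct",
       main = "learning curve", ...)
  segments(lc$trial_mid, lc$lower, lc$trial_mid, lc$upper)
  if ("experience" %in% names(x$coefficients)) {
    xx <- seq(0, 1, length.out = 101)
    tr <- seq(min(lc$trial_mid), max(lc$trial_mid), length.out = 101)
    lines(tr, plogis(x$coefficients["(Intercept)"] +
                       x$coefficients["experience"] * xx), col = 2)
  }
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}

#' @export
anova.learning_fit <- function(object, ...) {
  others <- Filter(function(o) inherits(o, "learning_fit"), list(...))
  if (length(others) != 1L)
    stop("anova needs exactly two learning_fit objects")
  other <- others[[1]]
  if (object$n_params < other$n_params) compare_nested(other, object)
  else compare_nested(object, other)
}
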