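#' Proportional-odds model of compensation class
#'
#' Cumulative-logit maximum likelihood for an ordered outcome
#' \eqn{P(Y \le k) = \mathrm{logit}^{-1}(\zeta_k - \beta x)} with a single
#' predictor. A positive \eqn{\beta} moves probability mass toward higher
#' outcome levels as `x` grows. For compensation, the outcome ordering is
#' `non < perfect < partial < full` (increasing behavioral adjustment)
#' and the predictor is the absolute start mismatch, so \eqn{\beta > 0}
#' means more-mismatched animals are more likely to fully compensate.
#' Cutpoints are optimized on a log-difference scale to keep them
#' strictly increasing; the 95% CI is Wald, from the numerical Hessian.
#'
#' @param y ordered factor (or factor whose level order is the outcome
#'   order); levels absent from the data are dropped (at least 2 must
#'   remain).
#' @param x numeric predictor.
#' @return an `ordinal_fit`: list with `beta`, `se`, `ci95`, `cutpoints`,
#'   `loglik`, `levels`, `n`, `separation` (TRUE when the likelihood
#'   diverges, e.g. complete separation).
#' @export
fit_ordinal <- function(y, x) {
  y <- droplevels(factor(y, ordered = TRUE))
  stopifnot(length(y) == length(x), nlevels(y) >= 2, all(is.finite(x)))
  K <- nlevels(y)
  yi <- as.integer(y)

  # parameters: beta, zeta_1, log(diff zeta_2..K-1)
  to_zeta <- function(par) cumsum(c(par[2], exp(par[-(1:2)])))
  nll <- function(par) {
    zeta <- to_zeta(par)
    eta <- par[1] * x
    upper <- c(zeta, Inf)[yi]
    lower <- c(-Inf, zeta)[yi]
    p <- stats::plogis(upper - eta) - stats::plogis(lower - eta)
    -sum(log(pmax(p, 1e-300)))
  }
  cum <- cumsum(table(yi)) / length(yi)
  zeta0 <- stats::qlogis(pmin(pmax(cum[-K], 0.02), 0.98))
  par0 <- unname(c(0, zeta0[1], if (K > 2) log(pmax(diff(zeta0), 0.1))))
  opt <- stats::optim(par0, nll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  beta <- opt$par[1]
  separation <- abs(beta) > 30
  if (separation)
    warning("diverging coefficient: possible complete separation",
            call. = FALSE)
  se <- tryCatch({
    v <- solve(opt$hessian)[1, 1]
    if (v > 0) sqrt(v) else NA_real_
  }, error = function(e) NA_real_)
  structure(list(beta = beta, se = se,
                 ci95 = beta + c(-1, 1) * stats::qnorm(0.975) * se,
                 cutpoints = to_zeta(opt$par), loglik = -opt$value,
                 levels = levels(y), n = length(y),
                 separation = separation),
            class = "ordinal_fit")
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat(sprintf(
    "<ordinal_fit> beta=%.3f (95%% CI %.3f-%.3f), OR=%.2f, logLik=%.1f, n=%d\n",
    x$beta, x$ci95[1], x$ci95[2], exp(x$beta), x$loglik, x$n))
  invisible(x)
}

#' Per-class predicted probabilities from a proportional-odds fit
#'
#' @param fit an `ordinal_fit`.
#' @param x predictor values.
#' @return matrix (length(x) rows, one column per outcome level); rows
#'   sum to 1.
#' @export
predict_ordinal <- function(fit, x) {
  K <- length(fit$levels)
  cum <- vapply(fit$cutpoints, function(z) stats::plogis(z - fit$beta * x),
                numeric(length(x)))
  cum <- cbind(matrix(cum, nrow = length(x)), 1)
  p <- cbind(cum[, 1], t(apply(cum, 1, diff)))
  colnames(p) <- fit$levels
  p
}

#' Odds ratio per unit predictor
#'
#' Exponentiates the proportional-odds coefficient (and its CI): the
#' multiplicative change in the odds of a higher outcome class per unit
#' increase in the predictor.
#'
#' @param fit an `ordinal_fit`, or a bare coefficient.
#' @return the odds ratio; for a fit, with attribute `ci95`.
#' @export
odds_ratio <- function(fit) {
  if (inherits(fit, "ordinal_fit")) {
    structure(exp(fit$beta), ci95 = exp(fit$ci95))
  } else {
    exp(as.numeric(fit))
  }
}
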