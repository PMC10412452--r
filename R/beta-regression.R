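#' Smithson-Verkuilen boundary transform
#'
#' Squeezes proportions off the [0, 1] boundary: `(y * (n - 1) + 0.5) / n`,
#' with `n` the sample size of the dataset entering the regression.
#'
#' @param y Proportions in [0, 1].
#' @param n Sample size (>= 1).
#' @return Values strictly inside (0, 1).
#' @export
sv_transform <- function(y, n) {
  if (length(n) != 1 || n < 1) stop("n must be a single value >= 1")
  if (any(y < 0 | y > 1, na.rm = TRUE)) stop("proportions must be in [0, 1]")
  (y * (n - 1) + 0.5) / n
}

# negative log-likelihood and gradient of a beta regression with logit link
# and constant precision; theta = (coefs, log phi)
betareg_nll <- function(theta, X, y) {
  p <- ncol(X)
  eta <- as.numeric(X %*% theta[seq_len(p)])
  mu <- plogis(eta)
  phi <- exp(theta[p + 1])
  a <- mu * phi; b <- (1 - mu) * phi
  -sum(dbeta(y, a, b, log = TRUE))
}

betareg_grad <- function(theta, X, y) {
  p <- ncol(X)
  eta <- as.numeric(X %*% theta[seq_len(p)])
  mu <- plogis(eta)
  phi <- exp(theta[p + 1])
  a <- mu * phi; b <- (1 - mu) * phi
  ystar <- qlogis(y)          # log(y) - log(1-y)
  mustar <- digamma(a) - digamma(b)
  dmu <- phi * (ystar - mustar)              # dll/deta via dmu/deta
  dl_deta <- dmu * mu * (1 - mu)
  dl_dphi <- mu * (ystar - mustar) + digamma(phi) - digamma(b) + log(1 - y)
  c(-as.numeric(t(X) %*% dl_deta), -sum(dl_dphi) * phi)
}

#' Beta regression of traded proportions on realm
#'
#' Maximum-likelihood beta regression with a logit link for the mean and a
#' constant precision, fitted by quasi-Newton optimization from a
#' method-of-moments start. Intended for per-cell proportions of a diversity
#' metric subject to trade with biogeographical realm as the sole fixed
#' effect, but accepts any single factor (or intercept-only) design.
#'
#' @param y Response proportions strictly inside (0, 1) (apply
#'   [sv_transform()] first if boundary values occur).
#' @param realm Factor (or coercible) of group labels; `NULL` fits an
#'   intercept-only model.
#' @param gradtol Convergence tolerance on the gradient norm.
#' @return An object of class `betareg_fit` with coefficients on the logit
#'   scale, precision `phi`, `logLik`, `vcov`, fitted realm means.
#' @export
betareg_fit <- function(y, realm = NULL, gradtol = 1e-6) {
  if (any(y <= 0 | y >= 1)) stop("responses must be strictly inside (0, 1)")
  if (is.null(realm)) {
    X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
    realm_f <- NULL
  } else {
    realm_f <- factor(realm)
    if (any(table(realm_f) < 2)) stop("every realm needs at least 2 cells")
    X <- model.matrix(~realm_f)
    colnames(X) <- c("(Intercept)", paste0("realm", levels(realm_f)[-1]))
  }
  p <- ncol(X)
  # start: logit of group means; phi from the mean-variance relation
  mu0 <- ave(y, if (is.null(realm_f)) rep(1, length(y)) else realm_f)
  v <- max(var(y - mu0), 1e-6)
  phi0 <- max(mean(mu0 * (1 - mu0)) / v - 1, 1)
  beta0 <- qr.solve(X, qlogis(pmin(pmax(mu0, 1e-4), 1 - 1e-4)))
  theta0 <- c(beta0, log(phi0))
  opt <- optim(theta0, betareg_nll, betareg_grad, X = X, y = y,
               method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
  # Newton polish to push the gradient norm below tolerance
  par <- opt$par
  H <- NULL
  for (i in seq_len(20)) {
    g <- betareg_grad(par, X, y)
    if (sqrt(sum(g^2)) < gradtol * max(1, abs(opt$value))) break
    H <- stats::optimHess(par, betareg_nll, betareg_grad, X = X, y = y)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    cand <- par - step
    if (betareg_nll(cand, X, y) <= betareg_nll(par, X, y) + 1e-8) par <- cand
    else break
  }
  g <- betareg_grad(par, X, y)
  if (sqrt(sum(g^2)) > 1e3 * gradtol * max(1, abs(opt$value)))
    stop("beta regression did not converge; |gradient| = ",
         signif(sqrt(sum(g^2)), 3))
  if (is.null(H))
    H <- stats::optimHess(par, betareg_nll, betareg_grad, X = X, y = y)
  opt$par <- par
  opt$value <- betareg_nll(par, X, y)
  vc <- tryCatch(solve(H), error = function(e)
    stop("singular Hessian (separation?): ", conditionMessage(e)))
  coefs <- setNames(opt$par[seq_len(p)], colnames(X))
  lv <- if (is.null(realm_f)) NULL else levels(realm_f)
  mu_realm <- if (is.null(realm_f)) plogis(coefs[1]) else
    plogis(coefs[1] + c(0, coefs[-1]))
  if (!is.null(lv)) names(mu_realm) <- lv
  structure(list(coefficients = coefs, phi = unname(exp(opt$par[p + 1])),
                 logLik = -opt$value, vcov = vc[seq_len(p), seq_len(p),
                                                drop = FALSE],
                 realm_means = mu_realm, levels = lv, n = length(y),
                 df = p + 1, y = y, realm = realm_f),
            class = "betareg_fit")
}

#' @export
print.betareg_fit <- function(x, ...) {
  cat("Beta regression (logit link, constant precision)\n")
  cat("  n =", x$n, " logLik =", format(x$logLik, digits = 6),
      " phi =", format(x$phi, digits = 4), "\n")
  cat("  realm means:\n")
  print(round(x$realm_means, 4))
  invisible(x)
}

#' @export
coef.betareg_fit <- function(object, ...) object$coefficients

#' @export
vcov.betareg_fit <- function(object, ...) object$vcov

#' @export
logLik.betareg_fit <- function(object, ...) {
  structure(object$logLik, df = object$df, class = "logLik")
}

#' Likelihood-ratio test between nested beta regressions
#'
#' @param full,null Two [betareg_fit()] objects on identical data, the null
#'   nested in the full model.
#' @return A list with `statistic` (`2 * (lnL_full - lnL_null)`), `df`
#'   (parameter difference) and `p_value` from the chi-square distribution.
#' @export
lrt <- function(full, null) {
  if (full$n != null$n) stop("models were not fitted to the same data")
  if (full$df < null$df) stop("the first model must be the larger one")
  stat <- max(0, 2 * (full$logLik - null$logLik))
  df <- full$df - null$df
  list(statistic = stat, df = df,
       p_value = if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE))
}

#' Tukey-style pairwise realm contrasts
#'
#' All pairwise realm differences on the logit scale, with standard errors
#' from the fit covariance and single-step familywise adjustment using the
#' joint multivariate-normal distribution of the contrast statistics
#' (Holm adjustment available as a fallback).
#'
#' @param fit A [betareg_fit()] with at least 3 realms.
#' @param adjust `"single-step"` (default) or `"holm"`.
#' @return A data.frame with one row per realm pair: estimate, standard
#'   error, z value, adjusted p value.
#' @export
pairwise_contrasts <- function(fit, adjust = c("single-step", "holm")) {
  adjust <- match.arg(adjust)
  if (is.null(fit$levels) || length(fit$levels) < 3)
    stop("need at least 3 realms for pairwise contrasts")
  lv <- fit$levels
  k <- length(lv)
  p <- length(fit$coefficients)
  # realm means on link scale: L %*% beta
  L <- cbind(1, rbind(0, diag(k - 1)))
  pairs <- utils::combn(k, 2)
  Cm <- t(apply(pairs, 2, function(ij) L[ij[1], ] - L[ij[2], ]))
  est <- as.numeric(Cm %*% fit$coefficients)
  V <- Cm %*% fit$vcov %*% t(Cm)
  if (any(!is.finite(V)) || any(diag(V) <= 0))
    stop("rank-deficient contrast covariance")
  se <- sqrt(diag(V))
  zval <- est / se
  if (adjust == "single-step") {
    R <- stats::cov2cor(V)
    m <- nrow(R)
    padj <- vapply(abs(zval), function(t0)
      1 - mvtnorm::pmvnorm(lower = rep(-t0, m), upper = rep(t0, m),
                           corr = R, keepAttr = FALSE), numeric(1))
    padj <- pmin(pmax(padj, 0), 1)
  } else {
    padj <- stats::p.adjust(2 * pnorm(-abs(zval)), "holm")
  }
  data.frame(contrast = paste(lv[pairs[1, ]], "-", lv[pairs[2, ]]),
             estimate = est, se = se, z = zval, p_adjusted = padj,
             stringsAsFactors = FALSE)
}
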