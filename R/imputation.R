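# Profile ML of a phylogenetic GLS: given covariance structure V (up to a
# scalar rate), the mean and rate have closed forms.  Returns mu, rate and
# the maximized log-likelihood.
gls_profile <- function(V, y) {
  n <- length(y)
  R <- tryCatch(chol(V), error = function(e)
    stop("covariance not positive definite (condition problem); rcond = ",
         signif(Matrix::rcond(Matrix::Matrix(V)), 3)))
  one <- rep(1, n)
  Vi_y <- backsolve(R, backsolve(R, y, transpose = TRUE))
  Vi_1 <- backsolve(R, backsolve(R, one, transpose = TRUE))
  mu <- sum(Vi_y) / sum(Vi_1)
  res <- y - mu
  Vi_r <- Vi_y - mu * Vi_1
  s2 <- sum(res * Vi_r) / n
  logdet <- 2 * sum(log(diag(R)))
  ll <- -0.5 * (n * log(2 * pi * s2) + logdet + n)
  list(mu = mu, rate = s2, loglik = ll)
}

# lambda transform of a covariance matrix: off-diagonals scaled, diagonal kept
lambda_cov <- function(C, lambda) {
  V <- lambda * C
  diag(V) <- diag(C)
  V
}

#' Pagel's lambda phylogenetic signal for a continuous trait
#'
#' Maximum-likelihood lambda in [0, 1] under a multivariate normal whose
#' off-diagonal tree covariance is scaled by lambda, with a chi-square(1)
#' likelihood-ratio test against lambda = 0 (no signal). On a star phylogeny
#' lambda is unidentifiable and reported as such.
#'
#' @param tree A `phylo` object.
#' @param x Named numeric trait vector (names = tips); `NA` entries are
#'   dropped. At least 10 observed tips are required.
#' @return A list with `lambda`, `loglik`, `loglik0` (lambda = 0), `loglik1`
#'   (lambda = 1), `p_value`, and `identifiable`.
#' @export
pagel_lambda <- function(tree, x) {
  x <- x[!is.na(x)]
  keep <- intersect(tree$tip.label, names(x))
  if (length(keep) < 10) stop("need at least 10 observed tips")
  C <- ape::vcv(tree)[keep, keep]
  y <- x[keep]
  offdiag <- C; diag(offdiag) <- 0
  if (max(abs(offdiag)) < 1e-12 * max(diag(C))) {
    return(list(lambda = NA_real_, loglik = NA_real_, loglik0 = NA_real_,
                loglik1 = NA_real_, p_value = NA_real_,
                identifiable = FALSE,
                note = "star phylogeny: lambda unidentifiable"))
  }
  nll <- function(l) -gls_profile(lambda_cov(C, l), y)$loglik
  opt <- optimize(nll, c(0, 1))
  ll0 <- -nll(0); ll1 <- -nll(1)
  lam <- opt$minimum; ll <- -opt$objective
  # the optimum can sit at a boundary that optimize() never evaluates exactly
  if (ll0 >= ll) { lam <- 0; ll <- ll0 }
  if (ll1 > ll) { lam <- 1; ll <- ll1 }
  stat <- max(0, 2 * (ll - ll0))
  list(lambda = lam, loglik = ll, loglik0 = ll0, loglik1 = ll1,
       p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       identifiable = TRUE)
}

# sum of absolute changes in nodal values over all edges, with nodal values
# estimated as the unweighted mean of daughter values (postorder)
sister_contrast_sum <- function(tree, x) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")$edge
  val <- numeric(nn)
  val[seq_len(ntip)] <- x[tree$tip.label]
  sums <- numeric(nn); cnts <- integer(nn)
  nchild <- tabulate(po[, 1], nbins = nn)
  # in postorder every child value is final when its edge is reached
  for (k in seq_len(nrow(po))) {
    pa <- po[k, 1]; ch <- po[k, 2]
    sums[pa] <- sums[pa] + val[ch]
    cnts[pa] <- cnts[pa] + 1L
    if (cnts[pa] == nchild[pa]) val[pa] <- sums[pa] / nchild[pa]
  }
  sum(abs(val[po[, 1]] - val[po[, 2]]))
}

#' D statistic of phylogenetic signal for a binary trait
#'
#' The observed sum of sister-clade contrasts is scaled between two
#' simulated anchors: the expectation under random shuffling of the trait
#' (D = 1) and under a threshold Brownian model matched to the observed
#' prevalence (D = 0).
#'
#' @param tree A `phylo` object.
#' @param x Named 0/1 trait vector; both states must be present.
#' @param n_perm Number of permutation and Brownian simulations (>= 1).
#' @return A list with `D`, `p_random` (proportion of shuffle nulls with a
#'   contrast sum at or below the observed: small values indicate phylogenetic
#'   structure) and `p_brownian` (proportion of Brownian nulls at or above
#'   the observed).
#' @export
d_statistic <- function(tree, x, n_perm = 100) {
  if (n_perm < 1) stop("n_perm must be >= 1 (nulls are required)")
  x <- x[tree$tip.label]
  if (anyNA(x)) stop("trait has missing values")
  if (length(unique(x)) < 2) stop("trait is monomorphic")
  k1 <- sum(x == 1)
  obs <- sister_contrast_sum(tree, setNames(as.numeric(x), tree$tip.label))
  rand <- replicate(n_perm, {
    xs <- setNames(sample(as.numeric(x)), tree$tip.label)
    sister_contrast_sum(tree, xs)
  })
  bm <- replicate(n_perm, {
    liab <- simulate_bm(tree, 0, 1)
    xb <- setNames(as.numeric(rank(liab, ties.method = "first") >
                              length(liab) - k1), tree$tip.label)
    sister_contrast_sum(tree, xb)
  })
  D <- (obs - mean(bm)) / (mean(rand) - mean(bm))
  list(D = D,
       p_random = mean(rand <= obs),
       p_brownian = mean(bm >= obs))
}

# conditional expectation of the missing entries of a Brownian trait given
# the observed ones (Gaussian kriging on the tree covariance)
impute_conditional <- function(C, y) {
  obs <- which(!is.na(y)); mis <- which(is.na(y))
  if (length(mis) == 0) return(y)
  Coo <- C[obs, obs, drop = FALSE]
  g <- gls_profile(Coo, y[obs])
  w <- solve(Coo, y[obs] - g$mu)
  y[mis] <- g$mu + as.numeric(C[mis, obs, drop = FALSE] %*% w)
  y
}

#' Brownian-motion phylogenetic imputation of missing traits
#'
#' Missing values are set to their conditional expectation under a Brownian
#' model given the observed tips (generalized-least-squares kriging on the
#' tree covariance). Body mass is imputed on the log scale; diet proportions
#' are imputed per category, clipped at zero and renormalized to sum to 100;
#' binaries are imputed as liabilities and thresholded at 0.5, with the
#' arboreal fallback applied to all-zero foraging rows. Observed values are
#' never altered. Traits with fewer than 3 observed tips are left missing
#' and the affected species flagged.
#'
#' @param tree A `phylo` object.
#' @param traits Trait table with `NA` for missing entries.
#' @return The completed table with columns `imputed` (logical flag per
#'   species) and an attribute `"failed_traits"` naming traits left
#'   unimputed.
#' @export
bm_impute <- function(tree, traits) {
  stopifnot(all(traits$species %in% tree$tip.label))
  C <- ape::vcv(tree)[traits$species, traits$species]
  out <- traits
  failed <- character(0)
  imputed_rows <- rowSums(is.na(traits[, setdiff(names(traits), "species"),
                                       drop = FALSE])) > 0

  fill <- function(y) {
    if (sum(!is.na(y)) < 3) return(NULL)
    impute_conditional(C, y)
  }

  if ("body_mass" %in% names(traits)) {
    y <- fill(log(traits$body_mass))
    if (is.null(y)) failed <- c(failed, "body_mass")
    else out$body_mass <- ifelse(is.na(traits$body_mass), exp(y),
                                 traits$body_mass)
  }
  diet_cols <- grep("^diet_", names(traits), value = TRUE)
  if (length(diet_cols)) {
    lat <- sapply(diet_cols, function(cl) {
      y <- fill(traits[[cl]])
      if (is.null(y)) { failed <<- c(failed, cl); traits[[cl]] } else y
    })
    lat <- pmax(as.matrix(lat), 0)
    need <- is.na(traits[[diet_cols[1]]]) & rowSums(is.na(lat)) == 0
    tot <- rowSums(lat)
    for (cl in diet_cols)
      out[[cl]] <- ifelse(!is.na(traits[[cl]]), traits[[cl]],
                          ifelse(need & tot > 0,
                                 100 * lat[, cl] / tot, lat[, cl]))
  }
  bin_cols <- c(grep("^strata_", names(traits), value = TRUE),
                grep("^activity_", names(traits), value = TRUE))
  for (cl in bin_cols) {
    y <- fill(traits[[cl]])
    if (is.null(y)) { failed <- c(failed, cl); next }
    out[[cl]] <- ifelse(is.na(traits[[cl]]), as.integer(y > 0.5),
                        traits[[cl]])
  }
  strata_cols <- grep("^strata_", names(out), value = TRUE)
  if ("strata_arboreal" %in% strata_cols) {
    allzero <- imputed_rows &
      rowSums(out[, strata_cols, drop = FALSE], na.rm = TRUE) == 0
    out$strata_arboreal[allzero] <- 1L
  }
  out$imputed <- imputed_rows
  attr(out, "failed_traits") <- unique(failed)
  out
}

#' Compare evolutionary models for a continuous trait
#'
#' Fits Brownian motion and a lambda-transformed Brownian model by maximum
#' likelihood (Ornstein-Uhlenbeck and kappa transformations are available
#' behind `extended = TRUE`) and ranks them by AIC (`2k - 2 lnL`).
#'
#' @param tree A `phylo` object.
#' @param x Named numeric trait vector (`NA` dropped).
#' @param extended Also fit OU and kappa models (default `FALSE`).
#' @return A list with `table` (model, logLik, k, AIC) and `chosen` (the
#'   minimum-AIC model).
#' @export
compare_evolutionary_models <- function(tree, x, extended = FALSE) {
  x <- x[!is.na(x)]
  keep <- intersect(tree$tip.label, names(x))
  C <- ape::vcv(tree)[keep, keep]
  y <- x[keep]
  rows <- list()
  ll_bm <- gls_profile(C, y)$loglik
  rows$BM <- c(ll = ll_bm, k = 2)
  lam <- tryCatch(pagel_lambda(tree, x), error = function(e) NULL)
  if (!is.null(lam) && isTRUE(lam$identifiable))
    rows$lambda <- c(ll = lam$loglik, k = 3)
  if (extended) {
    Tdepth <- max(diag(C))
    ou_ll <- function(log_a) {
      a <- exp(log_a)
      V <- exp(-2 * a * (Tdepth - C)) * (1 - exp(-2 * a * C)) / (2 * a)
      gls_profile(V, y)$loglik
    }
    opt_ou <- tryCatch(optimize(function(la) -ou_ll(la), c(-6, 3)),
                       error = function(e) NULL)
    if (!is.null(opt_ou)) rows$OU <- c(ll = -opt_ou$objective, k = 3)
    kap_ll <- function(kappa) {
      tk <- tree
      tk$edge.length <- tree$edge.length^kappa
      gls_profile(ape::vcv(tk)[keep, keep], y)$loglik
    }
    opt_k <- tryCatch(optimize(function(k) -kap_ll(k), c(1e-6, 3)),
                      error = function(e) NULL)
    if (!is.null(opt_k)) rows$kappa <- c(ll = -opt_k$objective, k = 3)
  }
  tab <- data.frame(model = names(rows),
                    logLik = vapply(rows, `[[`, numeric(1), "ll"),
                    k = vapply(rows, `[[`, numeric(1), "k"),
                    row.names = NULL)
  tab$AIC <- 2 * tab$k - 2 * tab$logLik
  list(table = tab, chosen = tab$model[which.min(tab$AIC)])
}

#' Leave-one-out cross-validation of the Brownian imputer
#'
#' Each observed value is held out and re-imputed from the others; accuracy
#' is summarized by the mean absolute error and the prediction coefficient
#' `1 - sum((pred - y)^2) / sum((y - mean(y))^2)`.
#'
#' @param tree A `phylo` object.
#' @param x Named numeric trait vector (`NA` dropped; >= 10 observed tips).
#' @return A list with `mae`, `prediction_coefficient` and the vector of
#'   `predictions`.
#' @export
loocv_impute <- function(tree, x) {
  x <- x[!is.na(x)]
  keep <- intersect(tree$tip.label, names(x))
  if (length(keep) < 10) stop("need at least 10 observed tips")
  C <- ape::vcv(tree)[keep, keep]
  y <- x[keep]
  g <- gls_profile(C, y)
  P <- solve(C)
  r <- as.numeric(P %*% (y - g$mu))
  pred <- y - r / diag(P)     # closed-form Gaussian leave-one-out mean
  sse <- sum((pred - y)^2)
  list(mae = mean(abs(pred - y)),
       prediction_coefficient = 1 - sse / sum((y - mean(y))^2),
       predictions = setNames(pred, keep))
}

#' Post-imputation sanity checks
#'
#' Diet proportions rounded to the nearest 5 must sum to 100; species
#' failing the rule are flagged for exclusion from functional-diversity
#' analyses. Foraging-strata rows that are all zero are set to arboreal.
#'
#' @param traits Completed trait table.
#' @return A list with `traits` (fallback applied), `report` (per-species
#'   `diet_ok`) and `excluded` (species failing the diet rule).
#' @export
sanity_check_imputed <- function(traits) {
  diet_cols <- grep("^diet_", names(traits), value = TRUE)
  rounded <- round(as.matrix(traits[, diet_cols, drop = FALSE]) / 5) * 5
  diet_ok <- abs(rowSums(rounded) - 100) < 1e-9
  strata_cols <- grep("^strata_", names(traits), value = TRUE)
  if ("strata_arboreal" %in% strata_cols) {
    allzero <- rowSums(traits[, strata_cols, drop = FALSE], na.rm = TRUE) == 0
    traits$strata_arboreal[allzero] <- 1L
  }
  list(traits = traits,
       report = data.frame(species = traits$species, diet_ok = diet_ok),
       excluded = traits$species[!diet_ok])
}
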