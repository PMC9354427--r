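# Univariate ACE decomposition for twin traits.
#
# The classical biometric model: a trait value for twin j of a pair is
#   y_j = mu + sqrt(a2) A_j + sqrt(c2) C + sqrt(e2) E_j   (times total SD),
# with corr(A_1, A_2) = 1 for MZ and 0.5 for DZ pairs, giving implied twin
# correlations r_MZ = a2 + c2 and r_DZ = 0.5 a2 + c2. Estimation is by
# maximum likelihood on pairs; incomplete pairs contribute their marginal
# (univariate) density, so missing co-twins are handled by full-information
# maximum likelihood rather than dropped.

#' Log-likelihood contribution of one (possibly incomplete) continuous pair
#'
#' Bivariate-normal log-density with common mean and variance and twin
#' correlation `r = a2 + c2` (MZ) or `0.5 a2 + c2` (DZ); a pair with a single
#' observed member contributes the univariate normal log-density. A
#' non-positive-definite implied covariance (r outside (-1, 1)) is penalized
#' with a large negative value rather than an error, so optimizers can
#' retreat from the boundary.
#'
#' @param pair_values Numeric matrix with two columns (or a length-2 vector),
#'   `NA` allowed.
#' @param zygosity `"MZ"`/`"DZ"` vector (recycled).
#' @param params List with `mu`, `var` (total variance), `a2`, `c2`
#'   (standardized shares).
#' @return Vector of per-pair log-likelihood contributions.
#' @export
pair_loglik_continuous <- function(pair_values, zygosity, params) {
  y <- if (is.matrix(pair_values)) pair_values else matrix(pair_values, ncol = 2)
  n <- nrow(y)
  zyg <- rep_len(zygosity, n)
  mu <- params$mu
  v <- params$var
  r <- params$a2 * zyg_rbar(zyg) + params$c2
  out <- numeric(n)
  s <- sqrt(v)
  z1 <- (y[, 1] - mu) / s
  z2 <- (y[, 2] - mu) / s
  both <- !is.na(z1) & !is.na(z2)
  one1 <- !is.na(z1) & is.na(z2)
  one2 <- is.na(z1) & !is.na(z2)
  none <- is.na(z1) & is.na(z2)
  bad <- v <= 0 | abs(r) >= 1
  if (any(both)) {
    rb <- r[both]
    q <- (z1[both]^2 + z2[both]^2 - 2 * rb * z1[both] * z2[both]) / (1 - rb^2)
    out[both] <- -log(2 * pi) - log(v) - 0.5 * log(1 - rb^2) - q / 2
  }
  out[one1] <- stats::dnorm(z1[one1], log = TRUE) - log(s)
  out[one2] <- stats::dnorm(z2[one2], log = TRUE) - log(s)
  out[none] <- 0
  out[bad & both] <- -1e10
  out
}

#' Fit the univariate ACE model to a continuous twin trait
#'
#' Maximum-likelihood fit over bounded standardized shares (unconstrained
#' path coefficients are squared internally, so shares are nonnegative by
#' construction and estimates with no signal pile up at the 0 boundary).
#' Standard errors come from the central-difference Hessian of the
#' minus-two-log-likelihood via the delta method; estimates on a boundary
#' are flagged as SE-unreliable.
#'
#' @param data Long-format coded data (one row per twin) with `family_id`,
#'   `twin_index`, `zygosity` columns.
#' @param trait Name of the trait column.
#' @return An object of class `ace_fit`: standardized shares `a2`, `c2`,
#'   `e2` with standard errors, `mean`, `total_variance`, `minus2LL`,
#'   per-zygosity pair counts, convergence and boundary flags.
#' @export
fit_ace_continuous <- function(data, trait) {
  w <- pair_wide(data, trait)
  y <- as.matrix(w[, paste0(trait, c(".1", ".2"))])
  keep <- rowSums(!is.na(y)) > 0
  y <- y[keep, , drop = FALSE]
  zyg <- w$zygosity[keep]
  for (z in c("MZ", "DZ"))
    if (sum(zyg == z & rowSums(!is.na(y)) == 2) < 2)
      stop("need at least 2 pairs with data per zygosity group")

  m2ll <- function(theta) {
    s <- shares_from_t(theta[3], theta[4])
    p <- list(mu = theta[1], var = exp(theta[2]), a2 = s[1], c2 = s[2])
    -2 * sum(pair_loglik_continuous(y, zyg, p))
  }
  yy <- y[!is.na(y)]
  start <- c(mean(yy), log(stats::var(yy)), t_from_shares(0.4, 0.2))
  opt <- stats::nlminb(start, m2ll, control = list(iter.max = 500))
  if (opt$convergence != 0) {
    opt2 <- stats::nlminb(opt$par * 1.0 + c(0, 0, 0.05, 0.05), m2ll,
                          control = list(iter.max = 500))
    if (opt2$objective < opt$objective) opt <- opt2
  }
  th <- opt$par
  sh <- shares_from_t(th[3], th[4])
  H <- num_hessian(m2ll, th)
  Vt <- vcov_from_m2ll_hessian(H)
  # delta method: gradient of (mu, var, a2, c2, e2) wrt theta
  J <- num_jacobian(function(t) {
    s <- shares_from_t(t[3], t[4])
    c(t[1], exp(t[2]), s)
  }, th)
  Vp <- J %*% Vt %*% t(J)
  se <- sqrt(pmax(diag(Vp), 0))
  boundary <- min(sh[1:2]) < 1e-4
  structure(list(
    trait = trait, type = "continuous",
    a2 = sh[1], c2 = sh[2], e2 = sh[3],
    se = c(mean = se[1], total_variance = se[2],
           a2 = se[3], c2 = se[4], e2 = se[5]),
    mean = th[1], total_variance = exp(th[2]),
    minus2LL = opt$objective,
    n_pairs_used = c(MZ = sum(zyg == "MZ"), DZ = sum(zyg == "DZ")),
    converged = opt$convergence == 0,
    boundary = boundary, se_reliable = !boundary,
    message = opt$message), class = "ace_fit")
}

num_jacobian <- function(f, x, h = NULL) {
  if (is.null(h)) h <- 1e-5 * (1 + abs(x))
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (i in seq_along(x)) {
    ei <- replace(numeric(length(x)), i, h[i])
    J[, i] <- (f(x + ei) - f(x - ei)) / (2 * h[i])
  }
  J
}

#' Log-likelihood contribution of an ordinal twin pair (liability model)
#'
#' Ordinal categories arise by cutting a standard-normal latent liability at
#' ordered thresholds; a pair's contribution is the log of the
#' bivariate-normal rectangle probability of its category pair under latent
#' correlation `r = a2 + c2` (MZ) or `0.5 a2 + c2` (DZ). A pair with one
#' observed member contributes the univariate interval probability.
#'
#' @param pair_categories Integer matrix with two columns (or length-2
#'   vector); categories `1 .. K+1` for `K` thresholds, `NA` allowed.
#' @param zygosity `"MZ"`/`"DZ"` vector (recycled).
#' @param thresholds Strictly increasing threshold vector.
#' @param a2,c2 Standardized latent variance shares.
#' @return Vector of per-pair log-likelihood contributions.
#' @export
pair_loglik_ordinal <- function(pair_categories, zygosity, thresholds, a2, c2) {
  if (is.unsorted(thresholds, strictly = TRUE)) stop("thresholds must be strictly increasing")
  k <- if (is.matrix(pair_categories)) pair_categories else
    matrix(pair_categories, ncol = 2)
  n <- nrow(k)
  zyg <- rep_len(zygosity, n)
  tau <- c(-Inf, thresholds, Inf)
  r <- a2 * zyg_rbar(zyg) + c2
  lo1 <- tau[k[, 1]];     hi1 <- tau[k[, 1] + 1]
  lo2 <- tau[k[, 2]];     hi2 <- tau[k[, 2] + 1]
  out <- numeric(n)
  both <- !is.na(k[, 1]) & !is.na(k[, 2])
  if (any(both))
    out[both] <- log(pmax(rect_prob(lo1[both], hi1[both], lo2[both], hi2[both],
                                    r[both]), 1e-300))
  one1 <- !is.na(k[, 1]) & is.na(k[, 2])
  one2 <- is.na(k[, 1]) & !is.na(k[, 2])
  out[one1] <- log(pmax(stats::pnorm(hi1[one1]) - stats::pnorm(lo1[one1]), 1e-300))
  out[one2] <- log(pmax(stats::pnorm(hi2[one2]) - stats::pnorm(lo2[one2]), 1e-300))
  out
}

#' Fit the univariate ACE liability model to an ordinal twin trait
#'
#' Thresholds and latent variance shares are estimated jointly by maximum
#' likelihood on the category-pair contingency (rectangle probabilities via
#' the bivariate-normal CDF, not simulation). The latent scale is
#' standardized, so `a2 + c2 + e2 = 1` by construction.
#'
#' @inheritParams fit_ace_continuous
#' @param trait Name of an ordinal column (integer codes, logical, or
#'   factor); logical `FALSE/TRUE` maps to categories 1/2.
#' @return An `ace_fit` with `thresholds` in place of `mean`/variance.
#' @export
fit_ace_ordinal <- function(data, trait) {
  w <- pair_wide(data, trait)
  k1 <- ord_codes(w[[paste0(trait, ".1")]])
  k2 <- ord_codes(w[[paste0(trait, ".2")]])
  keep <- !(is.na(k1) & is.na(k2))
  k <- cbind(k1, k2)[keep, , drop = FALSE]
  zyg <- w$zygosity[keep]
  K <- max(k, na.rm = TRUE) - 1L
  if (K < 1) stop("ordinal trait must have at least 2 observed categories")

  # aggregate: identical (cat1, cat2, zyg, pattern) cells share a probability
  key <- paste(k[, 1], k[, 2], zyg)
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- do.call(rbind, strsplit(agg$key, " "))
  ka <- suppressWarnings(cbind(as.integer(parts[, 1]), as.integer(parts[, 2])))
  za <- parts[, 3]
  cnt <- agg$Freq

  m2ll <- function(theta) {
    tau <- cumsum(c(theta[1], exp(theta[1 + seq_len(K - 1)])))
    s <- shares_from_t(theta[K + 1], theta[K + 2])
    -2 * sum(cnt * pair_loglik_ordinal(ka, za, tau, s[1], s[2]))
  }
  p1 <- mean(k == 1, na.rm = TRUE)
  tau0 <- stats::qnorm(seq_len(K) / (K + 1))
  tau0[1] <- stats::qnorm(max(min(p1, 0.99), 0.01))
  if (K > 1) tau0 <- sort(unique(pmax(tau0, tau0[1] + 0.1 * (seq_len(K) - 1))))
  start <- c(tau0[1], if (K > 1) log(diff(tau0)), t_from_shares(0.4, 0.2))
  opt <- stats::nlminb(start, m2ll, control = list(iter.max = 500))
  th <- opt$par
  tau <- cumsum(c(th[1], exp(th[1 + seq_len(K - 1)])))
  sh <- shares_from_t(th[K + 1], th[K + 2])
  H <- num_hessian(m2ll, th)
  Vt <- vcov_from_m2ll_hessian(H)
  J <- num_jacobian(function(t) {
    s <- shares_from_t(t[K + 1], t[K + 2])
    c(cumsum(c(t[1], exp(t[1 + seq_len(K - 1)]))), s)
  }, th)
  Vp <- J %*% Vt %*% t(J)
  se <- sqrt(pmax(diag(Vp), 0))
  boundary <- min(sh[1:2]) < 1e-4
  structure(list(
    trait = trait, type = "ordinal",
    a2 = sh[1], c2 = sh[2], e2 = sh[3],
    thresholds = tau,
    se = c(stats::setNames(se[seq_len(K)], paste0("tau", seq_len(K))),
           a2 = se[K + 1], c2 = se[K + 2], e2 = se[K + 3]),
    minus2LL = opt$objective,
    n_pairs_used = c(MZ = sum(zyg == "MZ"), DZ = sum(zyg == "DZ")),
    converged = opt$convergence == 0,
    boundary = boundary, se_reliable = !boundary,
    message = opt$message), class = "ace_fit")
}

ord_codes <- function(x) {
  if (is.logical(x)) return(as.integer(x) + 1L)
  if (is.factor(x)) return(as.integer(x))
  xi <- as.integer(x)
  xi - min(xi, na.rm = TRUE) + 1L
}

#' @export
print.ace_fit <- function(x, ...) {
  cat("Univariate ACE fit (", x$type, "): ", x$trait, "\n", sep = "")
  cat(sprintf("  a2 = %.3f  c2 = %.3f  e2 = %.3f\n", x$a2, x$c2, x$e2))
  if (x$type == "continuous")
    cat(sprintf("  mean = %.4f  total variance = %.4f\n",
                x$mean, x$total_variance))
  else
    cat("  thresholds:", sprintf("%.3f", x$thresholds), "\n")
  cat(sprintf("  -2LL = %.2f  pairs: MZ %d, DZ %d\n", x$minus2LL,
              x$n_pairs_used[["MZ"]], x$n_pairs_used[["DZ"]]))
  if (!x$converged) cat("  WARNING: optimizer did not report convergence\n")
  if (x$boundary) cat("  note: boundary estimate; standard errors unreliable\n")
  invisible(x)
}
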