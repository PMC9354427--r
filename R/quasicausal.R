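# Bivariate quasi-causal co-twin models.
#
# The predictor X (pillar count) is given its own ACE structure
#   X_ij = mu_x + a_x A_xij + c_x C_xi + e_x E_xij,
# and the outcome loads on X and on X's familial components directly:
#   Y_ij = mu_y + b_P X_ij + b_A A_xij + b_C C_xi + covariates
#          + a_u A_uij + c_u C_ui + e_u E_uij,
# with cross-twin corr(A) = 1 (MZ) / 0.5 (DZ) and corr(C) = 1. b_P is the
# phenotypic (within-person) association; b_A and b_C soak up
# between-family confounding. The constraint sequence mirrors the standard
# co-twin analysis: Model 1 fixes b_A = b_C = 0 (purely phenotypic);
# Model 2 estimates a single between-family path b_F = b_A = b_C (the two
# are not separately well identified); Model 3 additionally equates b_P
# across the male-pair and female-pair groups. Estimation is FIML over the
# partially observed (X1, Y1, X2, Y2) vectors; in the liability mode the
# ordinal count is a thresholded standard-normal latent and the likelihood
# integrates the latent pair over threshold rectangles by Gauss-Legendre
# quadrature.

#' Implied pair moments of the bivariate twin model
#'
#' Exact moment algebra for the 4-vector `(X1, Y1, X2, Y2)` under the
#' structural equations above.
#'
#' @param params List with `mu_x`, `mu_y`, paths `a_x`, `c_x`, `e_x`,
#'   slopes `b_P`, `b_A`, `b_C`, residual paths `a_u`, `c_u`, `e_u`.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return List with `mean` (length 4) and `cov` (4 x 4), order
#'   `(X1, Y1, X2, Y2)`.
#' @export
implied_pair_moments <- function(params, zygosity) {
  p <- params
  rbar <- zyg_rbar(zygosity)
  vx  <- p$a_x^2 + p$c_x^2 + p$e_x^2
  cxx <- rbar * p$a_x^2 + p$c_x^2
  vu  <- p$a_u^2 + p$c_u^2 + p$e_u^2
  cuu <- rbar * p$a_u^2 + p$c_u^2
  cxy <- p$b_P * vx + p$b_A * p$a_x + p$b_C * p$c_x
  cxy2 <- p$b_P * cxx + p$b_A * p$a_x * rbar + p$b_C * p$c_x
  vy  <- p$b_P^2 * vx + 2 * p$b_P * (p$b_A * p$a_x + p$b_C * p$c_x) +
    p$b_A^2 + p$b_C^2 + vu
  cyy <- p$b_P^2 * cxx + 2 * p$b_P * (p$b_A * p$a_x * rbar + p$b_C * p$c_x) +
    p$b_A^2 * rbar + p$b_C^2 + cuu
  S <- matrix(c(vx,   cxy,  cxx,  cxy2,
                cxy,  vy,   cxy2, cyy,
                cxx,  cxy2, vx,   cxy,
                cxy2, cyy,  cxy,  vy), 4, 4,
              dimnames = rep(list(c("X1", "Y1", "X2", "Y2")), 2))
  muy <- p$mu_y + p$b_P * p$mu_x      # mu_y is the structural intercept
  list(mean = c(X1 = p$mu_x, Y1 = muy, X2 = p$mu_x, Y2 = muy), cov = S)
}

# ---- continuous (observed-count) FIML engine --------------------------

# Group rows of a wide pair table by zygosity and observed-entry pattern of
# the 4-vector; returns per-cell index lists for fast repeated likelihoods.
qc_pattern_index <- function(x1, y1, x2, y2, zyg) {
  obs <- cbind(!is.na(x1), !is.na(y1), !is.na(x2), !is.na(y2))
  key <- paste(zyg, obs[, 1], obs[, 2], obs[, 3], obs[, 4])
  idx <- split(seq_along(key), key)
  idx[vapply(idx, function(i) any(obs[i[1], ]), TRUE)]
}

qc_m2ll_continuous <- function(p, dat, idx) {
  Y <- cbind(dat$x1, dat$y1, dat$x2, dat$y2)
  mom <- list(MZ = implied_pair_moments(p, "MZ"),
              DZ = implied_pair_moments(p, "DZ"))
  muy <- p$mu_y + p$b_P * p$mu_x
  mu_mat <- cbind(rep(p$mu_x, length(dat$x1)),
                  muy + dat$zshift1,
                  p$mu_x,
                  muy + dat$zshift2)
  total <- 0
  for (cell in idx) {
    i1 <- cell[1]
    zyg <- dat$zyg[i1]
    S <- mom[[zyg]]$cov
    obs <- which(!is.na(Y[i1, ]))
    Ss <- S[obs, obs, drop = FALSE]
    ch <- try(chol(Ss), silent = TRUE)
    if (inherits(ch, "try-error")) return(1e12)
    logdet <- 2 * sum(log(diag(ch)))
    inv <- chol2inv(ch)
    R <- Y[cell, obs, drop = FALSE] - mu_mat[cell, obs, drop = FALSE]
    q <- rowSums((R %*% inv) * R)
    total <- total + length(cell) * (length(obs) * log(2 * pi) + logdet) +
      sum(q)
  }
  total
}

# ---- liability-ordinal engine -----------------------------------------

#' Log-likelihood for ordinal-liability predictor pairs with continuous
#' outcomes
#'
#' Mixed likelihood of the bivariate twin model when the pillar count is
#' modeled as a thresholded standard-normal latent liability: the outcome
#' pair is conditionally bivariate normal given the latent liabilities, and
#' the observed category pair integrates the latent pair over its threshold
#' rectangle by fixed-order Gauss-Legendre quadrature (deterministic; the
#' order is configurable). Pairs with a missing outcome drop that dimension;
#' a missing category integrates its liability over the whole real line.
#'
#' @param pair_counts Integer matrix (n x 2) of count categories
#'   `1 .. K+1`, `NA` allowed.
#' @param pair_outcomes Numeric matrix (n x 2) of outcomes, `NA` allowed.
#' @param zygosity `"MZ"`/`"DZ"` vector.
#' @param params List as in [implied_pair_moments()] but with
#'   `thresholds` (ordered, length K) and standardized latent scale
#'   (`a_x^2 + c_x^2 + e_x^2 = 1`; `mu_x` ignored). Optional `yshift1`,
#'   `yshift2` add per-twin covariate shifts to the outcome mean.
#' @param gl_order Gauss-Legendre order per axis (default 8).
#' @return Vector of per-pair log-likelihood contributions.
#' @export
liability_predictor_loglik <- function(pair_counts, pair_outcomes, zygosity,
                                       params, gl_order = 8) {
  p <- params
  if (is.unsorted(p$thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  k <- as.matrix(pair_counts)
  y <- as.matrix(pair_outcomes)
  n <- nrow(k)
  zyg <- rep_len(zygosity, n)
  sh1 <- if (!is.null(p$yshift1)) rep_len(p$yshift1, n) else numeric(n)
  sh2 <- if (!is.null(p$yshift2)) rep_len(p$yshift2, n) else numeric(n)
  tau <- c(-Inf, p$thresholds, Inf)
  LIM <- 7.5
  # node count grows with interval width so tail categories stay accurate
  gl_cache <- list()
  gl_for <- function(a, b) {
    m <- max(gl_order, min(40L, ceiling(3 * (b - a))))
    key <- as.character(m)
    if (is.null(gl_cache[[key]])) gl_cache[[key]] <<- gauss_legendre(m)
    g <- gl_cache[[key]]
    list(nodes = (b - a) / 2 * g$nodes + (a + b) / 2,
         weights = (b - a) / 2 * g$weights)
  }
  out <- numeric(n)

  for (z in c("MZ", "DZ")) {
    zi <- which(zyg == z)
    if (!length(zi)) next
    mom <- implied_pair_moments(p, z)
    S <- mom$cov
    r_x <- S["X1", "X2"]
    SLL <- S[c(1, 3), c(1, 3)]
    SYL <- S[c(2, 4), c(1, 3)]
    SYY <- S[c(2, 4), c(2, 4)]
    B <- SYL %*% solve(SLL)
    CC <- SYY - B %*% t(SYL)          # conditional cov of (Y1, Y2) given L

    # category of NA integrates over the full (truncated) line
    kk <- k[zi, , drop = FALSE]
    cat1 <- ifelse(is.na(kk[, 1]), 0L, kk[, 1])
    cat2 <- ifelse(is.na(kk[, 2]), 0L, kk[, 2])
    ypat <- paste0(as.integer(!is.na(y[zi, 1])), as.integer(!is.na(y[zi, 2])))
    key <- paste(cat1, cat2, ypat)
    for (cell_key in unique(key)) {
      rows <- zi[key == cell_key]
      r1 <- cat1[key == cell_key][1]
      r2 <- cat2[key == cell_key][1]
      yp <- ypat[key == cell_key][1]
      lims <- function(cc) if (cc == 0L) c(-LIM, LIM) else
        c(max(tau[cc], -LIM), min(tau[cc + 1], LIM))
      l1 <- lims(r1); l2 <- lims(r2)
      obsy <- which(strsplit(yp, "")[[1]] == "1")

      if (length(obsy) == 0) {
        # pure rectangle probability, exact
        a1 <- if (r1 == 0L) -Inf else tau[r1]
        b1 <- if (r1 == 0L)  Inf else tau[r1 + 1]
        a2 <- if (r2 == 0L) -Inf else tau[r2]
        b2 <- if (r2 == 0L)  Inf else tau[r2 + 1]
        out[rows] <- log(pmax(rect_prob(a1, b1, a2, b2, r_x), 1e-300))
        next
      }
      g1l <- gl_for(l1[1], l1[2]); g2l <- gl_for(l2[1], l2[2])
      n1 <- g1l$nodes; w1 <- g1l$weights
      n2 <- g2l$nodes; w2 <- g2l$weights
      s_x <- sqrt(max(1 - r_x^2, 1e-12))
      yobs <- y[rows, obsy, drop = FALSE]
      muy0 <- cbind(p$mu_y + sh1[rows], p$mu_y + sh2[rows])
      Bo <- B[obsy, , drop = FALSE]
      Co <- CC[obsy, obsy, drop = FALSE]
      # flatten the node grid; everything below is matrix algebra
      g1 <- rep(n1, times = length(n2))
      g2 <- rep(n2, each = length(n1))
      wv <- rep(w1, times = length(n2)) * rep(w2, each = length(n1)) *
        stats::dnorm(g1) * stats::dnorm((g2 - r_x * g1) / s_x) / s_x
      cm <- Bo %*% rbind(g1, g2)                 # |obsy| x m conditional means
      if (length(obsy) == 2) {
        sd1 <- sqrt(Co[1, 1]); sd2 <- sqrt(Co[2, 2])
        rc <- Co[1, 2] / (sd1 * sd2)
        norm2 <- 1 / (2 * pi * sd1 * sd2 * sqrt(1 - rc^2))
        z1 <- outer(yobs[, 1] - muy0[, 1], cm[1, ], "-") / sd1
        z2 <- outer(yobs[, 2] - muy0[, 2], cm[2, ], "-") / sd2
        dy <- norm2 * exp(-(z1^2 - 2 * rc * z1 * z2 + z2^2) /
                            (2 * (1 - rc^2)))
      } else {
        sd1 <- sqrt(Co[1, 1])
        zz <- outer(yobs[, 1] - muy0[, obsy], cm[1, ], "-") / sd1
        dy <- stats::dnorm(zz) / sd1
      }
      prob <- drop(dy %*% wv)
      out[rows] <- log(pmax(prob, 1e-300))
    }
  }
  out
}

# ---- model fitting ----------------------------------------------------

qc_par_names <- function(model, mode, K, covariates) {
  base <- c("mu_y", "b_P",
            if (model >= 2) "b_F",
            "t_au", "t_cu", "t_eu",
            if (mode == "observed_count") c("mu_x", "t_ax", "t_cx", "t_ex")
            else c(paste0("tau", seq_len(K)), "t_ax", "t_cx"),
            if (length(covariates)) paste0("g_", covariates))
  base
}

qc_unpack <- function(theta, model, mode, K, covariates, prefix = "") {
  gv <- function(nm) unname(theta[paste0(prefix, nm)])
  p <- list(mu_y = gv("mu_y"), b_P = gv("b_P"))
  bf <- if (model >= 2) gv("b_F") else 0
  p$b_A <- bf; p$b_C <- bf
  p$a_u <- gv("t_au"); p$c_u <- gv("t_cu"); p$e_u <- gv("t_eu")
  if (mode == "observed_count") {
    p$mu_x <- gv("mu_x")
    p$a_x <- gv("t_ax"); p$c_x <- gv("t_cx"); p$e_x <- gv("t_ex")
  } else {
    p$mu_x <- 0
    s <- shares_from_t(gv("t_ax"), gv("t_cx"))
    p$a_x <- sqrt(s[1]); p$c_x <- sqrt(s[2]); p$e_x <- sqrt(s[3])
    raw <- vapply(seq_len(K), function(i) gv(paste0("tau", i)), 0)
    p$thresholds <- cumsum(c(raw[1], if (K > 1) exp(raw[-1])))
  }
  if (length(covariates)) p$gamma <- vapply(covariates,
    function(v) gv(paste0("g_", v)), 0)
  p
}

qc_group_data <- function(wide, outcome, covariates) {
  x1 <- wide$x.1; x2 <- wide$x.2
  y1 <- wide[[paste0(outcome, ".1")]]
  y2 <- wide[[paste0(outcome, ".2")]]
  zs1 <- zs2 <- rep(0, nrow(wide))
  Z1 <- Z2 <- NULL
  if (length(covariates)) {
    Z1 <- as.matrix(wide[paste0(covariates, ".1")])
    Z2 <- as.matrix(wide[paste0(covariates, ".2")])
    # an unobserved covariate removes that twin's outcome from the mean model
    y1[rowSums(is.na(Z1)) > 0] <- NA
    y2[rowSums(is.na(Z2)) > 0] <- NA
    Z1[is.na(Z1)] <- 0; Z2[is.na(Z2)] <- 0
  }
  keep <- !(is.na(x1) & is.na(x2) & is.na(y1) & is.na(y2))
  n <- sum(keep)
  list(x1 = x1[keep], x2 = x2[keep], y1 = y1[keep], y2 = y2[keep],
       zyg = wide$zygosity[keep],
       Z1 = if (!is.null(Z1)) Z1[keep, , drop = FALSE],
       Z2 = if (!is.null(Z2)) Z2[keep, , drop = FALSE],
       zshift1 = rep(0, n), zshift2 = rep(0, n))
}

qc_group_m2ll <- function(theta, dat, idx, model, mode, K, covariates, prefix,
                          gl_order) {
  p <- qc_unpack(theta, model, mode, K, covariates, prefix)
  if (length(covariates)) {
    dat$zshift1 <- drop(dat$Z1 %*% p$gamma)
    dat$zshift2 <- drop(dat$Z2 %*% p$gamma)
  }
  if (mode == "observed_count") {
    qc_m2ll_continuous(p, dat, idx)
  } else {
    p$yshift1 <- dat$zshift1
    p$yshift2 <- dat$zshift2
    ll <- liability_predictor_loglik(cbind(dat$x1, dat$x2) + 1L,
                                     cbind(dat$y1, dat$y2),
                                     dat$zyg, p, gl_order)
    -2 * sum(ll)
  }
}

qc_start <- function(dat, model, mode, K, covariates) {
  x <- c(dat$x1, dat$x2); y <- c(dat$y1, dat$y2)
  Z <- if (length(covariates)) rbind(dat$Z1, dat$Z2)
  ok <- !is.na(x) & !is.na(y)
  b0 <- if (sum(ok) > 5) stats::coef(stats::lm(y[ok] ~ x[ok]))[2] else 0
  if (!is.finite(b0)) b0 <- 0
  my <- mean(y, na.rm = TRUE)
  sy <- stats::sd(y, na.rm = TRUE); if (!is.finite(sy) || sy == 0) sy <- 1
  sx <- stats::sd(x, na.rm = TRUE); if (!is.finite(sx) || sx == 0) sx <- 1
  su <- sy * 0.9
  st <- c(mu_y = my, b_P = unname(b0),
          if (model >= 2) c(b_F = 0),
          t_au = su * 0.6, t_cu = su * 0.3, t_eu = su * 0.65)
  if (mode == "observed_count") {
    st <- c(st, mu_x = mean(x, na.rm = TRUE),
            t_ax = sx * 0.6, t_cx = sx * 0.35, t_ex = sx * 0.65)
    st["mu_y"] <- my - unname(b0) * mean(x, na.rm = TRUE)  # intercept scale
  } else {
    cum <- cumsum(tabulate(x + 1L, nbins = K + 1))[seq_len(K)] /
      sum(!is.na(x))
    cum <- pmin(pmax(cum, 0.01), 0.99)
    tau0 <- stats::qnorm(cum)
    tau0 <- tau0 + cumsum(c(0, pmax(0.05 - diff(tau0), 0)))  # enforce order
    st <- c(st, stats::setNames(c(tau0[1], if (K > 1) log(diff(tau0))),
                                paste0("tau", seq_len(K))),
            t_ax = 0.9, t_cx = 0.6)
    st["b_P"] <- st["b_P"] * sx  # latent scale is one SD of liability
  }
  if (length(covariates)) {
    g0 <- rep(0, length(covariates))
    if (sum(ok) > (length(covariates) + 5)) {
      fit <- try(stats::lm(y[ok] ~ x[ok] + Z[ok, , drop = FALSE]),
                 silent = TRUE)
      if (!inherits(fit, "try-error")) {
        cf <- stats::coef(fit)[-(1:2)]
        cf[!is.finite(cf)] <- 0
        g0 <- unname(cf)
      }
    }
    st <- c(st, stats::setNames(g0, paste0("g_", covariates)))
  }
  st
}

#' Fit the quasi-causal bivariate twin model
#'
#' Fits the co-twin model for a pillar-count predictor and a transformed
#' outcome over one or two sex groups, with the constraint sequence
#' Model 1 (phenotypic: `b_A = b_C = 0`), Model 2 (between-family path
#' `b_F = b_A = b_C` estimated), Model 3 (Model 2 with `b_P` equated across
#' groups). Missing entries of the pair 4-vector contribute their marginal
#' density (FIML). Covariates enter the outcome mean as fixed effects. In
#' `liability_ordinal` mode (the default, matching the liability-threshold
#' treatment of the count) the predictor is a thresholded latent liability;
#' `observed_count` treats the integer count as a continuous ACE phenotype
#' and is a fast, close approximation.
#'
#' @param data Coded long-format data (see [code_pillars()]).
#' @param outcome `"log_bmi"` or `"sqrt_phq"` (any numeric column works).
#' @param pillars Pillar subset: `"all"`, `"bmi_top2"`, `"phq_top2"`, or a
#'   character vector of indicator columns.
#' @param model Constraint level 1, 2 or 3.
#' @param covariates Optional subset of
#'   `c("age", "race", "income", "education")` (or any numeric columns;
#'   `race` is coded as a non-White indicator).
#' @param predictor_mode `"liability_ordinal"` or `"observed_count"`.
#' @param groups `"sex"` (male pairs and female pairs, the default when both
#'   sexes are present) or `"pooled"`.
#' @param gl_order Quadrature order for the liability mode.
#' @param se Compute standard errors from the central-difference Hessian
#'   (default `TRUE`; set `FALSE` to skip the Hessian for quick
#'   likelihood-only fits).
#' @return An object of class `qc_fit` with per-group estimates (`b_P`,
#'   `b_F`, covariate slopes, standard errors, p-values), `minus2LL`, the
#'   full parameter vector and covariance (for Wald tests), pair counts,
#'   and convergence/boundary flags.
#' @export
fit_quasicausal <- function(data, outcome, pillars = "all", model = 2,
                            covariates = NULL,
                            predictor_mode = c("liability_ordinal",
                                               "observed_count"),
                            groups = c("sex", "pooled"), gl_order = 8,
                            se = TRUE) {
  mode <- match.arg(predictor_mode)
  model <- as.integer(model)
  stopifnot(model %in% 1:3)
  cols <- resolve_pillars(pillars)
  data$x <- count_pillars(data[cols])
  K <- length(cols)

  if (!is.null(covariates) && "race" %in% covariates)
    data$race <- as.numeric(data$race == "non-White")
  if (!is.null(covariates) && "age" %in% covariates)
    data$age <- (data$age - mean(data$age, na.rm = TRUE)) / 10

  if (is.character(groups) && length(groups) > 1) groups <- groups[1]
  use_sex <- identical(groups, "sex") && "sex" %in% names(data) &&
    length(unique(stats::na.omit(data$sex))) == 2
  if (model == 3 && !use_sex)
    stop("model 3 equates b_P across sex groups and needs both sexes")
  grp_names <- if (use_sex) c("male", "female") else "pooled"

  wide <- pair_wide(data, c("x", outcome, covariates))
  gdat <- list(); idx <- list()
  for (g in grp_names) {
    wg <- if (use_sex) wide[wide$sex == g & !is.na(wide$sex), ] else wide
    d <- qc_group_data(wg, outcome, covariates)
    gdat[[g]] <- d
    idx[[g]] <- qc_pattern_index(d$x1, d$y1, d$x2, d$y2, d$zyg)
  }

  nm <- qc_par_names(model, mode, K, covariates)
  shared <- if (model == 3) "b_P" else character(0)
  theta0 <- c()
  for (g in grp_names) {
    st <- qc_start(gdat[[g]], model, mode, K, covariates)
    names(st) <- paste0(g, ".", nm)
    theta0 <- c(theta0, st)
  }
  if (length(shared)) {
    for (s in shared) {
      pos <- paste0(grp_names, ".", s)
      avg <- mean(theta0[pos])
      theta0 <- theta0[setdiff(names(theta0), pos[-1])]
      names(theta0)[names(theta0) == pos[1]] <- s
      theta0[s] <- avg
    }
  }

  expand <- function(theta) {
    # map shared names back onto each group's slot
    full <- theta
    for (s in shared)
      for (g in grp_names) full[paste0(g, ".", s)] <- theta[s]
    full
  }
  m2ll <- function(theta) {
    full <- expand(theta)
    tot <- 0
    for (g in grp_names) {
      tot <- tot + qc_group_m2ll(full, gdat[[g]], idx[[g]], model, mode, K,
                                 covariates, paste0(g, "."), gl_order)
      if (tot >= 1e12) return(tot)
    }
    tot
  }

  if (!length(shared) && length(grp_names) > 1) {
    # no cross-group parameters: groups are independent samples, so fit
    # each separately and assemble a block-diagonal covariance
    th <- numeric(0)
    V <- matrix(0, 0, 0)
    objective <- 0
    convergence <- 0
    for (g in grp_names) {
      gn <- grep(paste0("^", g, "\\."), names(theta0), value = TRUE)
      f_g <- function(tg) {
        names(tg) <- gn
        qc_group_m2ll(tg, gdat[[g]], idx[[g]], model, mode, K,
                      covariates, paste0(g, "."), gl_order)
      }
      o <- stats::nlminb(theta0[gn], f_g,
                         control = list(iter.max = 1000, eval.max = 2000))
      if (o$convergence != 0) {
        o2 <- stats::nlminb(o$par + stats::rnorm(length(o$par), 0, 1e-3),
                            f_g, control = list(iter.max = 1000,
                                                eval.max = 2000))
        if (o2$objective <= o$objective) o <- o2
      }
      objective <- objective + o$objective
      convergence <- max(convergence, o$convergence)
      Vg <- if (se) vcov_from_m2ll_hessian(num_hessian(f_g, o$par)) else
        matrix(NA_real_, length(gn), length(gn))
      pos <- length(th) + seq_along(gn)
      Vnew <- matrix(0, length(th) + length(gn), length(th) + length(gn))
      if (length(th)) Vnew[seq_along(th), seq_along(th)] <- V
      Vnew[pos, pos] <- Vg
      V <- Vnew
      th <- c(th, stats::setNames(o$par, gn))
    }
    opt <- list(par = th, objective = objective, convergence = convergence,
                message = NULL)
  } else {
    opt <- stats::nlminb(theta0, m2ll,
                         control = list(iter.max = 1000, eval.max = 2000))
    if (opt$convergence != 0) {
      jitter <- opt$par + stats::rnorm(length(opt$par), 0, 1e-3)
      opt2 <- stats::nlminb(jitter, m2ll,
                            control = list(iter.max = 1000, eval.max = 2000))
      if (opt2$objective <= opt$objective) opt <- opt2
    }
    th <- opt$par
    if (se) {
      H <- num_hessian(m2ll, th)
      V <- vcov_from_m2ll_hessian(H)
    } else {
      V <- matrix(NA_real_, length(th), length(th))
    }
  }
  th <- opt$par
  dimnames(V) <- list(names(th), names(th))
  se <- sqrt(pmax(diag(V), 0))
  names(se) <- names(th)

  full <- expand(th)
  res_groups <- list()
  boundary <- FALSE
  for (g in grp_names) {
    p <- qc_unpack(full, model, mode, K, covariates, paste0(g, "."))
    bP_name <- if (model == 3) "b_P" else paste0(g, ".b_P")
    bF_name <- paste0(g, ".b_F")
    est <- c(b_P = p$b_P, if (model >= 2) c(b_F = p$b_A))
    ses <- c(b_P = unname(se[bP_name]),
             if (model >= 2) c(b_F = unname(se[bF_name])))
    gam <- if (length(covariates)) {
      gn <- paste0(g, ".g_", covariates)
      data.frame(covariate = covariates, estimate = unname(p$gamma),
                 se = unname(se[gn]),
                 p = 2 * stats::pnorm(-abs(unname(p$gamma) / se[gn])))
    }
    vshares <- if (mode == "observed_count") {
      vx <- p$a_x^2 + p$c_x^2 + p$e_x^2
      c(a2_x = p$a_x^2 / vx, c2_x = p$c_x^2 / vx, e2_x = p$e_x^2 / vx,
        var_x = vx)
    } else c(a2_x = p$a_x^2, c2_x = p$c_x^2, e2_x = p$e_x^2, var_x = 1)
    vu <- p$a_u^2 + p$c_u^2 + p$e_u^2
    boundary <- boundary || min(abs(c(p$a_u, p$c_u, p$e_u))) < 1e-4
    res_groups[[g]] <- list(
      estimates = est, se = ses,
      p_values = 2 * stats::pnorm(-abs(est / ses)),
      predictor_shares = vshares,
      residual_shares = c(a2_u = p$a_u^2 / vu, c2_u = p$c_u^2 / vu,
                          e2_u = p$e_u^2 / vu, var_u = vu),
      mu_y = p$mu_y, mu_x = p$mu_x,
      thresholds = p$thresholds, covariate_table = gam,
      n_pairs = c(MZ = sum(gdat[[g]]$zyg == "MZ"),
                  DZ = sum(gdat[[g]]$zyg == "DZ")))
  }
  structure(list(outcome = outcome, pillars = cols, model = model,
                 predictor_mode = mode, covariates = covariates,
                 groups = res_groups, minus2LL = opt$objective,
                 theta = th, vcov = V,
                 converged = opt$convergence == 0, boundary = boundary,
                 message = opt$message), class = "qc_fit")
}

#' @export
print.qc_fit <- function(x, ...) {
  cat(sprintf("Quasi-causal bivariate twin model (Model %d, %s)\n",
              x$model, x$predictor_mode))
  cat("  outcome:", x$outcome, " predictor: count of",
      paste(x$pillars, collapse = ", "), "\n")
  for (g in names(x$groups)) {
    r <- x$groups[[g]]
    cat(sprintf("  [%s]  b_P = %.4f (SE %.4f, p = %.3g)", g,
                r$estimates["b_P"], r$se["b_P"], r$p_values["b_P"]))
    if ("b_F" %in% names(r$estimates))
      cat(sprintf("  b_F = %.4f (SE %.4f)", r$estimates["b_F"], r$se["b_F"]))
    cat("\n")
  }
  cat(sprintf("  -2LL = %.2f%s\n", x$minus2LL,
              if (!x$converged) "  (convergence not reported)" else ""))
  invisible(x)
}

#' Wald test of a linear restriction on fitted parameters
#'
#' Computes `W = (R theta - r)' (R V R')^{-1} (R theta - r)` with a
#' chi-squared reference on `rank(R)` degrees of freedom. The constraint can
#' be given as a restriction matrix over the fit's parameter vector or as
#' the named shortcut `"b_P_equal"` (equality of `b_P` across the two sex
#' groups of a Model 1/2 fit — the cross-sex test that motivates Model 3).
#'
#' @param fit A `qc_fit` (or any list with `theta` and `vcov`).
#' @param constraint `"b_P_equal"` or a numeric restriction matrix with one
#'   row per restriction and columns matching `fit$theta`.
#' @param rhs Right-hand side vector (default zeros).
#' @return List with `statistic`, `df`, `p`.
#' @export
wald_test <- function(fit, constraint = "b_P_equal", rhs = NULL) {
  th <- fit$theta
  V <- fit$vcov
  if (is.character(constraint)) {
    stopifnot(constraint == "b_P_equal")
    gn <- grep("\\.b_P$", names(th), value = TRUE)
    if (length(gn) != 2)
      stop("b_P_equal needs a two-group fit with group-specific b_P")
    R <- matrix(0, 1, length(th), dimnames = list(NULL, names(th)))
    R[1, gn[1]] <- 1; R[1, gn[2]] <- -1
  } else {
    R <- constraint
    if (is.null(dim(R))) R <- matrix(R, 1)
  }
  if (is.null(rhs)) rhs <- rep(0, nrow(R))
  d <- drop(R %*% th) - rhs
  M <- R %*% V %*% t(R)
  Mi <- try(solve(M), silent = TRUE)
  if (inherits(Mi, "try-error")) stop("restricted covariance is singular")
  W <- drop(t(d) %*% Mi %*% d)
  df <- qr(R)$rank
  list(statistic = W, df = df, p = stats::pchisq(W, df, lower.tail = FALSE))
}

#' Percent change in the outcome per additional pillar
#'
#' For an outcome modeled on the natural-log scale, a slope `b_P` per
#' pillar corresponds to a multiplicative factor `exp(b_P)`; this returns
#' the percent change `100 * (1 - exp(b_P))` (positive = decrease).
#'
#' @param b_P Slope(s) on the log scale.
#' @return Percent decrease per additional pillar met.
#' @export
percent_change_per_pillar <- function(b_P) 100 * (1 - exp(b_P))
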