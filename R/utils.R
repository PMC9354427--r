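# Shared numerical helpers.

# Central-difference Hessian of a scalar function.
num_hessian <- function(f, x, h = NULL) {
  p <- length(x)
  if (is.null(h)) h <- 1e-4 * (1 + abs(x))
  H <- matrix(0, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- replace(numeric(p), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

# Parameter covariance from the Hessian of minus-two-log-likelihood.
vcov_from_m2ll_hessian <- function(H) {
  V <- try(2 * solve(H), silent = TRUE)
  if (inherits(V, "try-error") || any(!is.finite(V))) {
    V <- try(2 * solve(H + diag(1e-8 * (1 + abs(diag(H))), nrow(H))),
             silent = TRUE)
    if (inherits(V, "try-error")) V <- matrix(NA_real_, nrow(H), nrow(H))
  }
  V
}

# Unconstrained (t_a, t_c) -> standardized variance shares (a2, c2, e2),
# shares = (t_a^2, t_c^2, 1) / (t_a^2 + t_c^2 + 1): nonnegative, sum to 1.
shares_from_t <- function(t_a, t_c) {
  s <- c(t_a^2, t_c^2, 1)
  s / sum(s)
}

t_from_shares <- function(a2, c2, e2 = 1 - a2 - c2) {
  e2 <- max(e2, 1e-6)
  c(sqrt(a2 / e2), sqrt(c2 / e2))
}

zyg_rbar <- function(zygosity) ifelse(zygosity == "MZ", 1, 0.5)

# Reshape a long one-row-per-twin table into one row per pair, with
# `<var>.1` / `<var>.2` columns for each requested variable.
pair_wide <- function(data, vars) {
  stopifnot(all(c("family_id", "twin_index", "zygosity") %in% names(data)))
  d1 <- data[data$twin_index == 1, , drop = FALSE]
  d2 <- data[data$twin_index == 2, , drop = FALSE]
  fam <- union(d1$family_id, d2$family_id)
  i1 <- match(fam, d1$family_id)
  i2 <- match(fam, d2$family_id)
  meta_cols <- intersect(c("zygosity", "sex"), names(data))
  out <- data.frame(family_id = fam, stringsAsFactors = FALSE)
  for (mc in meta_cols) {
    v <- d1[[mc]][i1]
    v[is.na(i1)] <- d2[[mc]][i2][is.na(i1)]
    out[[mc]] <- v
  }
  for (v in vars) {
    out[[paste0(v, ".1")]] <- if (all(is.na(i1))) rep(NA, length(fam)) else d1[[v]][i1]
    out[[paste0(v, ".2")]] <- if (all(is.na(i2))) rep(NA, length(fam)) else d2[[v]][i2]
  }
  out
}

logit <- function(p) log(p / (1 - p))
expit <- function(x) 1 / (1 + exp(-x))
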