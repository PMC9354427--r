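# Between-individual and within-pair outcome differences by pillar-count
# difference — the descriptive counterpart of the co-twin models. Outcomes
# are summarized on their raw scale (kg/m^2, PHQ-2 units); the models use
# the transformed scales.

#' Average between-individual outcome difference for a given pillar-count gap
#'
#' For gap `d`, each eligible contrast compares the mean outcome of
#' individuals meeting `k + d` pillars with those meeting `k` pillars
#' (`k + d` vs `k` for every `k` with both categories populated). The
#' summary is the unweighted average of those contrasts (an n-weighted
#' average is available); its standard error is propagated from the
#' independent category means through the linear combination the average
#' reduces to.
#'
#' @param data Coded data (one row per individual) with `n_pillars`.
#' @param outcome Outcome column (raw scale, e.g. `"bmi"`).
#' @param d Pillar-count gaps to summarize (default 1:5).
#' @param count_col Count column (default `"n_pillars"`).
#' @param weighted Use n-weighted averaging of contrasts.
#' @return Data frame with `d`, `mean_diff`, `se`, `n_contrasts`, `n`
#'   (individuals contributing).
#' @export
between_individual_diffs <- function(data, outcome, d = 1:5,
                                     count_col = "n_pillars",
                                     weighted = FALSE) {
  k <- data[[count_col]]
  y <- data[[outcome]]
  ok <- !is.na(k) & !is.na(y)
  k <- k[ok]; y <- y[ok]
  cats <- sort(unique(k))
  mns <- tapply(y, k, mean)
  vars <- tapply(y, k, stats::var)
  ns <- tapply(y, k, length)
  out <- NULL
  for (dd in d) {
    lo <- cats[(cats + dd) %in% cats]
    lo <- lo[ns[as.character(lo)] >= 1 & ns[as.character(lo + dd)] >= 1]
    if (!length(lo)) next
    w <- if (weighted) {
      ww <- as.numeric(ns[as.character(lo + dd)] + ns[as.character(lo)])
      ww / sum(ww)
    } else rep(1 / length(lo), length(lo))
    # coefficients of the averaged contrast on the category means
    coefs <- stats::setNames(rep(0, length(cats)), cats)
    for (i in seq_along(lo)) {
      coefs[as.character(lo[i] + dd)] <- coefs[as.character(lo[i] + dd)] + w[i]
      coefs[as.character(lo[i])] <- coefs[as.character(lo[i])] - w[i]
    }
    mean_diff <- sum(coefs * mns[names(coefs)])
    se <- sqrt(sum(coefs^2 * vars[names(coefs)] / ns[names(coefs)],
                   na.rm = TRUE))
    out <- rbind(out, data.frame(
      d = dd, mean_diff = mean_diff, se = se, n_contrasts = length(lo),
      n = sum(ns[as.character(unique(c(lo, lo + dd)))])))
  }
  if (is.null(out)) out <- data.frame(d = integer(), mean_diff = numeric(),
                                      se = numeric(), n_contrasts = integer(),
                                      n = integer())
  rownames(out) <- NULL
  out
}

#' Within-pair outcome differences by pillar-count discordance
#'
#' Among complete pairs discordant on the pillar count, the signed
#' difference is the outcome of the twin meeting more pillars minus the
#' co-twin's; pairs are grouped by the absolute count difference (and
#' zygosity). Strata with no pairs are absent from the output; the standard
#' error `sd/sqrt(n)` is reported only for strata with at least two pairs.
#'
#' @param data Coded data with `family_id`, `twin_index`, `zygosity`.
#' @param outcome Outcome column (raw scale).
#' @param by_zygosity Stratify by zygosity (default `TRUE`).
#' @param count_col Count column (default `"n_pillars"`).
#' @return Data frame with `d`, (`zygosity`), `mean_diff`, `se`, `n`.
#' @export
within_pair_diffs <- function(data, outcome, by_zygosity = TRUE,
                              count_col = "n_pillars") {
  w <- pair_wide(data, c(count_col, outcome))
  k1 <- w[[paste0(count_col, ".1")]]; k2 <- w[[paste0(count_col, ".2")]]
  y1 <- w[[paste0(outcome, ".1")]];  y2 <- w[[paste0(outcome, ".2")]]
  ok <- !is.na(k1) & !is.na(k2) & !is.na(y1) & !is.na(y2) & k1 != k2
  dd <- abs(k1 - k2)[ok]
  delta <- ifelse(k1[ok] > k2[ok], y1[ok] - y2[ok], y2[ok] - y1[ok])
  grp <- if (by_zygosity) list(d = dd, zygosity = w$zygosity[ok]) else
    list(d = dd)
  agg <- stats::aggregate(delta, grp, function(v)
    c(mean = mean(v), sd = stats::sd(v), n = length(v)))
  out <- cbind(agg[names(grp)], as.data.frame(agg$x))
  out$se <- ifelse(out$n >= 2, out$sd / sqrt(out$n), NA_real_)
  out <- out[order(out$d), c(names(grp), "mean", "se", "n")]
  names(out)[names(out) == "mean"] <- "mean_diff"
  rownames(out) <- NULL
  out
}
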