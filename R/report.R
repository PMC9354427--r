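# Pipeline orchestration and publication-style outputs.

#' Descriptive summary of a coded registry
#'
#' Means (SD) for age, BMI, and the PHQ-2 total, the percent White, each
#' pillar's met-percentage, and the 0-5 pillar-count distribution, overall
#' and by sex. Each statistic uses the observations available for that
#' variable (the models, by contrast, use full-information likelihoods).
#'
#' @param data Coded data (one row per individual).
#' @return Data frame with one row per statistic and columns `total`,
#'   `men`, `women`; counts of omitted observations are recorded in the
#'   `"omitted"` attribute.
#' @export
summarize_descriptives <- function(data) {
  strata <- list(total = rep(TRUE, nrow(data)),
                 men = data$sex == "male",
                 women = data$sex == "female")
  msd <- function(x, s) {
    x <- x[s & !is.na(x)]
    if (!length(x)) return(NA_character_)
    sprintf("%.1f (%.1f)", mean(x), stats::sd(x))
  }
  pct <- function(b, s) {
    b <- b[s]; b <- b[!is.na(b)]
    if (!length(b)) return(NA_real_) else round(100 * mean(b), 1)
  }
  rows <- list(
    `n individuals` = vapply(strata, function(s) as.character(sum(s,
      na.rm = TRUE)), ""),
    `Age, mean (SD)` = vapply(strata, function(s) msd(data$age, s), ""),
    `BMI (kg/m2), mean (SD)` = vapply(strata, function(s) msd(data$bmi, s), ""),
    `PHQ-2, mean (SD)` = vapply(strata, function(s)
      sprintf("%.2f (%.2f)", mean(data$phq_total[s], na.rm = TRUE),
              stats::sd(data$phq_total[s], na.rm = TRUE)), ""),
    `Race (% White)` = vapply(strata, function(s)
      as.character(pct(data$race == "White", s)), ""))
  lab <- c(sleep_met = "Sleep", fv_met = "Fruits/vegetables",
           sedentary_met = "Sedentary time", mvpa_met = "MVPA",
           nonsmoking_met = "Smoking (No)")
  for (v in names(lab))
    rows[[paste0(lab[[v]], " met (%)")]] <- vapply(strata, function(s)
      as.character(pct(data[[v]], s)), "")
  for (k in 0:5)
    rows[[sprintf("%d pillars met (%%)", k)]] <- vapply(strata, function(s)
      as.character(pct(data$n_pillars == k, s)), "")
  out <- data.frame(statistic = names(rows),
                    do.call(rbind, rows), row.names = NULL)
  attr(out, "omitted") <- c(
    bmi = sum(is.na(data$bmi)), phq = sum(is.na(data$phq_total)),
    n_pillars = sum(is.na(data$n_pillars)))
  out
}

#' Coefficient table for a set of quasi-causal fits
#'
#' One row per parameter per fit, with significance marked at `alpha`
#' (presentational bolding with `**`; p-values are always reported
#' numerically).
#'
#' @param fits Named list of `qc_fit` objects.
#' @param alpha Significance level (default 0.05).
#' @return Data frame with model, group, parameter, estimate, SE, p,
#'   and a formatted `display` column.
#' @export
qc_table <- function(fits, alpha = 0.05) {
  out <- NULL
  for (nm in names(fits)) {
    f <- fits[[nm]]
    for (g in names(f$groups)) {
      r <- f$groups[[g]]
      for (par in names(r$estimates)) {
        est <- r$estimates[[par]]; se <- r$se[[par]]; p <- r$p_values[[par]]
        disp <- sprintf("%.3f (%.3f)", est, se)
        if (!is.na(p) && p < alpha) disp <- paste0("**", disp, "**")
        out <- rbind(out, data.frame(fit = nm, model = f$model, group = g,
                                     parameter = par, estimate = est,
                                     se = se, p = p, display = disp))
      }
      if (!is.null(r$covariate_table)) {
        ct <- r$covariate_table
        for (i in seq_len(nrow(ct))) {
          disp <- sprintf("%.3f (%.3f)", ct$estimate[i], ct$se[i])
          if (!is.na(ct$p[i]) && ct$p[i] < alpha)
            disp <- paste0("**", disp, "**")
          out <- rbind(out, data.frame(fit = nm, model = f$model, group = g,
                                       parameter = ct$covariate[i],
                                       estimate = ct$estimate[i],
                                       se = ct$se[i], p = ct$p[i],
                                       display = disp))
        }
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Generates (or accepts) a registry, codes pillars and outcomes, and runs
#' descriptives, univariate ACE decompositions, the quasi-causal Model
#' 1-2-3 sequence with the cross-sex Wald test for both outcomes and both
#' pillar presets, cross-validated regression trees, and the within-pair
#' difference summaries. Deterministic for a fixed seed. When `outdir` is
#' given, JSON/CSV results and a run log are written there.
#'
#' @param config A [registry_config()], or a data frame of raw survey rows.
#' @param seed Integer seed controlling generation and fold assignment.
#' @param sleep_standard `"8h"` or `"7h"`.
#' @param models Constraint levels to fit (default `1:3`).
#' @param covariates Covariates for the final covariate-adjusted model
#'   (default none).
#' @param predictor_mode Predictor treatment for the co-twin fits; the
#'   observed-count approximation is the pipeline default for registry-scale
#'   data.
#' @param presets Named list mapping outcome name to the pillar subsets to
#'   fit.
#' @param alpha Significance level for table bolding.
#' @param outdir Optional output directory.
#' @return List with `data`, `descriptives`, `ace`, `qc` (fits), `wald`,
#'   `trees`, `importance`, `diffs`, `tables`, `log`.
#' @export
run_pipeline <- function(config = registry_config(), seed = 1,
                         sleep_standard = "8h", models = 1:3,
                         covariates = NULL,
                         predictor_mode = "observed_count",
                         presets = list(log_bmi = c("all", "bmi_top2"),
                                        sqrt_phq = c("all", "phq_top2")),
                         alpha = 0.05, outdir = NULL) {
  log <- c(sprintf("seed=%d", seed),
           sprintf("package twinpillars %s",
                   as.character(utils::packageVersion("twinpillars"))))
  raw <- if (is.data.frame(config)) config else
    generate_registry(config, seed = seed)
  dat <- code_pillars(raw, sleep_standard = sleep_standard)
  log <- c(log, sprintf("stage=code n=%d sleep_standard=%s", nrow(dat),
                        sleep_standard))

  desc <- summarize_descriptives(dat)
  om <- attr(desc, "omitted")
  log <- c(log, sprintf(
    "stage=descriptives omitted: bmi=%d phq=%d n_pillars=%d",
    om[["bmi"]], om[["phq"]], om[["n_pillars"]]))

  ace <- list(log_bmi = fit_ace_continuous(dat, "log_bmi"),
              sqrt_phq = fit_ace_continuous(dat, "sqrt_phq"))
  for (p in PILLAR_VARS)
    ace[[p]] <- fit_ace_ordinal(dat, p)
  log <- c(log, "stage=ace done")

  qc <- list(); wald <- list()
  for (outc in names(presets)) for (ps in presets[[outc]]) {
    for (m in models) {
      key <- sprintf("%s.%s.model%d", outc, ps, m)
      covs <- if (m == max(models)) covariates else NULL
      qc[[key]] <- fit_quasicausal(dat, outc, pillars = ps, model = m,
                                   covariates = covs,
                                   predictor_mode = predictor_mode)
      log <- c(log, sprintf("stage=quasicausal %s -2LL=%.2f", key,
                            qc[[key]]$minus2LL))
    }
    m2key <- sprintf("%s.%s.model2", outc, ps)
    if (m2key %in% names(qc) && length(qc[[m2key]]$groups) == 2)
      wald[[paste(outc, ps, sep = ".")]] <-
        wald_test(qc[[m2key]], "b_P_equal")
  }

  trees <- list(); importance <- list()
  tree_outcomes <- c(bmi = "bmi", phq_total = "phq_total")
  for (tn in names(tree_outcomes)) {
    gr <- pillar_tree(dat, tree_outcomes[[tn]])
    pr <- cv_prune(gr, dat, seed = seed)
    trees[[tn]] <- pr
    importance[[tn]] <- variable_importance(pr)
    log <- c(log, sprintf("stage=tree outcome=%s leaves=%d", tn,
                          length(tree_leaves(pr$tree))))
  }

  diffs <- list(
    bmi_between = between_individual_diffs(dat, "bmi"),
    bmi_within = within_pair_diffs(dat, "bmi"),
    phq_between = between_individual_diffs(dat, "phq_total"),
    phq_within = within_pair_diffs(dat, "phq_total"))
  log <- c(log, "stage=diffs done")

  tables <- qc_table(qc, alpha = alpha)
  res <- list(data = dat, descriptives = desc, ace = ace, qc = qc,
              wald = wald, trees = trees, importance = importance,
              diffs = diffs, tables = tables, log = log)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(desc, file.path(outdir, "descriptives.csv"),
                     row.names = FALSE)
    utils::write.csv(tables, file.path(outdir, "model_tables.csv"),
                     row.names = FALSE)
    for (nm in names(diffs))
      utils::write.csv(diffs[[nm]],
                       file.path(outdir, paste0("diffs_", nm, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(
      lapply(importance, function(x) x),
      file.path(outdir, "importance.json"), dataframe = "rows",
      auto_unbox = TRUE, digits = NA)
    writeLines(log, file.path(outdir, "run_log.txt"))
  }
  res
}
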