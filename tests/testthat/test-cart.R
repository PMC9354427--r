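# Exhaustive split oracle: try every binary predictor directly.
brute_force_split <- function(y, X) {
  best <- NULL
  for (v in names(X)) {
    x <- X[[v]]; ok <- !is.na(x)
    if (!any(ok) || length(unique(x[ok])) < 2) next
    yl <- y[ok & x]; yr <- y[ok & !x]
    imp <- sum((y[ok] - mean(y[ok]))^2) -
      sum((yl - mean(yl))^2) - sum((yr - mean(yr))^2)
    if (is.null(best) || imp > best$improvement + 1e-12)
      best <- list(variable = v, improvement = imp)
  }
  if (!is.null(best) && best$improvement <= 0) best <- NULL
  best
}

rand_cases <- function(n, p, seed, miss = 0) {
  set.seed(seed)
  X <- as.data.frame(matrix(runif(n * p) < runif(p, 0.2, 0.8), n, p))
  names(X) <- paste0("v", seq_len(p))
  if (miss > 0) for (v in names(X)) X[[v]][runif(n) < miss] <- NA
  X
}

test_that("primary splits match exhaustive SSE minimization", {
  for (seed in 1:25) {
    n <- sample(10:50, 1)
    p <- sample(2:6, 1)
    X <- rand_cases(n, p, seed, miss = ifelse(seed %% 3 == 0, 0.15, 0))
    y <- rnorm(n) + rowSums(sapply(X, function(v) ifelse(is.na(v), 0, v))) *
      runif(1, 0, 2)
    got <- best_split(y, X)
    want <- brute_force_split(y, X)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$variable, want$variable)
      expect_equal(got$improvement, want$improvement, tolerance = 1e-10)
    }
  }
})

test_that("degenerate splits: constant outcome and perfect predictor", {
  X <- data.frame(a = c(TRUE, TRUE, FALSE, FALSE),
                  b = c(TRUE, FALSE, TRUE, FALSE))
  expect_null(best_split(rep(2.5, 4), X))
  y <- c(1, 1, 0, 0)   # outcome is exactly the indicator of a
  bs <- best_split(y, X)
  expect_equal(bs$variable, "a")
  expect_equal(bs$improvement, sum((y - mean(y))^2), tolerance = 1e-12)
})

test_that("surrogate agreement matches hand enumeration", {
  # 12 cases; primary p; s1 agrees on 10/12, s2 is independent-ish
  X <- data.frame(
    p  = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,
           FALSE, FALSE),
    s1 = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
           FALSE, TRUE),
    s2 = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE,
           TRUE, FALSE),
    dup = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,
            FALSE, FALSE))
  sur <- find_surrogates(X, "p")
  # identical variable: agreement 1, listed first
  expect_equal(sur$variable[1], "dup")
  expect_equal(sur$agreement[1], 1)
  expect_equal(sur$adj_agreement[1], 1)
  # s1: 10/12 agreement, baseline 6/12
  expect_true("s1" %in% sur$variable)
  expect_equal(sur$agreement[sur$variable == "s1"], 10 / 12)
  expect_equal(sur$adj_agreement[sur$variable == "s1"],
               (10 / 12 - 0.5) / 0.5)
  # s2 at the 50/50 baseline is excluded
  expect_false("s2" %in% sur$variable)
})

test_that("minsplit makes small nodes leaves", {
  set.seed(9)
  d <- data.frame(sedentary_met = runif(19) < 0.5, bmi = rnorm(19, 26))
  tr <- pillar_tree(d, "bmi", predictors = "sedentary_met", minsplit = 20)
  expect_null(tr$nodes[[1]]$split)
  expect_equal(length(tr$nodes), 1L)
})

fig1a_fixture <- function(n = 2500, seed = 14, miss = 0) {
  set.seed(seed)
  sed <- runif(n) < 0.483
  mvpa <- runif(n) < 0.412
  d <- data.frame(
    sleep_met = runif(n) < 0.387, fv_met = runif(n) < 0.503,
    sedentary_met = sed, mvpa_met = mvpa,
    nonsmoking_met = runif(n) < 0.898,
    bmi = 27 - 2 * sed - 1 * mvpa * (1 - sed) + rnorm(n, 0, 0.8))
  if (miss > 0) {
    d$sedentary_met[runif(n) < miss] <- NA
    d$mvpa_met[runif(n) < miss] <- NA
  }
  d
}

test_that("the sedentary/MVPA generator reproduces the expected topology", {
  d <- fig1a_fixture()
  tr <- pillar_tree(d, "bmi")
  root <- tr$nodes[[1]]
  expect_equal(root$split$variable, "sedentary_met")
  left <- tr$nodes[[root$children["left"]]]    # sedentary criterion met
  right <- tr$nodes[[root$children["right"]]]
  expect_null(left$split)
  expect_equal(right$split$variable, "mvpa_met")
  leaf_means <- sort(unname(vapply(twinpillars:::tree_leaves(tr),
                                   function(id) tr$nodes[[id]]$mean, 0)))
  expect_lt(max(abs(leaf_means - c(25, 26, 27))), 0.1)
  # node accounting identities
  ids <- twinpillars:::tree_internal(tr)
  for (id in ids) {
    node <- tr$nodes[[id]]
    ch <- lapply(node$children, function(i) tr$nodes[[i]])
    expect_equal(ch[[1]]$n + ch[[2]]$n, node$n)
    expect_equal((ch[[1]]$n * ch[[1]]$mean + ch[[2]]$n * ch[[2]]$mean) /
                   node$n, node$mean, tolerance = 1e-10)
    expect_equal(ch[[1]]$fraction_of_root + ch[[2]]$fraction_of_root,
                 node$fraction_of_root, tolerance = 1e-12)
  }
  imp <- variable_importance(tr)
  expect_equal(imp$variable[1], "sedentary_met")
  expect_equal(imp$variable[2], "mvpa_met")
  expect_equal(sum(imp$importance), 100, tolerance = 0.5)
  expect_true(all(imp$importance >= 0))
})

test_that("without missing data surrogate routing equals primary routing", {
  d <- fig1a_fixture(n = 600, seed = 15)
  tr <- pillar_tree(d, "bmi")
  pred <- predict(tr, d)
  # strip surrogates: predictions must be unchanged when nothing is missing
  tr2 <- tr
  for (i in seq_along(tr2$nodes)) tr2$nodes[[i]]$surrogates <- NULL
  tr2$nodes <- lapply(tr2$nodes, function(nd) {
    if (!is.null(nd$surrogates)) nd$surrogates <- nd$surrogates[0, ]
    nd
  })
  expect_equal(predict(tr2, d), pred)
})

test_that("surrogates route missing cases and earn importance", {
  d <- fig1a_fixture(n = 2500, seed = 16, miss = 0.1)
  # fv correlates with sedentary so it can serve as a surrogate
  d$fv_met <- ifelse(is.na(d$sedentary_met), runif(nrow(d)) < 0.5,
                     d$sedentary_met & (runif(nrow(d)) < 0.9))
  tr <- pillar_tree(d, "bmi")
  expect_equal(tr$nodes[[1]]$split$variable, "sedentary_met")
  expect_true("fv_met" %in% tr$nodes[[1]]$surrogates$variable)
  imp <- variable_importance(tr)
  expect_gt(imp$importance[imp$variable == "fv_met"], 0)
})

test_that("pruning: noise collapses to the root and alphas increase", {
  set.seed(17)
  collapsed <- 0
  for (rep in 1:40) {
    d <- data.frame(sleep_met = runif(150) < 0.4,
                    fv_met = runif(150) < 0.5,
                    sedentary_met = runif(150) < 0.5,
                    mvpa_met = runif(150) < 0.4,
                    nonsmoking_met = runif(150) < 0.9,
                    bmi = rnorm(150, 26, 1))
    tr <- pillar_tree(d, "bmi", cp = 0.002)
    pr <- cv_prune(tr, d, seed = rep, rule = "1se")
    if (length(twinpillars:::tree_leaves(pr$tree)) == 1) collapsed <- collapsed + 1
  }
  expect_gte(collapsed, 38)   # >= 95% of replicates prune pure noise away
  # cp sequence decreasing in tree size on a structured fixture
  d <- fig1a_fixture(n = 800, seed = 18)
  tr <- pillar_tree(d, "bmi", cp = 0.001)
  alphas <- twinpillars:::cp_sequence(tr)
  expect_true(all(diff(alphas) > 0))
  pr <- cv_prune(tr, d, seed = 3)
  expect_true(all(diff(pr$cptable$leaves) <= 0))
})

test_that("single-split tree gives all importance to its variable", {
  set.seed(19)
  sed <- runif(300) < 0.5
  d <- data.frame(sleep_met = runif(300) < 0.4, sedentary_met = sed,
                  bmi = 26 - 2 * sed + rnorm(300, 0, 0.3))
  tr <- pillar_tree(d, "bmi", predictors = c("sleep_met", "sedentary_met"))
  imp <- variable_importance(tr)
  expect_equal(imp$importance[imp$variable == "sedentary_met"], 100,
               tolerance = 1e-9)
})

test_that("row order does not change the fitted tree", {
  d <- fig1a_fixture(n = 400, seed = 20, miss = 0.05)
  t1 <- pillar_tree(d, "bmi")
  set.seed(21)
  perm <- sample(nrow(d))
  t2 <- pillar_tree(d[perm, ], "bmi")
  expect_equal(t1$nodes[[1]]$split$variable, t2$nodes[[1]]$split$variable)
  expect_equal(variable_importance(t1), variable_importance(t2),
               tolerance = 1e-9)
  expect_equal(predict(t1, d), predict(t2, d), tolerance = 1e-9)
})

test_that("tree structure agrees with rpart on complete data", {
  skip_if_not_installed("rpart")
  d <- fig1a_fixture(n = 1500, seed = 22)
  tr <- pillar_tree(d, "bmi", minsplit = 20, cp = 0.01)
  rp <- rpart::rpart(
    bmi ~ sleep_met + fv_met + sedentary_met + mvpa_met + nonsmoking_met,
    data = d,
    control = rpart::rpart.control(minsplit = 20, minbucket = 1, cp = 0.01,
                                   xval = 0))
  rp_vars <- as.character(rp$frame$var[rp$frame$var != "<leaf>"])
  our_vars <- vapply(twinpillars:::tree_internal(tr),
                     function(id) tr$nodes[[id]]$split$variable, "")
  expect_setequal(our_vars, rp_vars)
  expect_equal(sort(predict(tr, d)), sort(unname(predict(rp, d))),
               tolerance = 1e-8)
})
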