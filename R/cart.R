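# Regression trees over binary pillar indicators.
#
# ANOVA-style recursive partitioning: the split at each node maximizes the
# reduction in within-node sum of squared errors (SSE), candidates being
# the binary met/not-met indicators. Cases missing the primary splitter are
# routed by surrogate splits (other indicators ranked by agreement with the
# primary, kept only when they beat the go-with-majority baseline) and
# finally by the majority side. Pruning is by cost-complexity with
# cross-validated selection of the penalty. Variable importance sums each
# variable's SSE improvements as a primary splitter plus
# adjusted-agreement-weighted improvements as a surrogate, rescaled to
# total 100.

node_sse <- function(y) sum((y - mean(y))^2)

#' Best binary split at a node
#'
#' For each candidate, the improvement is `SSE(parent) - SSE(left) -
#' SSE(right)` computed over the cases non-missing on that candidate;
#' the maximizer wins, with ties broken by candidate order (canonical
#' pillar order in [pillar_tree()]).
#'
#' @param y Outcome values of the node's cases.
#' @param X Data frame / list of logical candidate columns.
#' @return `NULL` when no candidate has positive improvement, else a list
#'   with `variable`, `improvement`, and the left-side value (`TRUE` = met
#'   goes left).
#' @export
best_split <- function(y, X) {
  best <- NULL
  for (v in names(X)) {
    x <- X[[v]]
    ok <- !is.na(x)
    if (!any(ok)) next
    yl <- y[ok & x]; yr <- y[ok & !x]
    if (!length(yl) || !length(yr)) next
    imp <- node_sse(y[ok]) - node_sse(yl) - node_sse(yr)
    if (imp > 0 && (is.null(best) || imp > best$improvement + 1e-12))
      best <- list(variable = v, improvement = imp, left_value = TRUE)
  }
  best
}

#' Surrogate splits for a primary splitter
#'
#' Each other variable is oriented (both directions tried) to maximize the
#' fraction of cases — among those non-missing on both the primary and the
#' candidate — sent to the same side as the primary split. Candidates are
#' retained only when that agreement exceeds the go-with-majority baseline
#' (the larger primary-side fraction), and are ordered by agreement.
#'
#' @param X Data frame of candidate columns (logical), including the
#'   primary.
#' @param primary Name of the primary split variable.
#' @return Data frame with `variable`, `left_value` (candidate value routed
#'   left), `agreement`, `adj_agreement` (excess over baseline, rescaled to
#'   1 at perfect agreement); zero rows when no surrogate qualifies.
#' @export
find_surrogates <- function(X, primary) {
  px <- X[[primary]]
  okp <- !is.na(px)
  nl <- sum(px[okp]); nr <- sum(!px[okp])
  baseline <- max(nl, nr) / (nl + nr)
  out <- data.frame(variable = character(), left_value = logical(),
                    agreement = numeric(), adj_agreement = numeric())
  for (v in setdiff(names(X), primary)) {
    x <- X[[v]]
    ok <- okp & !is.na(x)
    if (!any(ok)) next
    # orientation TRUE: candidate TRUE goes left (same as primary TRUE)
    agree_same <- mean(x[ok] == px[ok])
    agree_flip <- 1 - agree_same
    agr <- max(agree_same, agree_flip)
    if (agr > baseline + 1e-12) {
      out <- rbind(out, data.frame(
        variable = v, left_value = agree_same >= agree_flip,
        agreement = agr,
        adj_agreement = (agr - baseline) / (1 - baseline)))
    }
  }
  out[order(-out$agreement), , drop = FALSE]
}

# route a node's cases: primary, then surrogates in order, then majority
route_side <- function(X, split, surrogates, majority_left) {
  n <- length(X[[split$variable]])
  side <- rep(NA, n)
  px <- X[[split$variable]]
  side[!is.na(px)] <- (px[!is.na(px)] == split$left_value)
  if (is.null(surrogates)) surrogates <- data.frame()
  if (nrow(surrogates)) for (i in seq_len(nrow(surrogates))) {
    un <- is.na(side)
    if (!any(un)) break
    sx <- X[[surrogates$variable[i]]]
    use <- un & !is.na(sx)
    side[use] <- (sx[use] == surrogates$left_value[i])
  }
  side[is.na(side)] <- majority_left
  side   # TRUE = left
}

#' Grow a regression tree over binary pillar indicators
#'
#' Recursive partitioning with SSE improvement, surrogate-split routing of
#' missing values, a minimum parent-node size, and a complexity threshold:
#' a split is kept only when its improvement is at least `cp` times the
#' root SSE.
#'
#' @param data Data frame of cases (one row per individual).
#' @param outcome Name of the continuous outcome column (raw scale, e.g.
#'   `bmi` or `phq_total`).
#' @param predictors Character vector of logical indicator columns
#'   (default: the five pillars in canonical order).
#' @param minsplit Minimum cases in a parent node for a split (default 20).
#' @param cp Complexity parameter (default 0.01).
#' @param max_depth Safety cap on depth.
#' @return An object of class `pillar_tree`; see [variable_importance()],
#'   [cv_prune()], `predict()` and `print()` methods.
#' @export
pillar_tree <- function(data, outcome, predictors = PILLAR_VARS,
                        minsplit = 20, cp = 0.01, max_depth = 30) {
  y_all <- data[[outcome]]
  keep <- !is.na(y_all)
  if (!any(keep)) stop("no non-missing outcome values")
  y <- y_all[keep]
  X <- data[keep, predictors, drop = FALSE]
  for (v in predictors) X[[v]] <- as.logical(X[[v]])
  root_sse <- node_sse(y)
  env <- new.env()
  env$nodes <- list()
  env$next_id <- 1L

  build <- function(idx, depth) {
    id <- env$next_id; env$next_id <- id + 1L
    yi <- y[idx]
    node <- list(id = id, depth = depth, n = length(idx),
                 fraction_of_root = length(idx) / length(y),
                 mean = mean(yi), sse = node_sse(yi),
                 split = NULL, surrogates = NULL, children = NULL,
                 majority_left = TRUE, improvement = 0)
    env$nodes[[id]] <- node
    Xi <- X[idx, , drop = FALSE]
    if (length(idx) >= minsplit && depth < max_depth && node$sse > 0) {
      bs <- best_split(yi, Xi)
      if (!is.null(bs) && bs$improvement >= cp * root_sse) {
        sur <- find_surrogates(Xi, bs$variable)
        px <- Xi[[bs$variable]]
        majority_left <- sum(px, na.rm = TRUE) >=
          sum(!px, na.rm = TRUE)
        side <- route_side(Xi, bs, sur, majority_left)
        if (any(side) && any(!side)) {
          left_id <- build(idx[side], depth + 1L)
          right_id <- build(idx[!side], depth + 1L)
          node$split <- bs
          node$surrogates <- sur
          node$children <- c(left = left_id, right = right_id)
          node$majority_left <- majority_left
          node$improvement <- bs$improvement
          env$nodes[[id]] <- node
        }
      }
    }
    id
  }
  build(seq_along(y), 0L)
  structure(list(nodes = env$nodes, outcome = outcome,
                 predictors = predictors, minsplit = minsplit, cp = cp,
                 max_depth = max_depth, root_sse = root_sse,
                 n = length(y)), class = "pillar_tree")
}

tree_is_leaf <- function(tree, id) is.null(tree$nodes[[id]]$split)

# reachable internal node ids (pruning can orphan stored descendants)
tree_internal <- function(tree, id = 1L) {
  if (tree_is_leaf(tree, id)) return(integer(0))
  ch <- tree$nodes[[id]]$children
  c(id, tree_internal(tree, ch[1]), tree_internal(tree, ch[2]))
}

tree_leaves <- function(tree, id = 1L) {
  if (tree_is_leaf(tree, id)) return(id)
  ch <- tree$nodes[[id]]$children
  c(tree_leaves(tree, ch[1]), tree_leaves(tree, ch[2]))
}

#' @export
predict.pillar_tree <- function(object, newdata, ...) {
  X <- newdata[, object$predictors, drop = FALSE]
  for (v in object$predictors) X[[v]] <- as.logical(X[[v]])
  out <- numeric(nrow(X))
  descend <- function(id, idx) {
    node <- object$nodes[[id]]
    if (is.null(node$split)) { out[idx] <<- node$mean; return(invisible()) }
    side <- route_side(X[idx, , drop = FALSE], node$split, node$surrogates,
                       node$majority_left)
    if (any(side)) descend(node$children[1], idx[side])
    if (any(!side)) descend(node$children[2], idx[!side])
  }
  if (nrow(X)) descend(1L, seq_len(nrow(X)))
  out
}

#' @export
print.pillar_tree <- function(x, digits = 3, ...) {
  cat(sprintf("Regression tree: %s ~ %s  (n = %d)\n", x$outcome,
              paste(x$predictors, collapse = " + "), x$n))
  show <- function(id, indent) {
    node <- x$nodes[[id]]
    lab <- sprintf("%smean %.*f (%d%%, n = %d)", indent, digits, node$mean,
                   round(100 * node$fraction_of_root), node$n)
    if (!is.null(node$split)) {
      cat(lab, sprintf(" split: %s (improvement %.*f)\n", node$split$variable,
                       digits, node$improvement), sep = "")
      show(node$children[1], paste0(indent, "  [met] "))
      show(node$children[2], paste0(indent, "  [not] "))
    } else cat(lab, "\n", sep = "")
  }
  show(1L, "")
  invisible(x)
}

# ---- cost-complexity pruning ------------------------------------------

# subtree leaf-SSE and leaf count below each internal node
tree_subtree_stats <- function(tree) {
  stats <- list()
  recurse <- function(id) {
    node <- tree$nodes[[id]]
    if (is.null(node$split)) {
      stats[[id]] <<- c(R = node$sse, leaves = 1)
    } else {
      recurse(node$children[1]); recurse(node$children[2])
      stats[[id]] <<- stats[[node$children[1]]] + stats[[node$children[2]]]
    }
  }
  recurse(1L)
  stats
}

# prune (in place, copy) all internal nodes whose weakest-link g <= alpha
prune_at <- function(tree, alpha) {
  repeat {
    st <- tree_subtree_stats(tree)
    internal <- tree_internal(tree)
    if (!length(internal)) break
    g <- vapply(internal, function(id) {
      s <- st[[id]]
      (tree$nodes[[id]]$sse - s["R"]) / (s["leaves"] - 1)
    }, 0)
    weakest <- min(g)
    if (weakest > alpha + 1e-12) break
    for (id in internal[g <= weakest + 1e-12]) {
      if (is.null(tree$nodes[[id]]$split)) next     # already collapsed
      # drop all descendants' splits by collapsing this node
      tree$nodes[[id]]$split <- NULL
      tree$nodes[[id]]$surrogates <- NULL
      tree$nodes[[id]]$children <- NULL
      tree$nodes[[id]]$improvement <- 0
    }
  }
  tree
}

# alpha sequence of the nested cost-complexity subtrees
cp_sequence <- function(tree) {
  alphas <- 0
  t_cur <- tree
  repeat {
    internal <- tree_internal(t_cur)
    if (!length(internal)) break
    st <- tree_subtree_stats(t_cur)
    g <- vapply(internal, function(id) {
      s <- st[[id]]
      (t_cur$nodes[[id]]$sse - s["R"]) / (s["leaves"] - 1)
    }, 0)
    a <- min(g)
    alphas <- c(alphas, a)
    t_cur <- prune_at(t_cur, a)
  }
  unique(alphas)
}

#' Cost-complexity pruning by cross-validation
#'
#' Builds the nested cost-complexity sequence of the grown tree, estimates
#' out-of-sample error for each penalty by v-fold cross-validation (folds
#' assigned by family when a `family_id` column is present, so co-twins stay
#' in the same fold), and prunes at the penalty minimizing cross-validated
#' error (`rule = "min"`, default) or at the smallest tree within one
#' standard error of the minimum (`rule = "1se"`).
#'
#' @param tree A [pillar_tree()].
#' @param data The data the tree was grown from.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param rule `"min"` or `"1se"`.
#' @return List of class `pruned_pillar_tree`: `tree` (the pruned
#'   `pillar_tree`), `cptable` (alpha, leaves, cross-validated error and its
#'   SE), `alpha_chosen`.
#' @export
cv_prune <- function(tree, data, folds = 10, seed = 1, rule = c("min", "1se")) {
  rule <- match.arg(rule)
  y_all <- data[[tree$outcome]]
  keep <- which(!is.na(y_all))
  if (length(keep) < folds) stop("fewer cases than folds")
  dat <- data[keep, , drop = FALSE]
  n <- nrow(dat)

  alphas <- cp_sequence(tree)
  # evaluate at geometric midpoints of the interval ends (stable choice)
  a_eval <- if (length(alphas) > 1)
    c(sqrt(alphas[-length(alphas)] * alphas[-1]), Inf) else c(Inf)
  a_eval[1] <- 0

  set.seed(seed)
  unit <- if ("family_id" %in% names(dat)) dat$family_id else seq_len(n)
  fam <- unique(unit)
  fold_of_fam <- sample(rep_len(seq_len(folds), length(fam)))
  fold <- fold_of_fam[match(unit, fam)]

  errs <- matrix(0, folds, length(a_eval))
  cnts <- integer(folds)
  for (f in seq_len(folds)) {
    test <- fold == f
    if (!any(test) || sum(!test) < 2) next
    t_f <- pillar_tree(dat[!test, , drop = FALSE], tree$outcome,
                       tree$predictors, tree$minsplit, tree$cp,
                       tree$max_depth)
    cnts[f] <- sum(test)
    for (k in seq_along(a_eval)) {
      t_k <- if (is.finite(a_eval[k])) prune_at(t_f, a_eval[k]) else
        prune_at(t_f, max(cp_sequence(t_f)) + 1)
      pred <- predict(t_k, dat[test, , drop = FALSE])
      errs[f, k] <- sum((dat[[tree$outcome]][test] - pred)^2)
    }
  }
  cv <- colSums(errs) / sum(cnts)
  fold_means <- sweep(errs, 1, pmax(cnts, 1), "/")
  cv_se <- apply(fold_means[cnts > 0, , drop = FALSE], 2, stats::sd) /
    sqrt(sum(cnts > 0))
  kmin <- which.min(cv)
  kpick <- if (rule == "min") kmin else
    max(which(cv <= cv[kmin] + cv_se[kmin]))
  alpha_chosen <- a_eval[kpick]
  pruned <- if (is.finite(alpha_chosen)) prune_at(tree, alpha_chosen) else
    prune_at(tree, max(cp_sequence(tree)) + 1)
  leaves <- vapply(seq_along(a_eval), function(k) {
    tk <- if (is.finite(a_eval[k])) prune_at(tree, a_eval[k]) else
      prune_at(tree, max(cp_sequence(tree)) + 1)
    length(tree_leaves(tk))
  }, 0L)
  structure(list(tree = pruned,
                 cptable = data.frame(alpha = a_eval, leaves = leaves,
                                      cv_error = cv, cv_se = cv_se),
                 alpha_chosen = alpha_chosen, rule = rule, folds = folds),
            class = "pruned_pillar_tree")
}

#' @export
print.pruned_pillar_tree <- function(x, ...) {
  cat(sprintf("Cross-validated pruning (%d-fold, rule = %s): alpha = %.4g\n",
              x$folds, x$rule, x$alpha_chosen))
  print(x$tree)
  invisible(x)
}

#' Variable importance of a (pruned) tree
#'
#' Per-variable sum of SSE improvements over the splits where the variable
#' is the primary splitter, plus adjusted-agreement-weighted improvements
#' where it is a surrogate, rescaled so the scores total 100. Variables
#' never appearing as primary or surrogate score 0.
#'
#' @param tree A `pillar_tree` or `pruned_pillar_tree`.
#' @return Data frame with `variable` and `importance`, sorted descending.
#' @export
variable_importance <- function(tree) {
  if (inherits(tree, "pruned_pillar_tree")) tree <- tree$tree
  imp <- stats::setNames(rep(0, length(tree$predictors)), tree$predictors)
  for (id in tree_internal(tree)) {
    node <- tree$nodes[[id]]
    imp[node$split$variable] <- imp[node$split$variable] + node$improvement
    if (!is.null(node$surrogates) && nrow(node$surrogates))
      for (i in seq_len(nrow(node$surrogates)))
        imp[node$surrogates$variable[i]] <-
          imp[node$surrogates$variable[i]] +
          node$surrogates$adj_agreement[i] * node$improvement
  }
  if (sum(imp) > 0) imp <- 100 * imp / sum(imp)
  out <- data.frame(variable = names(imp), importance = unname(imp))
  out[order(-out$importance), , drop = FALSE]
}
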