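#' Growth control parameters for classification trees
#'
#' Defaults follow the conventional CART controls: a node is split only if
#' it holds at least `min_split` cases, children must keep at least
#' `min_leaf` cases, and depth is capped at `max_depth`.
#'
#' @param min_split minimum node size to attempt a split.
#' @param min_leaf minimum child size.
#' @param max_depth maximum tree depth (root = depth 0).
#' @export
cart_params <- function(min_split = 20, min_leaf = 7, max_depth = 30) {
  stopifnot(min_split >= 2, min_leaf >= 1, max_depth >= 0)
  structure(list(min_split = min_split, min_leaf = min_leaf,
                 max_depth = max_depth), class = "cart_params")
}

#' Gini impurity of a two-class count vector
#'
#' `1 - sum(p_i^2)` for class proportions `p_i`; 0 for a pure node, 0.5 for
#' an even split.
#'
#' @param class_counts non-negative counts, not all zero.
#' @export
gini_impurity <- function(class_counts) {
  n <- sum(class_counts)
  if (n <= 0 || any(class_counts < 0)) stop("counts must be >= 0, not all zero")
  1 - sum((class_counts / n)^2)
}

# improvement tie tolerance: two splits closer than this in impurity
# decrease (count scale) are ties, resolved by declared column order then
# ascending threshold / subset enumeration order
.gain_eps <- 1e-8

# left subsets of m categorical levels: bit patterns over the first m - 1
# levels, so the last level always stays right; 2^(m-1) - 1 proper subsets
cat_left_subsets <- function(levels) {
  m <- length(levels)
  lapply(seq_len(2^(m - 1) - 1),
         function(bits) levels[which(bitwAnd(bits, 2^(seq_len(m - 1) - 1)) > 0)])
}

#' Grow a binary classification tree
#'
#' Recursive best-first Gini partitioning.  Numeric splits are searched at
#' the midpoints of consecutive distinct sorted values; categorical
#' (factor) splits over all proper subsets of the levels observed at the
#' node.  Growth stops on purity, `min_split`, `min_leaf`, `max_depth`, or
#' when no split improves the Gini cost.  Ties in impurity decrease are
#' broken by declared column order, then by ascending threshold / subset
#' enumeration order, so the result is deterministic.
#'
#' @param X data frame of predictors; factor columns are treated as
#'   categorical, everything else as numeric.
#' @param y binary response: 0/1, logical, or a two-level factor whose
#'   second level is "present".
#' @param params a [cart_params()].
#' @return object of class `classification_tree`.
#' @export
grow_tree <- function(X, y, params = cart_params()) {
  y <- as_binary_response(y)
  X <- as.data.frame(X, stringsAsFactors = FALSE)
  for (j in seq_along(X))
    if (is.character(X[[j]])) X[[j]] <- factor(X[[j]])
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported")
  grow_node <- function(idx, depth) {
    yy <- y[idx]
    counts <- c(sum(yy == 0), sum(yy == 1))
    node <- list(n = length(idx), counts = counts,
                 pred = if (counts[2] > counts[1]) 1L else 0L,
                 split = NULL, improvement = 0,
                 left = NULL, right = NULL)
    if (counts[1] == 0 || counts[2] == 0) return(node)
    if (length(idx) < params$min_split || depth >= params$max_depth)
      return(node)
    cols <- lapply(X, function(col) {
      v <- col[idx]
      if (is.factor(v)) as.integer(v) else as.numeric(v)
    })
    raw <- cpp_best_split(cols, vapply(X, is.factor, TRUE), yy,
                          params$min_leaf, .gain_eps)
    if (is.null(raw)) return(node)
    best <- if (raw$kind == "numeric") {
      list(var = names(X)[raw$var], kind = "numeric",
           threshold = raw$threshold, improvement = raw$improvement)
    } else {
      lev <- levels(X[[raw$var]])
      list(var = names(X)[raw$var], kind = "categorical",
           left_set = lev[raw$left_codes], right_set = lev[raw$right_codes],
           improvement = raw$improvement)
    }
    go_left <- if (best$kind == "numeric")
      X[[best$var]][idx] < best$threshold
    else
      X[[best$var]][idx] %in% best$left_set
    node$split <- best[setdiff(names(best), "improvement")]
    node$improvement <- best$improvement
    node$left <- grow_node(idx[go_left], depth + 1)
    node$right <- grow_node(idx[!go_left], depth + 1)
    node
  }
  root <- grow_node(seq_along(y), 0)
  structure(list(root = root, params = params,
                 var_names = names(X),
                 xlevels = lapply(X[vapply(X, is.factor, TRUE)], levels)),
            class = "classification_tree")
}

as_binary_response <- function(y) {
  if (is.factor(y)) {
    if (nlevels(y) != 2) stop("response must be binary")
    return(as.integer(y) - 1L)
  }
  if (is.logical(y)) return(as.integer(y))
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("response must be binary (0/1)")
  y
}

#' Reference tree grower (independent oracle)
#'
#' A deliberately plain re-implementation of [grow_tree()]'s definition with
#' explicit loops over every variable and every candidate threshold/subset,
#' sharing only the split definition and tie rules.  Used to validate the
#' vectorised grower.
#'
#' @inheritParams grow_tree
#' @export
grow_tree_reference <- function(X, y, params = cart_params()) {
  y <- as_binary_response(y)
  X <- as.data.frame(X, stringsAsFactors = FALSE)
  for (j in seq_along(X))
    if (is.character(X[[j]])) X[[j]] <- factor(X[[j]])
  grow_node <- function(idx, depth) {
    yy <- y[idx]
    counts <- c(sum(yy == 0), sum(yy == 1))
    node <- list(n = length(idx), counts = counts,
                 pred = if (counts[2] > counts[1]) 1L else 0L,
                 split = NULL, improvement = 0, left = NULL, right = NULL)
    if (counts[1] == 0 || counts[2] == 0 ||
        length(idx) < params$min_split || depth >= params$max_depth)
      return(node)
    n <- length(idx)
    parent_imp <- n * gini_impurity(counts)
    # enumerate every candidate in canonical order with its gain, then take
    # the first within tolerance of the maximum (same tie rule, plain loops)
    cands <- list()
    for (v in names(X)) {
      xv <- X[[v]][idx]
      if (is.factor(xv)) {
        obs <- levels(xv)[levels(xv) %in% unique(as.character(xv))]
        if (length(obs) < 2) next
        for (left_set in cat_left_subsets(obs)) {
          gain <- loop_gain(yy, as.character(xv) %in% left_set,
                            parent_imp, params$min_leaf)
          if (!is.na(gain))
            cands[[length(cands) + 1]] <-
              list(var = v, kind = "categorical", left_set = left_set,
                   right_set = setdiff(obs, left_set), improvement = gain)
        }
      } else {
        ux <- sort(unique(xv))
        if (length(ux) < 2) next
        for (u in seq_len(length(ux) - 1)) {
          thr <- (ux[u] + ux[u + 1]) / 2
          gain <- loop_gain(yy, xv < thr, parent_imp, params$min_leaf)
          if (!is.na(gain))
            cands[[length(cands) + 1]] <-
              list(var = v, kind = "numeric", threshold = thr,
                   improvement = gain)
        }
      }
    }
    best <- NULL
    if (length(cands)) {
      gains <- vapply(cands, `[[`, 0, "improvement")
      if (max(gains) > .gain_eps)
        best <- cands[[which(gains >= max(gains) - .gain_eps)[1]]]
    }
    if (is.null(best)) return(node)
    go_left <- if (best$kind == "numeric") X[[best$var]][idx] < best$threshold
               else as.character(X[[best$var]][idx]) %in% best$left_set
    node$split <- best[setdiff(names(best), "improvement")]
    node$improvement <- best$improvement
    node$left <- grow_node(idx[go_left], depth + 1)
    node$right <- grow_node(idx[!go_left], depth + 1)
    node
  }
  root <- grow_node(seq_along(y), 0)
  structure(list(root = root, params = params, var_names = names(X),
                 xlevels = lapply(X[vapply(X, is.factor, TRUE)], levels)),
            class = "classification_tree")
}

loop_gain <- function(yy, go_left, parent_imp, min_leaf) {
  nL <- sum(go_left); nR <- length(yy) - nL
  if (nL < min_leaf || nR < min_leaf) return(NA_real_)
  cl <- c(sum(yy[go_left] == 0), sum(yy[go_left] == 1))
  cr <- c(sum(yy[!go_left] == 0), sum(yy[!go_left] == 1))
  parent_imp - nL * gini_impurity(cl) - nR * gini_impurity(cr)
}

# ---- tree structure helpers ------------------------------------------------

is_leaf <- function(node) is.null(node$split)

node_leaves <- function(node) {
  if (is_leaf(node)) 1L else node_leaves(node$left) + node_leaves(node$right)
}

node_risk <- function(node) node$n - max(node$counts)

subtree_risk <- function(node) {
  if (is_leaf(node)) node_risk(node)
  else subtree_risk(node$left) + subtree_risk(node$right)
}

collapse_to_leaf <- function(node) {
  node$split <- NULL; node$left <- NULL; node$right <- NULL
  node$improvement <- 0
  node
}

# Weakest-link collapse schedule, computed once per tree on a flattened
# (preorder) array representation.  Each internal node receives the alpha at
# which it leaves the nested pruning sequence; the subtree optimal at
# complexity alpha is obtained by collapsing every node whose collapse alpha
# is <= alpha.
collapse_schedule <- function(root, r0) {
  nid <- 0L
  risk <- integer(); lef <- integer(); rig <- integer()
  walk <- function(node) {
    nid <<- nid + 1L
    id <- nid
    risk[id] <<- node$n - max(node$counts)
    lef[id] <<- NA_integer_; rig[id] <<- NA_integer_
    if (!is_leaf(node)) {
      lef[id] <<- walk(node$left)
      rig[id] <<- walk(node$right)
    }
    id
  }
  walk(root)
  N <- nid
  internal <- !is.na(lef)
  calpha <- rep(NA_real_, N)
  alive <- internal
  recompute <- function() {
    Rsub <- risk; leaves <- rep(1L, N)
    for (id in N:1) if (alive[id]) {
      Rsub[id] <- Rsub[lef[id]] + Rsub[rig[id]]
      leaves[id] <- leaves[lef[id]] + leaves[rig[id]]
    }
    list(Rsub = Rsub, leaves = leaves)
  }
  kill_subtree <- function(id, a) {
    if (is.na(lef[id])) return()
    if (alive[id]) { calpha[id] <<- a; alive[id] <<- FALSE }
    kill_subtree(lef[id], a); kill_subtree(rig[id], a)
  }
  e_alpha <- numeric(); e_size <- integer(); e_rel <- numeric()
  repeat {
    st <- recompute()
    if (!any(alive)) {
      if (!length(e_alpha)) {
        e_alpha <- 0; e_size <- 1L
        e_rel <- if (r0 > 0) risk[1] / r0 else 0
      }
      break
    }
    ids <- which(alive)
    g <- (risk[ids] - st$Rsub[ids]) / (r0 * (st$leaves[ids] - 1))
    m <- min(g)
    if (m > 1e-12 && !length(e_alpha)) {   # record the alpha = 0 tree first
      e_alpha <- 0; e_size <- st$leaves[1]; e_rel <- st$Rsub[1] / r0
    }
    for (id in ids[g <= m + 1e-12]) kill_subtree(id, max(m, 0))
    st <- recompute()
    if (m > 1e-12) {
      e_alpha <- c(e_alpha, m)
      e_size <- c(e_size, st$leaves[1])
      e_rel <- c(e_rel, st$Rsub[1] / r0)
    }
  }
  list(calpha = calpha,
       entries = data.frame(alpha = e_alpha, n_leaves = as.integer(e_size),
                            rel_error = e_rel))
}

# materialise the subtree optimal at complexity alpha from the schedule
cut_tree_at <- function(root, calpha, alpha) {
  nid <- 0L
  walk <- function(node) {
    nid <<- nid + 1L
    id <- nid
    if (is_leaf(node)) return(node)
    cut <- !is.na(calpha[id]) && calpha[id] <= alpha + 1e-12
    l <- walk(node$left)
    r <- walk(node$right)
    if (cut) return(collapse_to_leaf(node))
    node$left <- l; node$right <- r
    node
  }
  walk(root)
}

# leaf predictions under the schedule at complexity alpha, without
# materialising the subtree
predict_cut <- function(tree, newdata, calpha, alpha) {
  out <- integer(nrow(newdata))
  # preorder ids assigned alongside routing, mirroring collapse_schedule
  route <- function(node, idx, id_env) {
    id_env$k <- id_env$k + 1L
    id <- id_env$k
    cut <- is_leaf(node) ||
      (!is.na(calpha[id]) && calpha[id] <= alpha + 1e-12)
    if (cut && length(idx)) out[idx] <<- node$pred
    if (is_leaf(node)) return()
    s <- node$split
    if (cut) idx <- integer()
    if (length(idx)) {
      xv <- newdata[[s$var]]
      go_left <- if (s$kind == "numeric") xv[idx] < s$threshold
                 else as.character(xv[idx]) %in% s$left_set
    } else go_left <- logical()
    route(node$left, idx[go_left], id_env)
    route(node$right, idx[!go_left], id_env)
  }
  id_env <- new.env()
  id_env$k <- 0L
  route(tree$root, seq_len(nrow(newdata)), id_env)
  out
}

root_risk <- function(tree) node_risk(tree$root)

#' Weakest-link cost-complexity pruning path
#'
#' Repeatedly collapses the internal node(s) minimising
#' `g(t) = (R(t) - R(T_t)) / (|leaves(T_t)| - 1)`, with misclassification
#' risk `R` scaled by the root risk, yielding the nested subtree sequence
#' with strictly increasing alpha and strictly decreasing leaf counts down
#' to the root.  The alpha = 0 entry is the smallest cost-complexity-optimal
#' tree at alpha 0 (splits with zero risk reduction are already collapsed);
#' on separable data this is the grown tree itself.
#'
#' @param tree a [grow_tree()] result.
#' @return list of entries `list(alpha, n_leaves, rel_error, tree)`; also a
#'   `data.frame` summary in `attr(, "summary")`.
#' @export
prune_path <- function(tree) {
  r0 <- root_risk(tree)
  sched <- collapse_schedule(tree$root, max(r0, 1))
  entries <- lapply(seq_len(nrow(sched$entries)), function(i) {
    e <- sched$entries[i, ]
    list(alpha = e$alpha, n_leaves = as.integer(e$n_leaves),
         rel_error = e$rel_error,
         tree = cut_tree_at(tree$root, sched$calpha, e$alpha))
  })
  attr(entries, "summary") <- sched$entries
  entries
}

#' Prune a tree to a given size
#'
#' Picks the entry of the pruning path with the requested leaf count.
#'
#' @param tree a [grow_tree()] result.
#' @param size leaf count; must occur in the pruning path.
#' @return a `classification_tree` pruned to `size` leaves.
#' @export
prune_to_size <- function(tree, size) {
  path <- prune_path(tree)
  sizes <- vapply(path, function(e) as.integer(e$n_leaves), 0L)
  hit <- which(sizes == size)
  if (!length(hit)) stop("size ", size, " not in pruning path (sizes: ",
                         paste(sizes, collapse = ", "), ")")
  out <- tree
  out$root <- path[[hit[1]]]$tree
  out
}

#' Ten-fold cross-validated relative errors
#'
#' Grows the master tree and its pruning path, then for a seeded random
#' (non-stratified) k-fold partition grows a tree on each training set and
#' scores the held-out cases at the geometric-mean alphas of the master
#' path.  `xerror` is pooled held-out misclassification scaled by the
#' full-data root risk; `xstd` is the per-case-loss standard error of that
#' estimate on the same scale.
#'
#' @inheritParams grow_tree
#' @param k number of folds.
#' @param seed integer seed for the fold partition.
#' @return object of class `cv_result`: a data frame with columns `size`,
#'   `alpha`, `rel_error`, `xerror`, `xstd` (one row per master-path entry,
#'   full tree first).
#' @export
cross_validate <- function(X, y, params = cart_params(), k = 10, seed = 1) {
  y <- as_binary_response(y)
  n <- length(y)
  if (k > n) stop("k must not exceed the number of cases")
  master <- grow_tree(X, y, params)
  cv_with_master(master, X, y, params, k, seed)
}

cv_with_master <- function(master, X, y, params, k, seed, summ = NULL) {
  n <- length(y)
  if (is.null(summ))
    summ <- collapse_schedule(master$root, max(root_risk(master), 1))$entries
  m <- nrow(summ)
  alphas <- summ$alpha
  betas <- if (m == 1) 0 else
    c(sqrt(alphas[-m] * alphas[-1]), Inf)
  r0 <- root_risk(master)
  loss <- matrix(0, n, m)
  if (r0 > 0) {
    folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))
    for (f in seq_len(k)) {
      hold <- which(folds == f)
      fit <- grow_tree(X[-hold, , drop = FALSE], y[-hold], params)
      fr0 <- max(root_risk(fit), 1)
      fsched <- collapse_schedule(fit$root, fr0)
      newd <- X[hold, , drop = FALSE]
      for (j in seq_len(m)) {
        pred <- predict_cut(fit, newd, fsched$calpha, betas[j])
        loss[hold, j] <- as.numeric(pred != y[hold])
      }
    }
  }
  xerror <- colSums(loss) / max(r0, 1)
  p <- colMeans(loss)
  xstd <- sqrt(pmax(p * (1 - p), 0) / n) * n / max(r0, 1)
  out <- data.frame(size = summ$n_leaves, alpha = alphas,
                    rel_error = summ$rel_error, xerror = xerror, xstd = xstd)
  attr(out, "k") <- k
  attr(out, "seed") <- seed
  class(out) <- c("cv_result", "data.frame")
  out
}

#' Select tree size by the 1-SE rule
#'
#' Returns the smallest tree size whose cross-validated error is within one
#' standard error of the minimum.
#'
#' @param cv a [cross_validate()] result.
#' @return list with `size` and `alpha`.
#' @export
select_1se <- function(cv) {
  if (!nrow(cv)) stop("empty cross-validation result")
  emin <- min(cv$xerror)
  at_min <- which(cv$xerror <= emin + 1e-12)
  s_star <- cv$xstd[at_min[which.min(cv$size[at_min])]]
  ok <- which(cv$xerror <= emin + s_star + 1e-12)
  pick <- ok[which.min(cv$size[ok])]
  list(size = cv$size[pick], alpha = cv$alpha[pick])
}

#' Modal optimal tree over repeated cross-validations
#'
#' Runs `n_repeats` cross-validations with seeds `base_seed, base_seed + 1,
#' ...`, applies the 1-SE rule to each, takes the mode of the selected sizes
#' (ties go to the smaller size), and returns the full-data tree pruned to
#' that size.
#'
#' @inheritParams cross_validate
#' @param n_repeats number of repeated cross-validations.
#' @param base_seed first fold seed.
#' @return a `classification_tree` with attributes `modal_size` and
#'   `size_votes` (table of selected sizes).
#' @export
modal_optimal_tree <- function(X, y, params = cart_params(), k = 10,
                               n_repeats = 50, base_seed = 1) {
  y <- as_binary_response(y)
  master <- grow_tree(X, y, params)
  summ <- collapse_schedule(master$root, max(root_risk(master), 1))$entries
  sizes <- integer(n_repeats)
  for (i in seq_len(n_repeats)) {
    cv <- cv_with_master(master, X, y, params, k, base_seed + i - 1, summ)
    sizes[i] <- select_1se(cv)$size
  }
  votes <- table(sizes)
  modal <- min(as.integer(names(votes)[votes == max(votes)]))
  out <- prune_to_size(master, modal)
  attr(out, "modal_size") <- modal
  attr(out, "size_votes") <- votes
  out
}

#' Predict classes from a classification tree
#'
#' Cases are routed by the split rules (numeric: value below the threshold
#' goes left; categorical: value in the left set goes left); the leaf
#' majority class is returned.  A category unseen at a categorical split is
#' an error.
#'
#' @param object a `classification_tree`.
#' @param newdata data frame holding the tree's variables.
#' @param ... unused.
#' @return integer vector of 0/1 labels.
#' @export
predict.classification_tree <- function(object, newdata, ...) {
  miss <- setdiff(unique(tree_split_vars(object)), names(newdata))
  if (length(miss)) stop("newdata lacks variables: ", paste(miss, collapse = ", "))
  out <- integer(nrow(newdata))
  route <- function(node, idx) {
    if (!length(idx)) return()
    if (is_leaf(node)) { out[idx] <<- node$pred; return() }
    s <- node$split
    xv <- newdata[[s$var]]
    if (s$kind == "numeric") {
      go_left <- xv[idx] < s$threshold
    } else {
      vals <- as.character(xv[idx])
      unseen <- !(vals %in% c(s$left_set, s$right_set))
      if (any(unseen))
        stop("unseen category '", vals[unseen][1], "' at a split on ", s$var)
      go_left <- vals %in% s$left_set
    }
    route(node$left, idx[go_left])
    route(node$right, idx[!go_left])
  }
  route(object$root, seq_len(nrow(newdata)))
  out
}

tree_split_vars <- function(tree) {
  vars <- character()
  walk <- function(node) {
    if (is_leaf(node)) return()
    vars <<- c(vars, node$split$var)
    walk(node$left); walk(node$right)
  }
  walk(tree$root)
  vars
}

#' Split variables of a tree
#' @param tree a `classification_tree`.
#' @return character vector of unique split variables (pre-order).
#' @export
split_variables <- function(tree) unique(tree_split_vars(tree))

#' Classification performance of predictions
#'
#' Confusion counts and the derived rates, with "present" (1) as the
#' positive class: misclassification `(FN + FP) / n`, sensitivity
#' `TP / (TP + FN)`, specificity `TN / (TN + FP)`.
#'
#' @param pred predicted labels (0/1) or a `classification_tree` (then `X`
#'   must be given).
#' @param y_true true labels (0/1).
#' @param X data frame of predictors when `pred` is a tree.
#' @return object of class `model_evaluation`: list with `confusion`
#'   (TP, FN, TN, FP), `misclassification` (exact fraction),
#'   `misclassification_pct` (rounded to integer), `sensitivity`,
#'   `specificity`.
#' @export
evaluate_classification <- function(pred, y_true, X = NULL) {
  if (inherits(pred, "classification_tree")) pred <- predict(pred, X)
  y_true <- as_binary_response(y_true)
  pred <- as_binary_response(pred)
  if (!length(y_true) || length(pred) != length(y_true))
    stop("predictions and labels must be non-empty and of equal length")
  tp <- sum(pred == 1 & y_true == 1)
  fn <- sum(pred == 0 & y_true == 1)
  tn <- sum(pred == 0 & y_true == 0)
  fp <- sum(pred == 1 & y_true == 0)
  mis <- (fn + fp) / length(y_true)
  structure(list(confusion = c(TP = tp, FN = fn, TN = tn, FP = fp),
                 misclassification = mis,
                 misclassification_pct = round_half_up(100 * mis),
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_),
            class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf("misclassification %d%% | sensitivity %.2f | specificity %.2f\n",
              x$misclassification_pct, x$sensitivity, x$specificity))
  cat(sprintf("confusion: TP %d FN %d TN %d FP %d\n",
              x$confusion["TP"], x$confusion["FN"],
              x$confusion["TN"], x$confusion["FP"]))
  invisible(x)
}

#' @export
print.classification_tree <- function(x, ...) {
  fmt_node <- function(node, prefix, label) {
    n1 <- node$counts[2]
    cat(sprintf("%s%s n=%d (absent %d, present %d) -> %s\n", prefix, label,
                node$n, node$counts[1], n1,
                if (node$pred == 1) "present" else "absent"))
    if (is_leaf(node)) return()
    s <- node$split
    rule <- if (s$kind == "numeric")
      sprintf("%s >= %g -> right", s$var, s$threshold)
    else
      sprintf("%s in {%s} -> left", s$var, paste(s$left_set, collapse = ","))
    cat(sprintf("%s  split: %s (improvement %.3f)\n", prefix, rule,
                node$improvement))
    fmt_node(node$left, paste0(prefix, "    "), "L:")
    fmt_node(node$right, paste0(prefix, "    "), "R:")
  }
  cat("classification_tree, ", node_leaves(x$root), " leaves\n", sep = "")
  fmt_node(x$root, "", "root:")
  invisible(x)
}

# display rounding, half away from zero (print conventions round 0.925 up
# to 0.93; R's round() would give 0.92)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# evaluate code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
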