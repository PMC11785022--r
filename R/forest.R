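# Bootstrap-aggregated classification forest (CART with Gini splitting).
# Implemented here because the scoring pipeline needs a bagged forest with
# out-of-bag validation and no tree learner is available as a dependency.

gini_best_split <- function(x, y, k) {
  # best threshold on one feature; y integer classes 1..k
  o <- order(x)
  xs <- x[o]; ys <- y[o]
  n <- length(xs)
  counts <- matrix(0L, n, k)
  counts[cbind(seq_len(n), ys)] <- 1L
  cum <- apply(counts, 2, cumsum)                 # class counts left of split
  tot <- cum[n, ]
  nl <- seq_len(n - 1)
  left <- cum[nl, , drop = FALSE]
  right <- matrix(tot, n - 1, k, byrow = TRUE) - left
  gl <- 1 - rowSums(left^2) / nl^2
  gr <- 1 - rowSums(right^2) / (n - nl)^2
  imp <- (nl * gl + (n - nl) * gr) / n
  valid <- xs[nl] < xs[nl + 1]                    # only between distinct values
  if (!any(valid)) return(NULL)
  imp[!valid] <- Inf
  i <- which.min(imp)
  list(threshold = (xs[i] + xs[i + 1]) / 2, impurity = imp[i])
}

node_gini <- function(y, k) {
  p <- tabulate(y, k) / length(y)
  1 - sum(p^2)
}

grow_tree <- function(X, y, k, mtry, min_node = 5, max_depth = 14) {
  nodes <- list()
  grow <- function(idx, depth) {
    yi <- y[idx]
    pred <- which.max(tabulate(yi, k))
    g <- node_gini(yi, k)
    if (length(idx) < min_node || depth >= max_depth || g == 0) {
      nodes[[length(nodes) + 1]] <<- list(leaf = TRUE, pred = pred)
      return(length(nodes))
    }
    feats <- sample.int(ncol(X), mtry)
    best <- NULL
    for (f in feats) {
      s <- gini_best_split(X[idx, f], yi, k)
      if (!is.null(s) && (is.null(best) || s$impurity < best$impurity)) {
        best <- c(s, feature = f)
      }
    }
    if (is.null(best) || best$impurity >= g - 1e-12) {
      nodes[[length(nodes) + 1]] <<- list(leaf = TRUE, pred = pred)
      return(length(nodes))
    }
    id <- length(nodes) + 1
    nodes[[id]] <<- list(leaf = FALSE)            # placeholder, filled below
    go_left <- X[idx, best$feature] <= best$threshold
    left <- grow(idx[go_left], depth + 1)
    right <- grow(idx[!go_left], depth + 1)
    nodes[[id]] <<- list(leaf = FALSE, feature = best$feature,
                         threshold = best$threshold, left = left,
                         right = right, pred = pred)
    id
  }
  root <- grow(seq_len(nrow(X)), 0)
  list(nodes = nodes, root = root)
}

predict_tree <- function(tree, X) {
  n <- nrow(X)
  cur <- rep(tree$root, n)
  out <- integer(n)
  repeat {
    leaf <- vapply(tree$nodes[cur], `[[`, TRUE, "leaf")
    if (any(leaf)) {
      out[leaf] <- vapply(tree$nodes[cur[leaf]], function(nd) as.integer(nd$pred),
                          integer(1))
    }
    if (all(leaf)) break
    act <- which(!leaf)
    feats <- vapply(tree$nodes[cur[act]], function(nd) as.integer(nd$feature),
                    integer(1))
    thr <- vapply(tree$nodes[cur[act]], `[[`, 1, "threshold")
    go_left <- X[cbind(act, feats)] <= thr
    nxt <- vapply(tree$nodes[cur[act]], function(nd)
      as.integer(c(nd$left, nd$right)), integer(2))
    cur[act] <- ifelse(go_left, nxt[1, ], nxt[2, ])
  }
  out
}

#' Bagged classification forest
#'
#' Trains `n_trees` CART trees (Gini splitting, `mtry = ceiling(sqrt(p))`
#' features per split) on stratified bootstrap resamples and reports the
#' out-of-bag (OOB) error.
#'
#' @param X numeric feature matrix (no missing values).
#' @param y factor of class labels (at least 2 classes present).
#' @param n_trees number of trees (default 128).
#' @param mtry features tried per split (default `ceiling(sqrt(ncol(X)))`).
#' @param min_node minimum node size to attempt a split (default 5).
#' @param seed RNG seed for reproducibility.
#' @return object of class `bagged_forest` with `trees`, `classes`,
#'   `oob_error`, `oob_votes`.
#' @export
bagged_forest <- function(X, y, n_trees = 128, mtry = ceiling(sqrt(ncol(X))),
                          min_node = 5, seed = 1L) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("missing feature values in training rows")
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("training labels contain a single class")
  set.seed(seed)
  k <- nlevels(y)
  yi <- as.integer(y)
  n <- nrow(X)
  by_class <- split(seq_len(n), yi)
  votes <- matrix(0L, n, k)
  trees <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    boot <- unlist(lapply(by_class, function(ix)
      sample(ix, length(ix), replace = TRUE)), use.names = FALSE)
    oob <- setdiff(seq_len(n), unique(boot))
    tr <- grow_tree(X[boot, , drop = FALSE], yi[boot], k, mtry, min_node)
    trees[[b]] <- tr
    if (length(oob)) {
      p <- predict_tree(tr, X[oob, , drop = FALSE])
      votes[cbind(oob, p)] <- votes[cbind(oob, p)] + 1L
    }
  }
  seen <- rowSums(votes) > 0
  oob_pred <- max.col(votes, ties.method = "first")
  oob_error <- mean(oob_pred[seen] != yi[seen])
  structure(list(trees = trees, classes = levels(y), mtry = mtry,
                 oob_error = oob_error, oob_votes = votes),
            class = "bagged_forest")
}

#' @param object a `bagged_forest`.
#' @param newdata feature matrix or data.frame.
#' @param ... unused.
#' @return factor of predicted classes.
#' @rdname bagged_forest
#' @export
predict.bagged_forest <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  votes <- matrix(0L, nrow(X), length(object$classes))
  for (tr in object$trees) {
    p <- predict_tree(tr, X)
    votes[cbind(seq_len(nrow(X)), p)] <- votes[cbind(seq_len(nrow(X)), p)] + 1L
  }
  factor(object$classes[max.col(votes, ties.method = "first")],
         levels = object$classes)
}

#' @export
print.bagged_forest <- function(x, ...) {
  cat("<bagged_forest>", length(x$trees), "trees, classes:",
      paste(x$classes, collapse = "/"),
      sprintf("; OOB error %.3f\n", x$oob_error))
  invisible(x)
}
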