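# Bootstrap-aggregated regression trees (a regression random forest).
#
# Implemented in-package because no forest regressor is available in the
# supported dependency set. Classic construction: each tree is a CART
# regression tree grown on a bootstrap resample, choosing at every node the
# best variance-reducing split among `mtry` randomly drawn candidate
# features; the forest prediction is the mean over trees. Categorical
# predictors are handled as integer-coded levels (exact for the binary
# root-zone factor used here).

#' Fit a regression forest
#'
#' @param x data.frame of predictors (numeric, factor or character columns).
#' @param y numeric response.
#' @param n_trees number of trees (default 500).
#' @param mtry candidate features per split (default `max(1, floor(p/3))`,
#'   the regression-forest convention).
#' @param min_node minimum node size eligible for splitting (default 5).
#' @param max_depth maximum tree depth (default 16).
#' @param seed integer seed; fits are reproducible under a fixed seed.
#' @return An object of class `regression_forest`.
#' @export
regression_forest <- function(x, y, n_trees = 500, mtry = NULL,
                              min_node = 5, max_depth = 16, seed = 1L) {
  x <- as.data.frame(x)
  if (nrow(x) != length(y)) stop("nrow(x) != length(y)", call. = FALSE)
  if (any(!is.finite(y))) stop("`y` must be finite", call. = FALSE)
  enc <- encode_predictors(x)
  xm <- enc$matrix
  p <- ncol(xm)
  if (is.null(mtry)) mtry <- max(1L, floor(p / 3))
  mtry <- min(as.integer(mtry), p)
  n <- nrow(xm)

  if (n < 2) stop("need at least 2 training rows", call. = FALSE)
  trees <- with_seed(seed,
    .forest_grow(xm, y, as.integer(n_trees), mtry,
                 as.integer(min_node), as.integer(max_depth)))
  structure(c(flatten_trees(trees),
              list(encoding = enc$spec, n_trees = n_trees,
                   mtry = mtry, min_node = min_node, max_depth = max_depth,
                   seed = as.integer(seed), feature_names = colnames(xm))),
            class = "regression_forest")
}

# Concatenate per-tree node arrays into flat vectors (child pointers shifted
# by each tree's offset) so prediction can route every tree simultaneously.
flatten_trees <- function(trees) {
  sizes <- vapply(trees, function(t) length(t$var), 0L)
  offset <- c(0L, cumsum(sizes))[seq_along(trees)]
  shift <- function(ptr, off) ifelse(ptr > 0L, ptr + off, 0L)
  list(var = unlist(lapply(trees, `[[`, "var")),
       split = unlist(lapply(trees, `[[`, "split")),
       left = unlist(mapply(function(t, o) shift(t$left, o), trees, offset,
                            SIMPLIFY = FALSE)),
       right = unlist(mapply(function(t, o) shift(t$right, o), trees, offset,
                             SIMPLIFY = FALSE)),
       pred = unlist(lapply(trees, `[[`, "pred")),
       roots = offset + 1L)
}

# Column encoding: factors/characters -> integer level codes; levels stored
# so prediction uses the training mapping.
encode_predictors <- function(x, spec = NULL) {
  if (is.null(spec)) {
    spec <- lapply(x, function(col) {
      if (is.numeric(col)) NULL else levels(factor(col))
    })
  }
  if (!identical(sort(names(spec)), sort(names(x))))
    stop("prediction features do not match the training feature set",
         call. = FALSE)
  cols <- lapply(names(spec), function(nm) {
    col <- x[[nm]]
    if (is.null(spec[[nm]])) as.numeric(col)
    else {
      codes <- as.numeric(factor(as.character(col), levels = spec[[nm]]))
      if (any(is.na(codes) & !is.na(col)))
        stop(sprintf("unseen level in feature `%s`", nm), call. = FALSE)
      codes
    }
  })
  m <- do.call(cbind, cols)
  colnames(m) <- names(spec)
  if (any(!is.finite(m))) stop("all predictor values must be finite", call. = FALSE)
  list(matrix = m, spec = spec)
}

#' Predict from a regression forest
#'
#' @param object a [regression_forest()].
#' @param newdata data.frame with the training feature columns.
#' @param ... unused.
#' @return Numeric predictions (mean over trees). Row order is respected;
#'   predictions are invariant to row permutation.
#' @export
predict.regression_forest <- function(object, newdata, ...) {
  xm <- encode_predictors(as.data.frame(newdata), spec = object$encoding)$matrix
  n <- nrow(xm)
  # route every (row, tree) pair simultaneously through the flattened nodes
  node <- rep(object$roots, each = n)
  row <- rep.int(seq_len(n), length(object$roots))
  repeat {
    active <- object$var[node] != 0L
    if (!any(active)) break
    ai <- which(active)
    nd <- node[ai]
    goes_left <- xm[cbind(row[ai], object$var[nd])] <= object$split[nd]
    node[ai] <- ifelse(goes_left, object$left[nd], object$right[nd])
  }
  rowSums(matrix(object$pred[node], nrow = n)) / length(object$roots)
}

#' @export
print.regression_forest <- function(x, ...) {
  cat(sprintf("regression forest: %d trees, mtry %d, %d features\n",
              x$n_trees, x$mtry, length(x$feature_names)))
  invisible(x)
}
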