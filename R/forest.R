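## Bagged CART classification forest.
##
## No decision-tree package ships with this package's dependency set, so the
## forest is implemented here: ntree CART trees grown on bootstrap resamples,
## Gini impurity splits, a fresh random subset of mtry features considered at
## every split, trees grown to purity (or min_split / max_depth). Prediction
## is by unweighted vote; probabilities are vote fractions.

#' Fit a random forest classifier
#'
#' @param x numeric matrix, rows = examples.
#' @param y factor of class labels (its level order is kept and used for
#'   deterministic tie-breaking).
#' @param ntree number of trees; default 100.
#' @param mtry features considered per split; default floor(sqrt(ncol(x))).
#' @param min_split smallest node that may be split further; default 2
#'   (grow to purity).
#' @param max_depth hard depth cap; default 30.
#' @param seed RNG seed for bootstrap and feature sampling.
#' @return object of class \code{rf_model}.
#' @export
rf_fit <- function(x, y, ntree = 100, mtry = NULL, min_split = 2,
                   max_depth = 30, seed = NULL) {
  x <- as.matrix(x)
  y <- as.factor(y)
  stopifnot(nrow(x) == length(y))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  if (!is.null(seed)) set.seed(seed)
  yi <- as.integer(y)
  K <- nlevels(y)
  n <- nrow(x); p <- ncol(x)
  trees <- vector("list", ntree)
  for (b in seq_len(ntree)) {
    boot <- sample.int(n, n, replace = TRUE)
    trees[[b]] <- .grow_tree(x, yi, boot, K, mtry, min_split, max_depth)
  }
  structure(list(trees = trees, levels = levels(y), ntree = ntree,
                 mtry = mtry, min_split = min_split, max_depth = max_depth,
                 p = p),
            class = "rf_model")
}

## Grow one tree; returns a node matrix with columns
## feature, threshold, left, right, class (class > 0 marks a leaf).
.grow_tree <- function(x, yi, rows, K, mtry, min_split, max_depth) {
  nodes <- new.env(parent = emptyenv())
  nodes$tab <- matrix(0, 64L, 5L)
  nodes$n <- 0L
  new_node <- function() {
    nodes$n <- nodes$n + 1L
    if (nodes$n > nrow(nodes$tab))
      nodes$tab <- rbind(nodes$tab, matrix(0, nrow(nodes$tab), 5L))
    nodes$n
  }
  p <- ncol(x)
  grow <- function(rows, depth) {
    id <- new_node()
    cnt <- tabulate(yi[rows], K)
    if (sum(cnt > 0) == 1L || length(rows) < min_split || depth >= max_depth) {
      nodes$tab[id, 5L] <- which.max(cnt)
      return(id)
    }
    feats <- if (mtry >= p) seq_len(p) else sample.int(p, mtry)
    best <- NULL
    for (f in feats) {
      xf <- x[rows, f]
      ord <- order(xf)
      xs <- xf[ord]
      m <- length(rows)
      valid <- which(xs[-m] < xs[-1L])
      if (!length(valid)) next
      ys <- yi[rows][ord]
      cum <- vapply(seq_len(K), function(k) cumsum(ys == k),
                    numeric(m))[-m, , drop = FALSE]
      tot <- cnt
      ln <- seq_len(m - 1L)
      rn <- m - ln
      rsl <- rowSums(cum^2)
      rsr <- rowSums((rep(tot, each = m - 1L) - cum)^2)
      score <- (ln - rsl / ln) + (rn - rsr / rn)
      i <- valid[which.min(score[valid])]
      if (is.null(best) || score[i] < best$score)
        best <- list(score = score[i], f = f, thr = (xs[i] + xs[i + 1L]) / 2)
    }
    if (is.null(best)) {
      nodes$tab[id, 5L] <- which.max(cnt)
      return(id)
    }
    go_left <- x[rows, best$f] <= best$thr
    left <- grow(rows[go_left], depth + 1L)
    right <- grow(rows[!go_left], depth + 1L)
    nodes$tab[id, ] <- c(best$f, best$thr, left, right, 0)
    id
  }
  grow(rows, 0L)
  nodes$tab[seq_len(nodes$n), , drop = FALSE]
}

#' Predict with a random forest
#'
#' @param object an \code{rf_model}.
#' @param newdata numeric matrix with the training feature count.
#' @param type "class" for labels, "prob" for the vote-fraction matrix.
#' @param ... unused.
#' @return factor of predicted labels, or an n x K probability matrix.
#' @export
predict.rf_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p)
    stop("shape error: expected ", object$p, " features, got ", ncol(newdata))
  n <- nrow(newdata)
  K <- length(object$levels)
  votes <- matrix(0, n, K, dimnames = list(NULL, object$levels))
  for (tr in object$trees) {
    node <- rep(1L, n)
    repeat {
      act <- which(tr[node, 5L] == 0)
      if (!length(act)) break
      nd <- node[act]
      f <- tr[nd, 1L]
      left <- newdata[cbind(act, f)] <= tr[nd, 2L]
      node[act] <- ifelse(left, tr[nd, 3L], tr[nd, 4L])
    }
    cls <- tr[node, 5L]
    votes[cbind(seq_len(n), cls)] <- votes[cbind(seq_len(n), cls)] + 1
  }
  if (type == "prob") return(votes / object$ntree)
  factor(object$levels[max.col(votes, ties.method = "first")],
         levels = object$levels)
}

#' @export
print.rf_model <- function(x, ...) {
  cat(sprintf("<rf_model> %d trees, mtry %d, %d features, classes: %s\n",
              x$ntree, x$mtry, x$p, paste(x$levels, collapse = ", ")))
  invisible(x)
}
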