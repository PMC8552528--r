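# Orthogonalized PLS discriminant analysis for a binary outcome: y-orthogonal
# variation is removed from the (autoscaled) predictor matrix before a single
# predictive PLS component is extracted; classification thresholds the
# predictive score; VIP comes from the predictive-component weights.

#' Fit an O-PLS-DA model
#'
#' Orthogonal-projection decomposition: starting from column-autoscaled
#' `X` and centered class labels, `n_orth` components orthogonal to the
#' outcome are removed (weights `p - (w'p) w` per orthogonal step), then one
#' predictive component is extracted from the filtered matrix. The
#' classification threshold on the predictive score maximizes training
#' balanced accuracy. VIP is computed from the predictive-component weights
#' (for a single component, `VIP_j = sqrt(K * w_j^2 / sum(w^2))`, so the mean
#' squared VIP is 1).
#'
#' @param X Numeric matrix (observations x variables), autoscaled columns
#'   (re-autoscaled internally; constant columns are dropped with a warning).
#' @param y Binary outcome (logical, 0/1, or 2-level factor).
#' @param n_orth Number of y-orthogonal components to remove (default 1).
#' @return Object of class `oplsda`: scaling constants, orthogonal weights /
#'   loadings, predictive weights `w`, scores, threshold, `vip`, training
#'   metrics.
#' @export
fit_oplsda <- function(X, y, n_orth = 1) {
  y <- .binary01(y)
  if (min(table(y)) < 5) stop("both classes need >= 5 members")
  X <- as.matrix(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  keep <- is.finite(sdv) & sdv > 1e-12
  if (any(!keep)) {
    warning("constant column(s) removed: ",
            paste(colnames(X)[!keep], collapse = ", "))
  }
  X <- X[, keep, drop = FALSE]
  mu <- mu[keep]; sdv <- sdv[keep]
  if (n_orth >= min(dim(X))) stop("n_orth must be below the rank of X")
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  yc <- y - mean(y)

  W_orth <- P_orth <- NULL
  Xf <- Xs
  for (j in seq_len(n_orth)) {
    w <- drop(crossprod(Xf, yc))
    w <- w / sqrt(sum(w^2))
    t_p <- drop(Xf %*% w)
    p <- drop(crossprod(Xf, t_p)) / sum(t_p^2)
    w_o <- p - sum(w * p) * w
    nw <- sqrt(sum(w_o^2))
    if (nw < 1e-10) break  # no y-orthogonal variation left
    w_o <- w_o / nw
    t_o <- drop(Xf %*% w_o)
    p_o <- drop(crossprod(Xf, t_o)) / sum(t_o^2)
    Xf <- Xf - tcrossprod(t_o, p_o)
    W_orth <- cbind(W_orth, w_o)
    P_orth <- cbind(P_orth, p_o)
  }
  w <- drop(crossprod(Xf, yc))
  w <- w / sqrt(sum(w^2))
  t_pred <- drop(Xf %*% w)
  K <- ncol(Xs)
  vip <- sqrt(K * w^2 / sum(w^2))
  names(vip) <- colnames(Xs)

  thr <- .best_threshold(t_pred, y)
  pred <- as.integer(t_pred > thr$threshold)
  model <- structure(
    list(mu = mu, sd = sdv, keep = keep, W_orth = W_orth, P_orth = P_orth,
         w = w, n_orth = if (is.null(W_orth)) 0 else ncol(W_orth),
         scores = t_pred, threshold = thr$threshold,
         flip = thr$flip, vip = vip, y = y,
         train_error = mean(.classify_scores(t_pred, thr) != y)),
    class = "oplsda"
  )
  model
}

.binary01 <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(as.logical(y) | y == 1)
  if (!all(y %in% c(0L, 1L))) stop("y must be binary")
  y
}

# threshold maximizing balanced accuracy; also decides class orientation
.best_threshold <- function(scores, y) {
  cand <- sort(unique(scores))
  cand <- c(cand[1] - 1, (cand[-1] + cand[-length(cand)]) / 2,
            cand[length(cand)] + 1)
  best <- list(ba = -Inf, threshold = cand[1], flip = FALSE)
  for (th in cand) {
    for (flip in c(FALSE, TRUE)) {
      pred <- if (flip) as.integer(scores <= th) else as.integer(scores > th)
      sens <- sum(pred == 1 & y == 1) / max(sum(y == 1), 1)
      spec <- sum(pred == 0 & y == 0) / max(sum(y == 0), 1)
      ba <- (sens + spec) / 2
      if (ba > best$ba) best <- list(ba = ba, threshold = th, flip = flip)
    }
  }
  best
}

.classify_scores <- function(scores, thr) {
  if (thr$flip) as.integer(scores <= thr$threshold)
  else as.integer(scores > thr$threshold)
}

#' Predict classes from an O-PLS-DA model
#'
#' Applies the training autoscaling, removes the stored orthogonal
#' components, projects onto the predictive weights and thresholds.
#'
#' @param object An `oplsda` model.
#' @param newdata Matrix with the training columns.
#' @param ... Unused.
#' @return List: `scores`, `class` (0/1 integers).
#' @export
predict.oplsda <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$keep, drop = FALSE]
  Xs <- sweep(sweep(X, 2, object$mu), 2, object$sd, "/")
  if (object$n_orth > 0) {
    for (j in seq_len(object$n_orth)) {
      t_o <- drop(Xs %*% object$W_orth[, j])
      Xs <- Xs - tcrossprod(t_o, object$P_orth[, j])
    }
  }
  sc <- drop(Xs %*% object$w)
  list(scores = sc,
       class = .classify_scores(sc, list(threshold = object$threshold,
                                         flip = object$flip)))
}

#' Holdout evaluation and permutation test
#'
#' Observed metrics come from one stratified 90/10 split: the model is built
#' from 90% of the observations and predicts the rest (error rate,
#' sensitivity, specificity). For each permutation the labels are shuffled, a
#' fresh random 90/10 split is drawn, an independent model fitted, and the
#' holdout error recorded; the p value is the smoothed proportion of
#' permutations with classification error at or below the observed one,
#' `(1 + #{e_perm <= e_obs}) / (n_perm + 1)`, never below `1/(n_perm + 1)`.
#'
#' @param X Predictor matrix.
#' @param y Binary outcome.
#' @param n_orth Orthogonal components (default 1).
#' @param n_perm Number of permutations (default 1000).
#' @param holdout Holdout fraction (default 0.10).
#' @param seed Integer seed.
#' @return List: `error_rate`, `sensitivity`, `specificity`, `perm_errors`,
#'   `p_value`.
#' @export
evaluate_and_permute <- function(X, y, n_orth = 1, n_perm = 1000,
                                 holdout = 0.10, seed = 1L) {
  y <- .binary01(y)
  n <- length(y)
  if (n < 20) stop("need n >= 20")
  split_once <- function(yy, stratified) {
    for (attempt in 1:100) {
      test <- if (stratified) {
        unlist(lapply(split(seq_len(n), yy), function(ix) {
          sample(ix, max(1, round(length(ix) * holdout)))
        }))
      } else {
        sample(seq_len(n), max(2, round(n * holdout)))
      }
      train <- setdiff(seq_len(n), test)
      if (length(unique(yy[train])) == 2) return(list(train = train,
                                                      test = test))
    }
    stop("could not draw a holdout with both classes in training")
  }
  holdout_error <- function(yy, stratified) {
    sp <- split_once(yy, stratified)
    fit <- fit_oplsda(X[sp$train, , drop = FALSE], yy[sp$train],
                      n_orth = n_orth)
    pred <- predict(fit, X[sp$test, , drop = FALSE])$class
    truth <- yy[sp$test]
    list(err = mean(pred != truth),
         sens = sum(pred == 1 & truth == 1) / max(sum(truth == 1), 1),
         spec = sum(pred == 0 & truth == 0) / max(sum(truth == 0), 1))
  }
  with_seed(derive_seed(seed, "analysis") + 77L, {
    obs <- holdout_error(y, stratified = TRUE)
    perm_errors <- vapply(seq_len(n_perm), function(b) {
      holdout_error(sample(y), stratified = FALSE)$err
    }, numeric(1))
  })
  p <- (1 + sum(perm_errors <= obs$err)) / (n_perm + 1)
  list(error_rate = obs$err, sensitivity = obs$sens, specificity = obs$spec,
       perm_errors = perm_errors, p_value = p)
}
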