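#' Sparse partial least squares discriminant analysis
#'
#' Supervised marker discovery for imputed segment-identity groups. The class
#' labels are one-hot encoded and, per component, the feature weight vector
#' maximizing covariance between feature space and class space is computed
#' from the singular structure of the cross-covariance matrix; sparsity is
#' imposed by retaining only the `keepX` largest-magnitude weights (signs
#' kept, vector renormalized to unit norm) — the keepX semantics of
#' lasso-style sparse PLS. Samples are scored on each component and the
#' matrices deflated before the next one; classification is by nearest class
#' centroid in score space.
#'
#' @param X numeric matrix, features (orthogroups) in rows, samples in
#'   columns — z-score scale, as produced by the integration step.
#' @param y class labels, one per sample (factor or character).
#' @param keepX number of features retained per component (scalar recycled,
#'   or one value per component). Values above the feature count are clipped
#'   with a warning.
#' @param ncomp number of components.
#' @return object of class `splsda_model`: `weights` (features x ncomp,
#'   exactly keepX nonzeros per column, unit norm), `scores` (samples x
#'   ncomp), `loadings`, `centroids` (class centroids in score space),
#'   `selected` (list of selected feature sets per component), `keepX`,
#'   `feature_means`, `classes`, `y`.
#' @export
fit_splsda <- function(X, y, keepX = nrow(X), ncomp = 2) {
  X <- as.matrix(X)
  p <- nrow(X)
  n <- ncol(X)
  y <- factor(y)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (any(table(y) < 2)) stop("every class needs at least 2 samples")
  if (is.null(rownames(X))) rownames(X) <- paste0("f", seq_len(p))
  keepX <- rep_len(as.integer(keepX), ncomp)
  if (any(keepX > p)) {
    warning("keepX exceeds the number of features; clipped")
    keepX <- pmin(keepX, p)
  }
  Y <- stats::model.matrix(~0 + y)
  colnames(Y) <- levels(y)
  Xc <- t(X)                       # samples x features
  mu <- colMeans(Xc)
  Xc <- sweep(Xc, 2, mu)
  Yc <- sweep(Y, 2, colMeans(Y))

  W <- matrix(0, p, ncomp, dimnames = list(rownames(X), NULL))
  P <- matrix(0, p, ncomp, dimnames = list(rownames(X), NULL))
  Tm <- matrix(0, n, ncomp, dimnames = list(colnames(X), NULL))
  selected <- vector("list", ncomp)
  for (h in seq_len(ncomp)) {
    M <- crossprod(Xc, Yc)                       # p x K cross-covariance
    w <- svd(M, nu = 1, nv = 0)$u[, 1]
    if (w[which.max(abs(w))] < 0) w <- -w        # deterministic sign
    if (keepX[h] < p) {
      thr <- sort(abs(w), decreasing = TRUE)[keepX[h]]
      w[abs(w) < thr] <- 0
      # exact keepX nonzeros even under ties: keep the first keepX by
      # magnitude then feature name
      nz <- which(w != 0)
      if (length(nz) > keepX[h]) {
        ord <- nz[order(-abs(w[nz]), rownames(X)[nz])]
        w[ord[-seq_len(keepX[h])]] <- 0
      }
    }
    w <- w / sqrt(sum(w^2))
    tt <- drop(Xc %*% w)
    pl <- drop(crossprod(Xc, tt)) / sum(tt^2)
    cl <- drop(crossprod(Yc, tt)) / sum(tt^2)
    Xc <- Xc - tcrossprod(tt, pl)
    Yc <- Yc - tcrossprod(tt, cl)
    W[, h] <- w
    P[, h] <- pl
    Tm[, h] <- tt
    selected[[h]] <- rownames(X)[w != 0]
  }
  # rotation giving scores directly from centered data: X W (P'W)^-1
  Wstar <- W %*% solve(crossprod(P, W))
  centroids <- apply(Tm, 2, function(t) tapply(t, y, mean))
  if (is.null(dim(centroids)))
    centroids <- matrix(centroids, nrow = nlevels(y),
                        dimnames = list(levels(y), NULL))
  structure(list(weights = W, loadings = P, scores = Tm, rotation = Wstar,
                 centroids = centroids, selected = selected,
                 keepX = keepX, ncomp = ncomp, feature_means = mu,
                 classes = levels(y), y = y, optimal_set = NULL),
            class = "splsda_model")
}

#' @export
print.splsda_model <- function(x, ...) {
  cat(sprintf("splsda_model: %d components, keepX = %s, %d classes (%s)\n",
              x$ncomp, paste(x$keepX, collapse = "/"),
              length(x$classes), paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Predict class labels for new samples
#'
#' Projects new samples into the model's score space via the PLS rotation
#' and assigns the nearest class centroid (Euclidean distance over all
#' components).
#'
#' @param object an `splsda_model`.
#' @param newdata features x samples matrix on the training feature set.
#' @param ... unused.
#' @return factor of predicted class labels.
#' @export
predict.splsda_model <- function(object, newdata, ...) {
  Xn <- t(as.matrix(newdata))
  Xn <- sweep(Xn, 2, object$feature_means)
  sc <- Xn %*% object$rotation
  d2 <- vapply(seq_len(nrow(object$centroids)), function(k)
    rowSums(sweep(sc, 2, object$centroids[k, ])^2),
    numeric(nrow(sc)))
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1)
  factor(object$classes[apply(d2, 1, which.min)], levels = object$classes)
}

.balanced_error <- function(truth, pred) {
  truth <- factor(truth)
  per_class <- vapply(levels(truth), function(cl) {
    sel <- truth == cl
    if (!any(sel)) return(NA_real_)
    mean(pred[sel] != cl)
  }, numeric(1))
  mean(per_class, na.rm = TRUE)
}

#' Cross-validated keepX selection
#'
#' Balanced classification error for every candidate `keepX` under
#' leave-one-species-out cross-validation (samples from one species are
#' never split across training and test, since within-species samples are
#' not exchangeable). The chosen keepX is the smallest whose error is within
#' `tolerance` of the minimum — the "optimal sufficient" marker count. With
#' fewer than two species a stratified k-fold is used instead, with a
#' warning.
#'
#' @param X features x samples matrix.
#' @param y class labels per sample.
#' @param grid candidate keepX values.
#' @param species species id per sample (the CV fold unit).
#' @param ncomp components per fitted model.
#' @param tolerance error slack over the minimum.
#' @param n_folds folds for the stratified fallback.
#' @return list with `keepX` (chosen), `error` (named numeric error curve)
#'   and `folds_used`.
#' @export
cv_select_keepX <- function(X, y, grid, species = NULL, ncomp = 2,
                            tolerance = 0.02, n_folds = 5) {
  X <- as.matrix(X)
  y <- factor(y)
  if (!is.null(species) && length(unique(species)) >= 2) {
    folds <- split(seq_len(ncol(X)), species)
    folds_used <- "leave-one-species-out"
  } else {
    warning("fewer than 2 species; falling back to stratified k-fold CV")
    folds <- split(seq_len(ncol(X)),
                   unsplit(lapply(split(seq_along(y), y), function(ix)
                     rep_len(seq_len(n_folds), length(ix))), y))
    folds_used <- sprintf("stratified %d-fold", n_folds)
  }
  err <- vapply(grid, function(kx) {
    fe <- vapply(folds, function(test) {
      train <- setdiff(seq_len(ncol(X)), test)
      if (nlevels(droplevels(y[train])) < 2) return(NA_real_)
      fit <- fit_splsda(X[, train, drop = FALSE], droplevels(y[train]),
                        keepX = kx, ncomp = ncomp)
      pred <- predict(fit, X[, test, drop = FALSE])
      .balanced_error(droplevels(y[test]), as.character(pred))
    }, numeric(1))
    mean(fe, na.rm = TRUE)
  }, numeric(1))
  names(err) <- grid
  chosen <- grid[err <= min(err) + tolerance][1]
  list(keepX = chosen, error = err, folds_used = folds_used)
}

#' Rank discriminant markers
#'
#' Features ranked by absolute weight on component 1 (component 2 breaking
#' ties), zero-weight features omitted, with a flag for membership in the
#' optimal sufficient discriminant set (the component-1 selection at the
#' cross-validated keepX, when one is attached to the model).
#'
#' @param model an `splsda_model`, optionally carrying `optimal_set`.
#' @return data.frame: `feature`, `weight_comp1`, `weight_comp2`, `rank`,
#'   `optimal`.
#' @export
rank_markers <- function(model) {
  w1 <- model$weights[, 1]
  w2 <- if (model$ncomp >= 2) model$weights[, 2] else rep(0, length(w1))
  keep <- w1 != 0 | w2 != 0
  df <- data.frame(feature = names(w1)[keep],
                   weight_comp1 = unname(w1[keep]),
                   weight_comp2 = unname(w2[keep]))
  df <- df[order(-abs(df$weight_comp1), -abs(df$weight_comp2), df$feature), ]
  df$rank <- seq_len(nrow(df))
  df$optimal <- if (is.null(model$optimal_set)) NA else
    df$feature %in% model$optimal_set
  rownames(df) <- NULL
  df
}
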