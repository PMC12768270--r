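#' Effective rank of a symmetric matrix
#'
#' Number of eigenvalues exceeding a small positive threshold. The default
#' threshold is exp(-13) (~2.26e-6), applied to the eigenvalues of the
#' correlation matrix being iterated; 1e-13 is a supported alternative for a
#' stricter notion of numerical rank.
#'
#' @param M symmetric numeric matrix.
#' @param threshold positive cutoff on the eigenvalues.
#' @return integer count of eigenvalues above the threshold.
#' @export
effective_rank <- function(M, threshold = exp(-13)) {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stop("M must be a square matrix")
  if (any(!is.finite(M))) stop("M must be finite")
  if (max(abs(M - t(M))) > 1e-8)
    stop("M is not symmetric within tolerance")
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sum(ev > threshold)
}

#' Iterated correlation to rank 2
#'
#' The first half of Rank-2 Elliptical (R2E) seriation: start from the
#' Pearson correlation matrix between items (rows of `X`), then repeatedly
#' take the correlation matrix of that matrix's rows, until the effective
#' rank drops to 2 or below. On data with an underlying one-dimensional
#' (Robinson) order this contracts quickly — a handful of iterations — onto
#' a rank-2 matrix whose singular vectors trace an ellipse.
#'
#' @param X numeric matrix, items in rows, features in columns; or an
#'   already-computed symmetric correlation matrix (detected by symmetry and
#'   unit diagonal), which is then used as the starting point.
#' @param threshold eigenvalue cutoff passed to [effective_rank()].
#' @param max_iter iteration cap.
#' @return list with `matrix` (the first rank-<=2 correlation matrix),
#'   `rank_trajectory` (effective rank after each round, starting at the
#'   initial correlation matrix) and `iterations_used`.
#' @export
iterate_correlation <- function(X, threshold = exp(-13), max_iter = 50) {
  X <- as.matrix(X)
  if (nrow(X) < 3) stop("need at least 3 items to seriate")
  is_corr <- nrow(X) == ncol(X) && max(abs(X - t(X))) < 1e-10 &&
    max(abs(diag(X) - 1)) < 1e-10
  if (is_corr) {
    R <- X
  } else {
    sds <- apply(X, 1, stats::sd)
    if (any(sds == 0))
      stop("constant item row(s): ",
           paste(rownames(X)[sds == 0], collapse = ", "))
    R <- stats::cor(t(X))
  }
  R0 <- R
  traj <- effective_rank(R, threshold)
  iter <- 0L
  degenerate <- FALSE
  while (traj[length(traj)] > 2) {
    if (iter >= max_iter) {
      err <- simpleError(sprintf(
        "correlation iteration did not reach rank 2 in %d iterations", max_iter))
      err$rank_trajectory <- traj
      stop(err)
    }
    sds <- apply(R, 2, stats::sd)
    if (any(sds == 0))
      stop("item(s) became constant during iteration: ",
           paste(colnames(R)[sds == 0], collapse = ", "))
    Rn <- stats::cor(R)
    rk <- effective_rank(Rn, threshold)
    if (rk < 2) {
      # over-contraction: the next iterate collapses past rank 2 to a line,
      # where angular order is lost; keep the last matrix above rank 2 and
      # let the caller order on its leading two singular vectors
      degenerate <- TRUE
      break
    }
    R <- Rn
    iter <- iter + 1L
    traj <- c(traj, rk)
  }
  list(matrix = R, rank_trajectory = traj, iterations_used = iter,
       degenerate = degenerate, initial = R0)
}

#' Order items on the rank-2 ellipse
#'
#' The second half of R2E seriation: the left singular vectors of a rank-2
#' correlation matrix fall on an ellipse; each item's angular position
#' (atan2 of its two singular-vector coordinates) induces a circular order.
#' The circle is cut at the largest angular gap between consecutive items —
#' the natural series start — and the traversal direction is fixed
#' deterministically: if an `anchor` item is supplied it must land in the
#' first half of the order (use the known anterior-most segment to orient a
#' gut series); otherwise the orientation with the lexicographically smaller
#' first item id is taken.
#'
#' @param R2 symmetric correlation matrix of effective rank <= 2 (from
#'   [iterate_correlation()]).
#' @param anchor optional item id to place in the first half.
#' @param threshold eigenvalue cutoff used to verify the rank precondition.
#' @param score_matrix similarity matrix on which ambiguous cut candidates
#'   are scored by Robinson-violation count (defaults to `R2`; `seriate_r2e`
#'   passes the initial correlation matrix).
#' @return an object of class `r2e_seriation`: `permutation` (1-based index
#'   order into the input rows), `items` (ids in seriation order), `angles`
#'   (radians, per input item), `start_gap` (largest angular gap, radians),
#'   `direction` (+1 counterclockwise / -1 clockwise) and `anchor_used`.
#' @export
elliptical_order <- function(R2, anchor = NULL, threshold = exp(-13),
                             score_matrix = R2) {
  if (effective_rank(R2, threshold) > 2)
    stop("input has effective rank > 2; run iterate_correlation first")
  .ellipse_order_core(R2, anchor, score_matrix = score_matrix)
}

# per-row Robinson violation count of similarity matrix S: under a correct
# order every row decays monotonically away from the diagonal
.robinson_score <- function(S) {
  n <- nrow(S)
  v <- 0L
  for (i in seq_len(n)) {
    if (i < n) v <- v + sum(diff(S[i, i:n]) > 1e-12)
    if (i > 1) v <- v + sum(diff(S[i, i:1]) > 1e-12)
  }
  v
}

# angular ordering on the leading two left singular vectors; no rank guard
# (used directly when the iteration stops just above rank 2, see
# iterate_correlation's over-contraction fallback). The circle is cut at a
# large angular gap; when several gaps are comparable (the ellipse can close
# on itself for strongly decaying series, leaving the true endpoint gap no
# larger than internal ones), the candidate cut minimizing the Robinson
# violation count of the reordered score matrix wins.
.ellipse_order_core <- function(R2, anchor = NULL, score_matrix = R2) {
  n <- nrow(R2)
  ids <- rownames(R2)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  U <- svd(R2, nu = 2, nv = 0)$u
  # sign convention: make each singular vector's largest-magnitude entry
  # positive so the angles (hence the cut) are reproducible across BLAS
  for (j in 1:2) if (U[which.max(abs(U[, j])), j] < 0) U[, j] <- -U[, j]
  angles <- atan2(U[, 2], U[, 1])
  ord <- order(angles, ids)
  a <- angles[ord]
  gaps <- c(diff(a), a[1] + 2 * pi - a[n])
  cand <- which(gaps >= 0.5 * max(gaps))
  cand <- cand[order(-gaps[cand])]
  if (length(cand) > 12) cand <- cand[1:12]
  rotation_at <- function(cut) {
    start <- if (cut == n) 1L else cut + 1L
    ord[c(seq(start, n), if (start > 1) seq(1, start - 1))]
  }
  if (length(cand) > 1) {
    scores <- vapply(cand, function(cut)
      .robinson_score(score_matrix[rotation_at(cut), rotation_at(cut)]),
      integer(1))
    # ties go to the larger gap (candidates are gap-sorted already)
    cand <- cand[which.min(scores)]
  }
  cut <- cand[1]
  fwd <- rotation_at(cut)
  bwd <- rev(fwd)
  if (!is.null(anchor)) {
    if (!anchor %in% ids) stop("anchor item not found: ", anchor)
    pf <- match(anchor, ids[fwd])
    perm <- if (pf <= n + 1 - pf) fwd else bwd
    direction <- if (pf <= n + 1 - pf) 1L else -1L
  } else {
    take_fwd <- ids[fwd[1]] <= ids[fwd[n]]
    perm <- if (take_fwd) fwd else bwd
    direction <- if (take_fwd) 1L else -1L
  }
  structure(list(permutation = perm, items = ids[perm],
                 angles = stats::setNames(angles, ids),
                 start_gap = gaps[cut], direction = direction,
                 anchor_used = anchor, iterations_used = NA_integer_,
                 rank_trajectory = NA_integer_),
            class = "r2e_seriation")
}

#' Rank-2 Elliptical (R2E) seriation
#'
#' Full R2E seriation of the rows or columns of a data matrix: iterate the
#' Pearson correlation matrix to rank 2 ([iterate_correlation()]), then read
#' the linear order off the ellipse traced by the left singular vectors
#' ([elliptical_order()]). Recovers the ordering of a Robinson-structured
#' similarity matrix — e.g., gut segments by anteroposterior position, or
#' genes by the position of their expression peak.
#'
#' @param X numeric matrix (or a precomputed correlation matrix, see
#'   [iterate_correlation()]).
#' @param axis seriate `"rows"` (default) or `"columns"`.
#' @param anchor optional item id to orient the order (first half).
#' @param threshold eigenvalue cutoff defining rank.
#' @param max_iter iteration cap for the correlation iteration.
#' @return an `r2e_seriation` (see [elliptical_order()]) with the iteration
#'   count and rank trajectory filled in.
#' @export
seriate_r2e <- function(X, axis = c("rows", "columns"), anchor = NULL,
                        threshold = exp(-13), max_iter = 50) {
  axis <- match.arg(axis)
  X <- as.matrix(X)
  if (axis == "columns") X <- t(X)
  it <- iterate_correlation(X, threshold = threshold, max_iter = max_iter)
  res <- if (isTRUE(it$degenerate))
    .ellipse_order_core(it$matrix, anchor, score_matrix = it$initial)
  else elliptical_order(it$matrix, anchor = anchor, threshold = threshold,
                        score_matrix = it$initial)
  res$iterations_used <- it$iterations_used
  res$rank_trajectory <- it$rank_trajectory
  res$degenerate <- it$degenerate
  res
}

#' @export
print.r2e_seriation <- function(x, ...) {
  cat(sprintf("R2E seriation of %d items (%d correlation iterations, rank trajectory %s)\n",
              length(x$permutation), x$iterations_used,
              paste(x$rank_trajectory, collapse = " -> ")))
  cat("order: ", paste(utils::head(x$items, 8), collapse = ", "),
      if (length(x$items) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Seriation-guided constrained hierarchical clustering
#'
#' Partitions a seriation order into `k` contiguous blocks by agglomerative
#' merging restricted to adjacent blocks; merge cost is average linkage on
#' the correlation distance (1 - correlation). Because merges respect the
#' seriation, blocks are contiguous stretches of the R2E order.
#'
#' @param order an `r2e_seriation` (or character vector of item ids in
#'   order).
#' @param D item-item correlation matrix (dimnames = item ids).
#' @param k target number of blocks.
#' @return list with `blocks` (list of item-id vectors, in seriation order)
#'   and `membership` (named integer vector, block id per item in seriation
#'   order).
#' @export
constrained_cluster <- function(order, D, k) {
  items <- if (inherits(order, "r2e_seriation")) order$items else
    as.character(order)
  n <- length(items)
  if (k < 1) stop("k must be at least 1")
  if (k > n) stop("k cannot exceed the number of items")
  path <- .constrained_merge_path(items, D)
  blocks <- path$levels[[k]]
  membership <- integer(n)
  for (b in seq_along(blocks)) membership[blocks[[b]]] <- b
  names(membership) <- items
  list(blocks = lapply(blocks, function(ix) items[ix]),
       membership = membership, merge_costs = path$costs)
}

# full adjacent-merge agglomeration path: levels[[k]] = block structure with
# k blocks; costs[k] = average-linkage cost of the merge reducing k to k-1
.constrained_merge_path <- function(items, D) {
  n <- length(items)
  dd <- 1 - D[items, items, drop = FALSE]
  blocks <- as.list(seq_len(n))
  levels <- vector("list", n)
  levels[[n]] <- blocks
  costs <- rep(NA_real_, n)
  while (length(blocks) > 1) {
    k <- length(blocks)
    cost_i <- vapply(seq_len(k - 1), function(i)
      mean(dd[blocks[[i]], blocks[[i + 1]], drop = FALSE]), numeric(1))
    i <- which.min(cost_i)
    costs[k] <- cost_i[i]
    blocks[[i]] <- c(blocks[[i]], blocks[[i + 1]])
    blocks[[i + 1]] <- NULL
    levels[[k - 1]] <- blocks
  }
  list(levels = levels, costs = costs)
}

#' Assemble a Generalized Association Plot bundle
#'
#' Packages the three matrices of a GAP display — the segment-segment
#' correlation matrix, the gene-gene correlation matrix, and the expression
#' matrix — under one consistent pair of seriation orderings, ready for
#' export or plotting. No new computation is performed.
#'
#' @param expr expression matrix, genes x segments.
#' @param gene_order `r2e_seriation` (or id vector) for the rows.
#' @param segment_order `r2e_seriation` (or id vector) for the columns.
#' @param gene_cor,segment_cor correlation matrices; computed as Spearman
#'   correlations of `expr` if missing.
#' @return list of class `gap_bundle`.
#' @export
build_gap <- function(expr, gene_order, segment_order,
                      gene_cor = NULL, segment_cor = NULL) {
  g <- if (inherits(gene_order, "r2e_seriation")) gene_order$items else gene_order
  s <- if (inherits(segment_order, "r2e_seriation")) segment_order$items else
    segment_order
  if (is.null(gene_cor)) gene_cor <- stats::cor(t(expr), method = "spearman")
  if (is.null(segment_cor)) segment_cor <- stats::cor(expr, method = "spearman")
  stopifnot(setequal(g, rownames(expr)), setequal(s, colnames(expr)))
  structure(list(expression = expr[g, s, drop = FALSE],
                 gene_cor = gene_cor[g, g, drop = FALSE],
                 segment_cor = segment_cor[s, s, drop = FALSE],
                 gene_order = g, segment_order = s),
            class = "gap_bundle")
}

#' Write a GAP bundle to a directory of TSVs plus a JSON ordering file
#'
#' @param bundle a [build_gap()] result.
#' @param dir output directory.
#' @export
write_gap_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counts_tsv(bundle$expression, file.path(dir, "expression.tsv"))
  write_counts_tsv(bundle$gene_cor, file.path(dir, "gene_cor.tsv"))
  write_counts_tsv(bundle$segment_cor, file.path(dir, "segment_cor.tsv"))
  jsonlite::write_json(list(gene_order = bundle$gene_order,
                            segment_order = bundle$segment_order),
                       file.path(dir, "orderings.json"))
  invisible(dir)
}
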