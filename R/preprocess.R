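#' Filter lowly expressed genes
#'
#' Keeps genes with at least `min_count` raw counts in at least `min_samples`
#' samples; the conventional bulk RNA-seq detectability filter, with the
#' sample threshold defaulting to the number of replicates so a gene must be
#' detectable in at least one full segment's worth of samples.
#'
#' @param ds raw-stage [expression_dataset()].
#' @param min_count minimum count per sample.
#' @param min_samples minimum number of samples reaching `min_count`;
#'   defaults to the number of replicate levels in the metadata.
#' @return filtered-stage dataset, gene order preserved.
#' @export
filter_low_expression <- function(ds, min_count = 10, min_samples = NULL) {
  if (is.null(min_samples))
    min_samples <- length(unique(ds$meta$replicate))
  if (min_samples > ncol(ds$x))
    stop("min_samples exceeds the number of samples")
  keep <- rowSums(ds$x >= min_count) >= min_samples
  if (!any(keep)) warning("no genes survive the expression filter")
  ds$x <- ds$x[keep, , drop = FALSE]
  .advance_stage(ds, "raw", "filtered")
}

#' Library-size normalization
#'
#' Default is log2(CPM + 1): counts per million within each sample, then a
#' log transform; monotone in counts within a sample. `method = "sqrt"`
#' offers a square-root-anchored mean-variance flattening alternative
#' (sqrt of CPM), useful when downstream statistics are sensitive to the
#' count-variance trend; rank-based downstream steps are insensitive to the
#' choice of monotone stabilizer.
#'
#' @param ds filtered-stage [expression_dataset()].
#' @param method `"logcpm"` (default) or `"sqrt"`.
#' @return normalized-stage dataset.
#' @export
normalize_counts <- function(ds, method = c("logcpm", "sqrt")) {
  method <- match.arg(method)
  libsize <- colSums(ds$x)
  if (any(libsize == 0))
    stop("zero library size in sample(s): ",
         paste(colnames(ds$x)[libsize == 0], collapse = ", "))
  cpm <- sweep(ds$x, 2, libsize, "/") * 1e6
  ds$x <- switch(method, logcpm = log2(cpm + 1), sqrt = sqrt(cpm))
  .advance_stage(ds, "filtered", "normalized")
}

#' Remove replicate batch effects
#'
#' Residualizes each gene on batch indicators while protecting segment
#' effects (two-way linear fit: the batch coefficients are estimated jointly
#' with segment means and only the batch part is subtracted), via
#' [limma::removeBatchEffect]. With a single batch level the data are
#' returned unchanged.
#'
#' @param ds normalized-stage [expression_dataset()].
#' @param batch batch labels, one per sample; defaults to the replicate id.
#' @return batch_removed-stage dataset.
#' @export
remove_batch <- function(ds, batch = NULL) {
  if (is.null(batch)) batch <- ds$meta$replicate
  batch <- as.factor(batch)
  if (nlevels(batch) >= 2) {
    seg <- as.factor(ds$meta$segment)
    design <- stats::model.matrix(~seg)
    full <- cbind(design, stats::model.matrix(~batch)[, -1, drop = FALSE])
    if (qr(full)$rank < ncol(full))
      stop("batch is confounded with segment; effects are not separable")
    ds$x <- limma::removeBatchEffect(ds$x, batch = batch, design = design)
  }
  .advance_stage(ds, "normalized", "batch_removed")
}

#' Collapse replicates to segment-level profiles
#'
#' One column per gut segment: the mean over replicates, columns ordered by
#' AP rank.
#'
#' @param ds batch_removed-stage [expression_dataset()].
#' @return segment_level-stage dataset (one sample per segment).
#' @export
collapse_replicates <- function(ds) {
  ord <- order(ds$meta$ap_rank)
  seg <- ds$meta$segment[ord]
  usg <- unique(seg)
  x <- vapply(usg, function(s) rowMeans(ds$x[, ord[seg == s], drop = FALSE]),
              numeric(nrow(ds$x)))
  rk <- vapply(usg, function(s) unique(ds$meta$ap_rank[ds$meta$segment == s])[1],
               integer(1))
  colnames(x) <- paste0(ds$species, "_", usg)
  meta <- data.frame(sample = colnames(x), segment = usg,
                     ap_rank = as.integer(rk), replicate = "pooled")
  ds$x <- x
  ds$meta <- meta
  .advance_stage(ds, "batch_removed", "segment_level")
}

#' Row-wise z-scoring
#'
#' Centers and scales each gene across segments: (value - gene mean) / gene
#' sd. The sd convention defaults to the sample sd (n - 1), the base-R
#' `scale()` convention. Constant rows become all-zero and are recorded in
#' the `constant_genes` attribute.
#'
#' @param ds segment_level-stage [expression_dataset()].
#' @param sd_type `"sample"` (n - 1, default) or `"population"` (n).
#' @return zscored-stage dataset.
#' @export
zscore_rows <- function(ds, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  mu <- rowMeans(ds$x)
  n <- ncol(ds$x)
  sdv <- sqrt(rowSums((ds$x - mu)^2) / (if (sd_type == "sample") n - 1 else n))
  const <- sdv == 0
  sdv[const] <- 1
  ds$x <- (ds$x - mu) / sdv
  ds$x[const, ] <- 0
  ds <- .advance_stage(ds, "segment_level", "zscored")
  attr(ds, "constant_genes") <- rownames(ds$x)[const]
  ds
}

#' Select the most variant genes
#'
#' The k genes of highest across-segment variance (computed on the values as
#' given, so apply at segment level, before z-scoring). Ties are broken by
#' gene id, lexicographically smaller first.
#'
#' @param ds segment_level- or zscored-stage [expression_dataset()].
#' @param k number of genes to keep.
#' @return dataset restricted to the top-k genes, ranked by variance.
#' @export
top_variant <- function(ds, k = 2000) {
  if (!ds$stage %in% c("segment_level", "zscored"))
    stop("top_variant expects a segment_level or zscored dataset")
  v <- apply(ds$x, 1, stats::var)
  if (k > length(v)) {
    warning("k exceeds the number of genes; returning all genes")
    k <- length(v)
  }
  ord <- order(-v, rownames(ds$x))
  ds$x <- ds$x[ord[seq_len(k)], , drop = FALSE]
  ds
}

#' Run the per-species preprocessing chain
#'
#' filter -> normalize -> batch removal -> replicate collapse, returning the
#' segment-level dataset (z-scoring is applied separately where needed so the
#' pre-z-score values stay available for variance selection).
#'
#' @param ds raw-stage [expression_dataset()].
#' @inheritParams filter_low_expression
#' @inheritParams normalize_counts
#' @return segment_level-stage dataset.
#' @export
preprocess_species <- function(ds, min_count = 10, min_samples = NULL,
                               method = "logcpm") {
  ds <- filter_low_expression(ds, min_count = min_count,
                              min_samples = min_samples)
  ds <- normalize_counts(ds, method = method)
  ds <- remove_batch(ds)
  collapse_replicates(ds)
}
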