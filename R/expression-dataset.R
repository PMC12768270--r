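#' Segment-resolved expression dataset for one species
#'
#' The unit all per-species preprocessing acts on: a gene x sample matrix
#' (raw counts or transformed values) together with sample metadata placing
#' every sample on the gut anteroposterior (AP) axis, and a stage tag that
#' enforces the order of the preprocessing pipeline
#' (raw -> filtered -> normalized -> batch_removed -> segment_level -> zscored).
#'
#' @param x numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns (colnames = sample ids). Raw datasets must hold non-negative
#'   integers.
#' @param meta data.frame with one row per column of `x`, columns
#'   `sample`, `segment` (label), `ap_rank` (1-based integer position along
#'   the gut tube, anterior to posterior) and `replicate` (batch id).
#' @param species single species identifier.
#' @param stage processing stage tag.
#' @return an object of class `expression_dataset`.
#' @export
expression_dataset <- function(x, meta, species,
                               stage = c("raw", "filtered", "normalized",
                                         "batch_removed", "segment_level",
                                         "zscored")) {
  stage <- match.arg(stage)
  x <- as.matrix(x)
  if (is.null(rownames(x))) stop("counts matrix must have gene ids as rownames")
  if (is.null(colnames(x))) colnames(x) <- meta$sample
  meta <- as.data.frame(meta)
  req <- c("sample", "segment", "ap_rank", "replicate")
  if (!all(req %in% names(meta)))
    stop("meta must have columns: ", paste(req, collapse = ", "))
  if (nrow(meta) != ncol(x)) stop("meta rows must match matrix columns")
  if (!identical(as.character(meta$sample), colnames(x)))
    stop("meta$sample must match column names in order")
  ranks <- sort(unique(as.integer(meta$ap_rank)))
  if (!identical(ranks, seq_along(ranks)))
    stop("AP ranks must form a contiguous 1..n sequence")
  if (stage == "raw") {
    if (any(x < 0) || any(x != round(x)))
      stop("raw counts must be non-negative integers")
  }
  structure(list(x = x, meta = meta, species = as.character(species)[1],
                 stage = stage),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset [%s]: %d genes x %d samples, %d segments, stage '%s'\n",
              x$species, nrow(x$x), ncol(x$x),
              length(unique(x$meta$segment)), x$stage))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$x)

.stage_order <- c("raw", "filtered", "normalized", "batch_removed",
                  "segment_level", "zscored")

# enforce the one legal stage transition; stages never repeat or skip
.advance_stage <- function(ds, from, to) {
  if (!identical(ds$stage, from))
    stop(sprintf("operation requires stage '%s' but dataset is at stage '%s'",
                 from, ds$stage))
  ds$stage <- to
  ds
}

#' Read / write counts and metadata
#'
#' Plain-text interchange for gene x sample matrices: tab-separated values
#' (first column = gene id) or MatrixMarket plus separate row/column name
#' files are both supported, matching the formats segment-level RNA-seq
#' counts are usually shipped in.
#'
#' @param path file path.
#' @param x matrix to write.
#' @name counts_io
NULL

#' @rdname counts_io
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}

#' @rdname counts_io
#' @param stage_comment optional stage tag written as a `#` header comment.
#' @export
write_counts_tsv <- function(x, path, stage_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(stage_comment)) writeLines(paste0("# stage: ", stage_comment), con)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname counts_io
#' @export
read_counts_mm <- function(path) {
  m <- as.matrix(Matrix::readMM(path))
  rn <- readLines(paste0(path, ".rownames"))
  cn <- readLines(paste0(path, ".colnames"))
  dimnames(m) <- list(rn, cn)
  m
}

#' @rdname counts_io
#' @export
write_counts_mm <- function(x, path) {
  Matrix::writeMM(Matrix::Matrix(x, sparse = TRUE), path)
  writeLines(rownames(x), paste0(path, ".rownames"))
  writeLines(colnames(x), paste0(path, ".colnames"))
  invisible(path)
}

#' @rdname counts_io
#' @export
read_metadata_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, comment.char = "#",
                    colClasses = c(ap_rank = "integer"))
}

#' @rdname counts_io
#' @param meta metadata data.frame.
#' @export
write_metadata_tsv <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
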