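#' Orthology table
#'
#' Orthogroup -> species -> gene-id lists, the unit of cross-species
#' comparison (the output format of OrthoFinder-style orthogroup inference,
#' which this package consumes rather than produces).
#'
#' @param groups named list: orthogroup id -> named list (species -> character
#'   vector of gene ids).
#' @param species character vector of species ids (column order for IO).
#' @return object of class `orthology_table`.
#' @export
orthology_table <- function(groups, species = NULL) {
  if (length(groups) == 0) stop("orthology table cannot be empty")
  if (is.null(species))
    species <- unique(unlist(lapply(groups, names)))
  for (og in names(groups)) {
    g <- unlist(groups[[og]])
    if (length(g) == 0) stop("empty orthogroup: ", og)
  }
  for (sp in species) {
    g <- unlist(lapply(groups, function(m) m[[sp]]))
    if (anyDuplicated(g))
      stop("duplicated gene ids within species ", sp)
  }
  structure(list(groups = groups, species = species),
            class = "orthology_table")
}

#' @export
print.orthology_table <- function(x, ...) {
  cat(sprintf("orthology_table: %d orthogroups x %d species, %d genes\n",
              length(x$groups), length(x$species),
              length(unlist(x$groups))))
  invisible(x)
}

#' Read / write `Orthogroups.tsv`
#'
#' The OrthoFinder dialect: tab-separated, first column the orthogroup id,
#' one column per species, cells holding `", "`-separated gene lists.
#'
#' @param path file path.
#' @name orthogroups_io
#' @export
read_orthogroups <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  species <- names(df)[-1]
  groups <- lapply(seq_len(nrow(df)), function(i) {
    m <- lapply(species, function(sp) {
      cell <- df[i, sp]
      if (is.na(cell) || cell == "") character(0)
      else strsplit(cell, ", ", fixed = TRUE)[[1]]
    })
    names(m) <- species
    m[vapply(m, length, 1L) > 0]
  })
  names(groups) <- df[[1]]
  orthology_table(groups, species)
}

#' @rdname orthogroups_io
#' @param tbl an [orthology_table()].
#' @export
write_orthogroups <- function(tbl, path) {
  rows <- vapply(names(tbl$groups), function(og) {
    cells <- vapply(tbl$species, function(sp) {
      g <- tbl$groups[[og]][[sp]]
      if (is.null(g)) "" else paste(g, collapse = ", ")
    }, "")
    paste(c(og, cells), collapse = "\t")
  }, "")
  writeLines(c(paste(c("Orthogroup", tbl$species), collapse = "\t"), rows),
             path)
  invisible(path)
}

#' Filter orthogroups by size and cross-species balance
#'
#' Drops orthogroups with more than `hard_max` genes in total, and those with
#' more than `soft_max` genes whose representation is unbalanced across
#' species — operationalized as (max per-species gene count) / (min nonzero
#' per-species gene count) exceeding `balance_ratio`.
#'
#' @param tbl an [orthology_table()].
#' @param hard_max absolute size cap (default 120).
#' @param soft_max size above which balance is required (default 80).
#' @param balance_ratio max/min-nonzero per-species count ratio tolerated for
#'   large orthogroups (default 3).
#' @return filtered [orthology_table()].
#' @export
filter_orthogroups <- function(tbl, hard_max = 120, soft_max = 80,
                               balance_ratio = 3.0) {
  keep <- vapply(tbl$groups, function(m) {
    sizes <- vapply(m, length, 1L)
    total <- sum(sizes)
    if (total > hard_max) return(FALSE)
    if (total > soft_max) {
      nz <- sizes[sizes > 0]
      if (max(nz) / min(nz) > balance_ratio) return(FALSE)
    }
    TRUE
  }, logical(1))
  orthology_table(tbl$groups[keep], tbl$species)
}

.check_protein <- function(seqs) {
  bad <- names(seqs)[grepl("[^ACDEFGHIKLMNPQRSTVWY]",
                           as.character(seqs))]
  if (length(bad))
    stop("invalid amino-acid residues in: ", paste(bad, collapse = ", "))
}

#' Pairwise local-alignment protein similarity
#'
#' Smith-Waterman local alignment scores under BLOSUM62 with affine gap
#' penalties (open 2, extend 0.1 — the permissive mafft-like setting used
#' for within-orthogroup comparisons), optionally normalized to \[0, 1\] by
#' the geometric mean of the two self-alignment scores so that scores are
#' comparable across proteins of different lengths. The alignment kernel is
#' a double-precision affine-gap (Gotoh) dynamic program in compiled code;
#' with gap penalties this permissive, adjacent deletion+insertion pairs can
#' outscore poor substitutions, so transitions between the two gap states
#' are allowed.
#'
#' @param seqs [Biostrings::AAStringSet] or named character vector of protein
#'   sequences (standard 20-letter alphabet).
#' @param gap_opening,gap_extension affine gap penalties (a gap of length L
#'   costs `gap_opening + L * gap_extension`).
#' @param normalize divide by the geometric mean of self-scores (default
#'   TRUE); FALSE returns raw Smith-Waterman scores.
#' @return symmetric similarity matrix with sequence names as dimnames.
#' @export
pairwise_similarity <- function(seqs, gap_opening = 2, gap_extension = 0.1,
                                normalize = TRUE) {
  if (!methods::is(seqs, "AAStringSet")) seqs <- Biostrings::AAStringSet(seqs)
  if (length(seqs) < 2) stop("need at least 2 sequences")
  if (is.null(names(seqs))) names(seqs) <- as.character(seq_along(seqs))
  .check_protein(seqs)
  sub <- .blosum62()
  enc <- lapply(as.character(seqs), function(s)
    match(strsplit(s, "", fixed = TRUE)[[1]], rownames(sub)) - 1L)
  n <- length(seqs)
  S <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  self <- vapply(enc, function(e)
    .sw_local_score(e, e, sub, gap_opening, gap_extension), numeric(1))
  for (i in seq_len(n)) {
    S[i, i] <- self[i]
    if (i < n) for (j in (i + 1):n) {
      sc <- .sw_local_score(enc[[i]], enc[[j]], sub, gap_opening,
                            gap_extension)
      S[i, j] <- sc
      S[j, i] <- sc
    }
  }
  if (normalize) S <- S / sqrt(outer(self, self))
  S
}

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Best ancestral orthologue within one orthogroup
#'
#' For each species, among its paralogs, picks the protein with the highest
#' mean similarity to all proteins of all *other* species in the orthogroup —
#' the member most likely to have conserved the ancestral sequence. Ties are
#' broken by lexicographically smaller gene id; the margin to the runner-up
#' is recorded but not enforced.
#'
#' @param group named list: species -> named character vector (or
#'   `AAStringSet`) of that species' member protein sequences.
#' @param similarity optional precomputed similarity matrix over all member
#'   sequences (from [pairwise_similarity()]).
#' @param ... passed to [pairwise_similarity()].
#' @return data.frame with one row per species: `species`, `gene`, `score`,
#'   `n_candidates`, `margin`.
#' @export
best_ancestral_orthologue <- function(group, similarity = NULL, ...) {
  sp_of <- rep(names(group), vapply(group, length, 1L))
  all_seqs <- character(0)
  for (s in group) {
    v <- if (methods::is(s, "AAStringSet"))
      stats::setNames(as.character(s), names(s)) else s
    all_seqs <- c(all_seqs, v)
  }
  names(sp_of) <- names(all_seqs)
  if (is.null(similarity)) {
    if (length(all_seqs) >= 2) similarity <- pairwise_similarity(all_seqs, ...)
    else similarity <- matrix(1, 1, 1, dimnames = list(names(all_seqs),
                                                       names(all_seqs)))
  }
  out <- lapply(names(group), function(sp) {
    cand <- names(all_seqs)[sp_of == sp]
    others <- names(all_seqs)[sp_of != sp]
    if (length(others) == 0) {
      sc <- stats::setNames(rep(NA_real_, length(cand)), cand)
    } else {
      sc <- vapply(cand, function(g) mean(similarity[g, others]), numeric(1))
    }
    ord <- order(-sc, cand)
    best <- cand[ord[1]]
    margin <- if (length(cand) > 1) sc[ord[1]] - sc[ord[2]] else NA_real_
    data.frame(species = sp, gene = best, score = unname(sc[ord[1]]),
               n_candidates = length(cand), margin = unname(margin))
  })
  do.call(rbind, out)
}

#' Resolve a full orthology table to one representative gene per species
#'
#' Applies [best_ancestral_orthologue()] to every orthogroup, skipping the
#' alignment work for strictly one-to-one groups.
#'
#' @param tbl an [orthology_table()].
#' @param sequences named list of per-species `AAStringSet` proteomes.
#' @param ... passed to [pairwise_similarity()].
#' @return data.frame (the resolved map): `orthogroup`, `species`, `gene`,
#'   `score`, `n_candidates`, `margin`.
#' @export
resolve_orthogroups <- function(tbl, sequences, ...) {
  out <- lapply(names(tbl$groups), function(og) {
    m <- tbl$groups[[og]]
    if (all(vapply(m, length, 1L) == 1)) {
      res <- data.frame(species = names(m), gene = unlist(m, use.names = FALSE),
                        score = NA_real_, n_candidates = 1L,
                        margin = NA_real_)
    } else {
      group <- lapply(names(m), function(sp) {
        s <- sequences[[sp]][m[[sp]]]
        stats::setNames(as.character(s), m[[sp]])
      })
      names(group) <- names(m)
      res <- best_ancestral_orthologue(group, ...)
    }
    res$orthogroup <- og
    res
  })
  res <- do.call(rbind, out)
  res[, c("orthogroup", "species", "gene", "score", "n_candidates", "margin")]
}

#' Expand transcription-factor flags to the orthogroup level
#'
#' An orthogroup is a TF orthogroup iff any member gene in any species is
#' flagged; the flag then propagates to all members. Idempotent by
#' construction.
#'
#' @param gene_tf_flags character vector of TF gene ids, or named logical per
#'   gene.
#' @param tbl an [orthology_table()].
#' @return named logical vector over orthogroups.
#' @export
expand_tf_flags <- function(gene_tf_flags, tbl) {
  tf_genes <- if (is.logical(gene_tf_flags)) names(gene_tf_flags)[gene_tf_flags]
  else as.character(gene_tf_flags)
  vapply(tbl$groups, function(m) any(unlist(m) %in% tf_genes), logical(1))
}

#' Apply manual orthogroup overrides
#'
#' Dissolves every orthogroup containing a gene referenced in the override
#' table and regroups the referenced genes into the new orthogroups — the
#' mechanism for families (e.g., Hox) whose automatic orthogroups fragment
#' paralogue positions across groups and must be regrouped by hand.
#' Unreferenced genes of dissolved orthogroups are dropped (the source groups
#' are discarded wholesale, as in manual curation).
#'
#' @param tbl an [orthology_table()].
#' @param overrides data.frame with columns `orthogroup` (new id), `species`,
#'   `gene`.
#' @return updated [orthology_table()].
#' @export
apply_overrides <- function(tbl, overrides) {
  if (is.null(overrides) || nrow(overrides) == 0) return(tbl)
  if (anyDuplicated(overrides$gene))
    stop("gene(s) referenced more than once in overrides: ",
         paste(unique(overrides$gene[duplicated(overrides$gene)]),
               collapse = ", "))
  all_genes <- unlist(tbl$groups)
  missing <- setdiff(overrides$gene, all_genes)
  if (length(missing))
    stop("override gene(s) absent from the table: ",
         paste(missing, collapse = ", "))
  dissolved <- names(tbl$groups)[vapply(tbl$groups, function(m)
    any(unlist(m) %in% overrides$gene), logical(1))]
  groups <- tbl$groups[setdiff(names(tbl$groups), dissolved)]
  for (og in unique(overrides$orthogroup)) {
    sub <- overrides[overrides$orthogroup == og, ]
    groups[[og]] <- split(sub$gene, sub$species)
  }
  orthology_table(groups, tbl$species)
}

#' Integrate z-scored per-species datasets on orthogroups
#'
#' Builds the cross-species comparison substrate: one row per orthogroup
#' whose representative gene survived expression filtering in every species,
#' holding each species' representative-gene z-score profile concatenated
#' over that species' segments. Within-species z-scoring is what lets
#' samples cluster by position along the gut rather than by species.
#'
#' @param datasets named list (by species) of zscored-stage
#'   [expression_dataset()]s.
#' @param resolved resolved map from [resolve_orthogroups()].
#' @param tf_flags optional named logical per orthogroup (from
#'   [expand_tf_flags()]).
#' @return object of class `integrated_matrix`: `x` (orthogroup x column
#'   z-matrix), `col_meta` (`species`, `segment`, `ap_rank`), `row_meta`
#'   (`orthogroup`, `tf`, per-species representative gene).
#' @export
integrate_species <- function(datasets, resolved, tf_flags = NULL) {
  species <- names(datasets)
  miss <- setdiff(species, unique(resolved$species))
  if (length(miss))
    stop("species missing from the resolved map: ", paste(miss, collapse = ", "))
  for (ds in datasets) if (ds$stage != "zscored")
    stop("all datasets must be at the zscored stage")
  rep_by_sp <- lapply(species, function(sp) {
    sub <- resolved[resolved$species == sp, ]
    stats::setNames(sub$gene, sub$orthogroup)
  })
  names(rep_by_sp) <- species
  ogs <- Reduce(intersect, lapply(species, function(sp) {
    r <- rep_by_sp[[sp]]
    names(r)[r %in% rownames(datasets[[sp]]$x)]
  }))
  if (length(ogs) == 0) stop("no orthogroup is expressed in all species")
  blocks <- lapply(species, function(sp)
    datasets[[sp]]$x[rep_by_sp[[sp]][ogs], , drop = FALSE])
  x <- do.call(cbind, blocks)
  rownames(x) <- ogs
  col_meta <- do.call(rbind, lapply(species, function(sp)
    data.frame(species = sp, segment = datasets[[sp]]$meta$segment,
               ap_rank = datasets[[sp]]$meta$ap_rank)))
  colnames(x) <- paste0(col_meta$species, "_", col_meta$segment)
  row_meta <- data.frame(orthogroup = ogs,
                         tf = if (is.null(tf_flags)) NA else
                           unname(tf_flags[ogs]))
  genes <- do.call(cbind, lapply(species, function(sp) rep_by_sp[[sp]][ogs]))
  colnames(genes) <- species
  structure(list(x = x, col_meta = col_meta, row_meta = row_meta,
                 genes = genes, species = species),
            class = "integrated_matrix")
}

#' @export
print.integrated_matrix <- function(x, ...) {
  cat(sprintf("integrated_matrix: %d orthogroups x %d (species, segment) columns; %d species\n",
              nrow(x$x), ncol(x$x), length(x$species)))
  invisible(x)
}
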