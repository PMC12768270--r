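#' Extract conserved AP modules by pooled seriation and contiguous clustering
#'
#' Given the integrated matrix restricted to conserved AP-associated
#' orthogroups, computes the gene-gene Spearman correlation over all pooled
#' (species, segment) columns, R2E-seriates the genes, and partitions the
#' seriation order into contiguous modules with [constrained_cluster()].
#' With `k = "auto"` the module count is chosen over `k_range` by BIC under
#' the segmented mean-profile model: each candidate partition models every
#' gene's pooled profile as its module's mean profile plus Gaussian noise,
#' and the k minimizing N log(SSE/N) + k p log(N) is taken (N = entries of
#' the profile matrix, p = pooled columns). Modules are numbered anterior to
#' posterior (by cross-species
#' median peak rank of their mean profile), so module order follows the AP
#' axis regardless of the seriation's orientation.
#'
#' @param im an [integrate_species()] result.
#' @param orthogroups character vector restricting the rows (e.g., the
#'   conserved set from [screen_conserved()]); default all rows.
#' @param k number of modules, or `"auto"`.
#' @param k_range candidate counts for auto selection.
#' @return object of class `module_set`: `membership` (named integer, module
#'   per orthogroup), `modules` (list: per module the members and the mean
#'   z-profile per species), `k`, `criterion` (named vector of the auto-k
#'   scores), `seriation` (the gene `r2e_seriation`).
#' @export
extract_modules <- function(im, orthogroups = NULL, k = "auto",
                            k_range = 2:8) {
  ogs <- if (is.null(orthogroups)) im$row_meta$orthogroup
  else intersect(im$row_meta$orthogroup, orthogroups)
  X <- im$x[ogs, , drop = FALSE]
  C <- stats::cor(t(X), method = "spearman")
  ord <- seriate_r2e(X, axis = "rows")
  crit <- NULL
  if (identical(k, "auto")) {
    k_range <- k_range[k_range * 2 <= length(ogs)]
    crit <- vapply(k_range, function(kk) .segmentation_bic(X, ord, C, kk),
                   numeric(1))
    names(crit) <- k_range
    k <- k_range[which.min(crit)]
  }
  k <- as.integer(k)
  if (2 * k > length(ogs))
    stop("need at least 2*k member orthogroups")
  cl <- constrained_cluster(ord, C, k)

  species <- im$species
  profile_of <- function(members) lapply(species, function(sp) {
    sel <- im$col_meta$species == sp
    p <- colMeans(im$x[members, sel, drop = FALSE])
    stats::setNames(p, im$col_meta$segment[sel])[order(im$col_meta$ap_rank[sel])]
  })
  modules <- lapply(cl$blocks, function(members) {
    prof <- profile_of(members)
    names(prof) <- species
    peaks <- vapply(prof, which.max, integer(1))
    nseg <- vapply(prof, length, integer(1))
    list(members = members, profiles = prof, peak_rank = peaks,
         median_rel_peak = stats::median((peaks - 1) / (nseg - 1)))
  })
  # number modules along the AP axis, anterior first
  ap_ord <- order(vapply(modules, `[[`, numeric(1), "median_rel_peak"))
  modules <- modules[ap_ord]
  membership <- integer(length(ogs))
  names(membership) <- ogs
  for (m in seq_along(modules)) membership[modules[[m]]$members] <- m
  structure(list(membership = membership, modules = modules, k = k,
                 criterion = crit, seriation = ord, species = species),
            class = "module_set")
}

# BIC of the k-block contiguous partition under the segmented mean-profile
# model (gene profile = module mean profile + iid Gaussian noise)
.segmentation_bic <- function(X, ord, C, k) {
  cl <- constrained_cluster(ord, C, k)
  sse <- sum(vapply(cl$blocks, function(b) {
    sub <- X[b, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }, numeric(1)))
  N <- length(X)
  N * log(sse / N) + k * ncol(X) * log(N)
}

#' @export
print.module_set <- function(x, ...) {
  sizes <- vapply(x$modules, function(m) length(m$members), integer(1))
  cat(sprintf("module_set: %d modules over %d orthogroups (sizes %s)\n",
              x$k, length(x$membership), paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Place modules relative to compartments and flag positional deviations
#'
#' For every module and species: the segment where the module's mean profile
#' peaks, the compartment (anterior/posterior of the species' boundary)
#' containing that peak, and a deviation flag when the species' peak
#' compartment differs from the cross-species majority — the signature of a
#' module that has shifted (e.g., anteriorised) in one lineage.
#'
#' @param ms a [extract_modules()] result.
#' @param calls named list (by species) of [detect_boundary()]
#'   `compartment_call`s.
#' @return data.frame: `module`, `species`, `peak_rank`, `compartment`,
#'   `majority`, `deviates`.
#' @export
module_position <- function(ms, calls) {
  out <- list()
  for (m in seq_along(ms$modules)) {
    mod <- ms$modules[[m]]
    comp <- vapply(ms$species, function(sp) {
      b <- calls[[sp]]$boundary
      if (mod$peak_rank[[sp]] < b) "anterior" else "posterior"
    }, "")
    tab <- table(comp)
    majority <- names(tab)[which.max(tab)]
    for (sp in ms$species)
      out[[length(out) + 1]] <- data.frame(
        module = m, species = sp, peak_rank = mod$peak_rank[[sp]],
        compartment = comp[[sp]], majority = majority,
        deviates = comp[[sp]] != majority)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
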