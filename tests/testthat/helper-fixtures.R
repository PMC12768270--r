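# Fixture builders and independent oracles shared across the suite.
# Everything is generated in code; nothing is read from disk.

# small raw dataset with explicit counts (genes x samples)
toy_dataset <- function(counts, segments = NULL, replicates = NULL,
                        species = "spX") {
  n <- ncol(counts)
  if (is.null(segments)) segments <- rep(sprintf("S%d", seq_len(n %/% 1)), 1)
  if (is.null(replicates)) replicates <- rep("r1", n)
  ranks <- as.integer(factor(segments, levels = unique(segments)))
  meta <- data.frame(sample = colnames(counts), segment = segments,
                     ap_rank = ranks, replicate = replicates)
  expression_dataset(counts, meta, species, stage = "raw")
}

# perfect Robinson similarity matrix from points on a line
robinson_cor <- function(n, seed) {
  set.seed(seed)
  p <- sort(stats::runif(n, 0, 10))
  L <- stats::runif(1, 2, 6)
  C <- exp(-abs(outer(p, p, "-")) / L)
  dimnames(C) <- list(letters[seq_len(n)], letters[seq_len(n)])
  C
}

# does a recovered r2e permutation equal the generating order (or reversal)?
recovers_order <- function(perm, n) {
  all(perm == seq_len(n)) || all(perm == rev(seq_len(n)))
}

# Robinson-violation count of similarity matrix C under permutation p:
# in a perfect order every row decays monotonically away from the diagonal
robinson_violations <- function(C, p) {
  S <- C[p, p]
  n <- nrow(S)
  v <- 0L
  for (i in seq_len(n)) {
    if (i < n) v <- v + sum(diff(S[i, i:n]) > 1e-12)
    if (i > 1) v <- v + sum(diff(S[i, i:1]) > 1e-12)
  }
  v
}

# recursive enumeration of all permutations of 1..n (n small), one per row
perms_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- matrix(c(seq_len(n))[-k][sub], nrow(sub), n - 1L)
    cbind(rep(k, nrow(sub)), rest)
  }))
}

# independent textbook Smith-Waterman DP (affine gaps, gap-state cross
# transitions, full matrices, pure R) -- the oracle for pairwise_similarity
sw_oracle <- function(a, b, sub, gap_open = 2, gap_extend = 0.1) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                   X[i - 1, j] - gap_extend,
                   Y[i - 1, j] - gap_open - gap_extend)
    Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                   Y[i, j - 1] - gap_extend,
                   X[i, j - 1] - gap_open - gap_extend)
    M[i, j] <- max(0, max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) +
                     sub[av[i - 1], bv[j - 1]])
    best <- max(best, M[i, j], X[i, j], Y[i, j])
  }
  best
}

random_protein <- function(len) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y"), len, TRUE),
        collapse = "")
}

# z-profile matrix of planted bipartite (block + staggered gradient) genes
# for one species, built from the generator's noiseless means
bipartite_z <- function(n_seg = 9, n_genes = 300, seed = 1, noise = 0) {
  cfg <- synth_config(n_species = 1, segments_per_species = n_seg,
                      n_orthogroups = n_genes,
                      frac_block = 0.4, frac_gradient = 0.4,
                      frac_terminal = 0,
                      module_spec = transform(default_module_spec(),
                                              n_genes = 0),
                      boundary_rel = 0.5, seed = seed)
  pr <- make_profiles(cfg)
  m <- pr$means[[1]][pr$truth$archetype != "null", , drop = FALSE]
  colnames(m) <- sprintf("s%d", seq_len(n_seg))
  # segment correlations are computed on pre-z-score expression (Spearman is
  # invariant to the log transform); z is the scale noise is added on
  z <- t(scale(t(log2(m + 1))))
  if (noise > 0) z <- z + matrix(stats::rnorm(length(z), 0, noise), nrow(z))
  colnames(z) <- colnames(m)
  list(m = m, z = z, boundary = pr$truth$boundary[[1]])
}

# integrated_matrix built directly from per-species z blocks (module genes)
module_integrated <- function(n_genes_per_module = 20, jitter_sd = 0.05,
                              noise = 0.5, seed = 1,
                              segments = c(8, 7, 9)) {
  cfg <- synth_config(n_species = length(segments),
                      segments_per_species = segments,
                      n_orthogroups = 5 * n_genes_per_module + 10,
                      frac_block = 0, frac_gradient = 0, frac_terminal = 0,
                      module_spec = transform(default_module_spec(),
                                              n_genes = n_genes_per_module,
                                              jitter_sd = jitter_sd),
                      seed = seed)
  pr <- make_profiles(cfg)
  mods <- names(pr$truth$archetype)[grepl("^module:", pr$truth$archetype)]
  sps <- names(pr$means)
  blocks <- lapply(pr$means, function(mm) {
    z <- t(scale(t(log2(mm[mods, , drop = FALSE] + 1))))
    z + matrix(stats::rnorm(length(z), 0, noise), nrow(z))
  })
  X <- do.call(cbind, blocks)
  col_meta <- do.call(rbind, lapply(seq_along(sps), function(s)
    data.frame(species = sps[s],
               segment = sprintf("S%02d", seq_len(segments[s])),
               ap_rank = seq_len(segments[s]))))
  colnames(X) <- paste0(col_meta$species, "_", col_meta$segment)
  im <- structure(list(x = X,
                       col_meta = col_meta,
                       row_meta = data.frame(orthogroup = mods, tf = TRUE),
                       genes = NULL, species = sps),
                  class = "integrated_matrix")
  list(im = im, truth = pr$truth, modules = mods)
}
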