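test_that("config validation rejects impossible designs", {
  expect_error(synth_config(boundary_rel = 1.2), "boundary_rel")
  expect_error(synth_config(boundary_rel = 0), "boundary_rel")
  expect_error(synth_config(frac_block = 0.6, frac_gradient = 0.6),
               "sum to at most 1")
  expect_error(synth_config(segments_per_species = c(3, 8, 8, 8, 8)),
               "at least 4 segments")
  expect_error(synth_config(tf_fraction = -0.1), "proportions")
})

test_that("zero-jitter modules peak exactly at the programmed center", {
  # centers chosen off the .5 grid so the nearest-segment peak is unambiguous
  centers <- c(0.06, 0.27, 0.52, 0.73, 0.94)
  ms <- transform(default_module_spec(), n_genes = 6, jitter_sd = 0,
                  center = centers)
  cfg <- synth_config(n_species = 3, segments_per_species = c(8, 6, 10),
                      n_orthogroups = 60,
                      frac_block = 0, frac_gradient = 0, frac_terminal = 0,
                      module_spec = ms,
                      seed = 5)
  pr <- make_profiles(cfg)
  for (s in seq_len(3)) {
    n_seg <- cfg$segments_per_species[s]
    for (k in 1:5) {
      sel <- pr$truth$archetype == sprintf("module:%d", k)
      expected <- round(centers[k] * (n_seg - 1)) + 1
      expect_true(all(pr$truth$peak[sel, s] == expected),
                  info = sprintf("module %d species %d", k, s))
    }
  }
})

test_that("block genes are high before the boundary and low after", {
  cfg <- synth_config(n_species = 2, segments_per_species = c(8, 9),
                      n_orthogroups = 50, frac_block = 0.5,
                      frac_gradient = 0, frac_terminal = 0,
                      module_spec = transform(default_module_spec(),
                                              n_genes = 0),
                      seed = 6)
  pr <- make_profiles(cfg)
  blk <- pr$truth$archetype == "block"
  for (s in 1:2) {
    b <- pr$truth$boundary[[s]]
    m <- pr$means[[s]]
    ant <- rowMeans(m[blk, seq_len(b - 1), drop = FALSE])
    post <- rowMeans(m[blk, b:ncol(m), drop = FALSE])
    expect_true(all(ant > post))
  }
})

test_that("gradient genes are flat before the boundary and ramp after it", {
  bp <- bipartite_z(n_seg = 9, n_genes = 100, seed = 7)
  cfg <- synth_config(n_species = 1, segments_per_species = 9,
                      n_orthogroups = 100, frac_block = 0, frac_gradient = 1,
                      frac_terminal = 0,
                      module_spec = transform(default_module_spec(),
                                              n_genes = 0),
                      boundary_rel = 0.5, seed = 8)
  pr <- make_profiles(cfg)
  b <- pr$truth$boundary[[1]]
  m <- pr$means[[1]]
  grd <- pr$truth$archetype == "gradient"
  pre <- m[grd, seq_len(b - 1), drop = FALSE]
  expect_true(all(abs(pre - pre[, 1]) < 1e-9))       # flat anterior floor
  post <- m[grd, b:ncol(m), drop = FALSE]
  expect_true(all(apply(post, 1, function(x) all(diff(x) >= -1e-12))))
  expect_true(all(pr$truth$peak[grd, 1] == ncol(m))) # peak at the posterior end
})

test_that("an all-null design yields flat profiles", {
  cfg <- synth_config(n_species = 1, segments_per_species = 6,
                      n_orthogroups = 30, frac_block = 0, frac_gradient = 0,
                      frac_terminal = 0,
                      module_spec = transform(default_module_spec(),
                                              n_genes = 0),
                      seed = 9)
  pr <- make_profiles(cfg)
  expect_true(all(pr$truth$archetype == "null"))
  expect_true(all(apply(pr$means[[1]], 1, function(x) diff(range(x)) == 0)))
})

test_that("the generator is byte-deterministic under a fixed seed", {
  cfg <- synth_config(n_species = 2, segments_per_species = c(6, 7),
                      n_orthogroups = 40,
                      module_spec = transform(default_module_spec(),
                                              n_genes = 4),
                      seed = 123)
  s1 <- simulate_gut_study(cfg)
  s2 <- simulate_gut_study(cfg)
  expect_identical(s1$datasets[[1]]$x, s2$datasets[[1]]$x)
  expect_identical(as.character(s1$sequences[[2]]),
                   as.character(s2$sequences[[2]]))
  expect_identical(s1$truth$archetype, s2$truth$archetype)
  expect_identical(s1$truth$batch, s2$truth$batch)
})

test_that("counts are non-negative integers with contiguous AP ranks", {
  cfg <- synth_config(n_species = 2, segments_per_species = c(6, 8),
                      n_orthogroups = 50,
                      module_spec = transform(default_module_spec(),
                                              n_genes = 4),
                      seed = 10)
  sim <- simulate_gut_study(cfg)
  for (ds in sim$datasets) {
    expect_true(all(ds$x >= 0))
    expect_true(all(ds$x == round(ds$x)))
    ranks <- sort(unique(ds$meta$ap_rank))
    expect_identical(ranks, seq_along(ranks))
  }
})

test_that("sampled counts track the programmed means (Monte-Carlo)", {
  # many replicates, no library-size or batch nuisance: the empirical mean
  # per gene and segment must sit within 5% of the programmed mean
  cfg <- synth_config(n_species = 1, segments_per_species = 4,
                      n_orthogroups = 40, replicates = 1000,
                      libsize_sigma = 0, batch_sd = 0,
                      module_spec = transform(default_module_spec(),
                                              n_genes = 4),
                      seed = 11)
  pr <- make_profiles(cfg)
  cnt <- sample_counts(pr, cfg)
  ds <- cnt$datasets[[1]]
  m <- pr$means[[1]]
  for (seg in 1:4) {
    sel <- ds$meta$ap_rank == seg
    emp <- rowMeans(ds$x[, sel])
    big <- m[, seg] >= 50
    expect_true(all(abs(emp[big] - m[big, seg]) / m[big, seg] < 0.05))
  }
})

test_that("the Poisson limit is reached when dispersion vanishes", {
  cfg <- synth_config(n_species = 1, segments_per_species = 4,
                      n_orthogroups = 20, replicates = 3,
                      nb_dispersion = c(meanlog = -Inf, sdlog = 0),
                      libsize_sigma = 0, batch_sd = 0,
                      module_spec = transform(default_module_spec(),
                                              n_genes = 0),
                      frac_block = 0, frac_gradient = 0, frac_terminal = 0,
                      seed = 12)
  pr <- make_profiles(cfg)
  pr$means[[1]][] <- 0           # zero programmed mean => all-zero counts
  cnt <- sample_counts(pr, cfg)
  expect_true(all(cnt$datasets[[1]]$x == 0))
})

test_that("sequences mutate at the programmed rates", {
  base <- synth_config(n_species = 3, segments_per_species = c(6, 6, 6),
                       n_orthogroups = 30, seq_len = 200, paralog_rate = 1,
                       module_spec = transform(default_module_spec(),
                                               n_genes = 0),
                       frac_block = 0, frac_gradient = 0, frac_terminal = 0)
  # zero mutation: every sequence equals the ancestor
  cfg0 <- base; cfg0$mut_rate_ortho <- 0; cfg0$mut_rate_extra <- 0
  cfg0$seed <- 13L
  pr <- make_profiles(cfg0)
  sq <- make_sequences(cfg0, pr$truth)
  anc <- sq$truth$ancestor_seq
  for (sp in names(sq$sequences)) {
    seqs <- as.character(sq$sequences[[sp]])
    og_of <- sub("^sp\\d+_", "", sub("_p2$", "", names(seqs)))
    expect_identical(unname(seqs), unname(anc[og_of]))
  }
  # extra paralogs diverge more than primaries
  cfg1 <- base; cfg1$mut_rate_ortho <- 0.1; cfg1$mut_rate_extra <- 0.5
  cfg1$seed <- 14L
  pr <- make_profiles(cfg1)
  sq <- make_sequences(cfg1, pr$truth)
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  worse <- vapply(names(sq$orthology$groups), function(og) {
    m <- sq$orthology$groups[[og]]
    sp <- names(m)[vapply(m, length, 1L) == 2][1]
    genes <- m[[sp]]
    prim <- genes[!grepl("_p2$", genes)]
    extra <- genes[grepl("_p2$", genes)]
    s <- as.character(sq$sequences[[sp]])
    ham(s[extra], sq$truth$ancestor_seq[og]) >
      ham(s[prim], sq$truth$ancestor_seq[og])
  }, logical(1))
  expect_gte(mean(worse), 0.95)
})

test_that("paralog_rate zero gives a strictly one-to-one orthology table", {
  cfg <- synth_config(n_species = 3, segments_per_species = c(6, 6, 6),
                      n_orthogroups = 25, paralog_rate = 0, seq_len = 50,
                      module_spec = transform(default_module_spec(),
                                              n_genes = 0),
                      seed = 15)
  pr <- make_profiles(cfg)
  sq <- make_sequences(cfg, pr$truth)
  sizes <- unlist(lapply(sq$orthology$groups, vapply, length, 1L))
  expect_true(all(sizes == 1))
})

test_that("the orthology table round-trips through Orthogroups.tsv", {
  cfg <- synth_config(n_species = 3, segments_per_species = c(6, 6, 6),
                      n_orthogroups = 15, paralog_rate = 0.5, seq_len = 30,
                      module_spec = transform(default_module_spec(),
                                              n_genes = 0),
                      seed = 16)
  pr <- make_profiles(cfg)
  sq <- make_sequences(cfg, pr$truth)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_orthogroups(sq$orthology, path)
  back <- read_orthogroups(path)
  expect_identical(back$species, sq$orthology$species)
  expect_identical(back$groups, sq$orthology$groups)
})

test_that("written simulations can be read back", {
  cfg <- synth_config(n_species = 2, segments_per_species = c(6, 6),
                      n_orthogroups = 12, seq_len = 30,
                      module_spec = transform(default_module_spec(),
                                              n_genes = 0),
                      seed = 17)
  sim <- simulate_gut_study(cfg)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  cnts <- read_counts_tsv(file.path(dir, "sp1_counts.tsv"))
  expect_identical(cnts, sim$datasets[[1]]$x)
  mm <- read_counts_mm(file.path(dir, "sp1_counts.mtx"))
  expect_equal(mm, sim$datasets[[1]]$x, ignore_attr = FALSE)
  meta <- read_metadata_tsv(file.path(dir, "sp1_meta.tsv"))
  expect_identical(meta$ap_rank, sim$datasets[[1]]$meta$ap_rank)
})
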