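og_table <- function(...) orthology_table(list(...))

test_that("orthogroup size and balance filters apply the documented rules", {
  g <- function(og, n_per_sp) {
    m <- lapply(seq_along(n_per_sp), function(i)
      sprintf("%s_s%d_g%03d", og, i, seq_len(n_per_sp[i])))
    names(m) <- paste0("sp", seq_along(n_per_sp))
    m[n_per_sp > 0]
  }
  tbl <- orthology_table(list(
    og_small = g("a", c(1, 1, 1, 1, 1)),
    og_121 = g("b", c(25, 24, 24, 24, 24)),      # 121 genes: hard cap
    og_81_bal = g("c", c(16, 16, 16, 16, 17)),   # 81 genes, balanced: kept
    og_81_unbal = g("d", c(70, 3, 3, 3, 2)),     # ratio 35 > 3: dropped
    og_80_unbal = g("e", c(70, 3, 3, 2, 2))      # 80 genes: balance not tested
  ))
  out <- filter_orthogroups(tbl)
  expect_setequal(names(out$groups), c("og_small", "og_81_bal", "og_80_unbal"))
})

test_that("similarity is symmetric, unit on identicals, and matches the DP oracle", {
  set.seed(30)
  sub <- gutmap:::.blosum62()
  s <- c(p1 = random_protein(50), p2 = random_protein(50))
  v <- strsplit(s[["p1"]], "")[[1]]
  v[25] <- if (v[25] == "A") "W" else "A"
  s[["p3"]] <- paste(v, collapse = "")     # p1 with one substitution
  S <- pairwise_similarity(s)
  expect_equal(max(abs(S - t(S))), 0)
  expect_equal(unname(diag(S)), rep(1, 3))
  Sid <- pairwise_similarity(c(a = s[["p1"]], b = s[["p1"]]))
  expect_equal(Sid["a", "b"], 1.0, tolerance = 1e-12)
  # raw scores against the independent textbook DP, including gapped pairs
  raw <- pairwise_similarity(s, normalize = FALSE)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    ora <- sw_oracle(s[[pair[1]]], s[[pair[2]]], sub)
    expect_equal(raw[pair[1], pair[2]], ora, tolerance = 1e-9)
  }
  gapped <- c(a = s[["p1"]],
              b = paste(strsplit(s[["p1"]], "")[[1]][-(10:13)], collapse = ""))
  raw2 <- pairwise_similarity(gapped, normalize = FALSE)
  expect_equal(raw2["a", "b"], sw_oracle(gapped[["a"]], gapped[["b"]], sub),
               tolerance = 1e-9)
  expect_error(pairwise_similarity(c(x = "MKTA", y = "MKBZ")), "y")
})

test_that("best ancestral orthologue follows mean cross-species similarity", {
  set.seed(31)
  anc <- random_protein(80)
  mut <- function(s, rate) {
    v <- strsplit(s, "")[[1]]
    hit <- runif(length(v)) < rate
    v[hit] <- vapply(v[hit], function(ch)
      sample(setdiff(c("A","C","D","E","F","G","H","I","K","L","M","N",
                       "P","Q","R","S","T","V","W","Y"), ch), 1), "")
    paste(v, collapse = "")
  }
  group <- list(sp1 = c(sp1_a = mut(anc, 0.1), sp1_b = mut(anc, 0.5)),
                sp2 = c(sp2_a = mut(anc, 0.1)),
                sp3 = c(sp3_a = mut(anc, 0.1)))
  res <- best_ancestral_orthologue(group)
  expect_identical(res$gene[res$species == "sp1"], "sp1_a")
  expect_identical(res$gene[res$species == "sp2"], "sp2_a")
  expect_equal(res$n_candidates, c(2L, 1L, 1L))
  expect_false(is.na(res$margin[res$species == "sp1"]))
  # identical paralogs tie-break to the lexicographically smaller id
  group2 <- list(sp1 = c(sp1_z = anc, sp1_a = anc),
                 sp2 = c(sp2_a = mut(anc, 0.1)))
  res2 <- best_ancestral_orthologue(group2)
  expect_identical(res2$gene[res2$species == "sp1"], "sp1_a")
  # stability: adding a strictly worse paralog never changes the choice
  group3 <- group
  group3$sp1 <- c(group3$sp1, sp1_c = mut(anc, 0.8))
  res3 <- best_ancestral_orthologue(group3)
  expect_identical(res3$gene[res3$species == "sp1"], "sp1_a")
})

test_that("TF flags expand to whole orthogroups and are idempotent", {
  tbl <- og_table(og1 = list(sp1 = "s1_a", sp2 = c("s2_a", "s2_b")),
                  og2 = list(sp1 = "s1_b", sp2 = "s2_c"))
  flags <- expand_tf_flags(c("s2_b"), tbl)
  expect_identical(unname(flags), c(TRUE, FALSE))
  # idempotent: re-expanding from all member genes of flagged groups
  genes_flagged <- unlist(tbl$groups[flags])
  expect_identical(expand_tf_flags(genes_flagged, tbl), flags)
  expect_identical(unname(expand_tf_flags(character(0), tbl)),
                   c(FALSE, FALSE))
})

test_that("manual overrides dissolve and regroup orthogroups", {
  tbl <- og_table(og1 = list(sp1 = "s1_hox1", sp2 = "s2_hox1"),
                  og2 = list(sp1 = "s1_hox2", sp2 = "s2_hox2x"),
                  og3 = list(sp1 = "s1_x", sp2 = "s2_x"))
  expect_identical(apply_overrides(tbl, NULL), tbl)
  ov <- data.frame(orthogroup = "OGHOX01",
                   species = c("sp1", "sp2", "sp1", "sp2"),
                   gene = c("s1_hox1", "s2_hox1", "s1_hox2", "s2_hox2x"))
  out <- apply_overrides(tbl, ov)
  expect_setequal(names(out$groups), c("og3", "OGHOX01"))
  expect_setequal(unlist(out$groups$OGHOX01),
                  c("s1_hox1", "s2_hox1", "s1_hox2", "s2_hox2x"))
  dup <- rbind(ov, ov[1, ])
  expect_error(apply_overrides(tbl, dup), "more than once")
  bad <- ov; bad$gene[1] <- "missing_gene"
  expect_error(apply_overrides(tbl, bad), "absent")
})

test_that("a 21-to-8 regrouping scheme is expressible", {
  # 21 fragmented single-family orthogroups across 3 species, regrouped into
  # 8 position-defined orthogroups
  genes <- expand.grid(sp = paste0("sp", 1:3), pos = 1:7,
                       stringsAsFactors = FALSE)
  genes$gene <- sprintf("%s_hox%d", genes$sp, genes$pos)
  groups <- lapply(seq_len(21), function(i)
    stats::setNames(list(genes$gene[i]), genes$sp[i]))
  names(groups) <- sprintf("OG%04d", seq_len(21))
  groups$OG_other <- list(sp1 = "sp1_x", sp2 = "sp2_x")
  tbl <- orthology_table(groups, species = paste0("sp", 1:3))
  new_og <- sprintf("OG000PG%02d", c(1:6, 7, 8))
  ov <- data.frame(orthogroup = new_og[c(genes$pos, 8)[seq_len(21)]],
                   species = genes$sp, gene = genes$gene)
  ov$orthogroup[genes$pos == 7] <- "OG000PG0708"  # merged neighbour group
  out <- apply_overrides(tbl, ov)
  expect_equal(length(out$groups), 1 + length(unique(ov$orthogroup)))
  expect_true("OG_other" %in% names(out$groups))
})

test_that("integration keeps only orthogroups expressed in every species", {
  cfg <- synth_config(n_species = 3, segments_per_species = c(8, 7, 9),
                      n_orthogroups = 120, paralog_rate = 0.2, seq_len = 60,
                      module_spec = transform(default_module_spec(),
                                              n_genes = 8),
                      seed = 32)
  sim <- simulate_gut_study(cfg)
  zs <- lapply(sim$datasets, function(d) zscore_rows(preprocess_species(d)))
  resolved <- resolve_orthogroups(sim$orthology, sim$sequences)
  tf <- sim$truth$tf
  im <- integrate_species(zs, resolved, tf_flags = tf)
  # present in every species' filtered set
  for (sp in names(zs)) {
    genes <- im$genes[, sp]
    expect_true(all(genes %in% rownames(zs[[sp]]$x)))
  }
  # an orthogroup dropped in one species is absent
  dropped <- setdiff(sim$orthology$species, character(0))
  missing_og <- setdiff(names(sim$orthology$groups), im$row_meta$orthogroup)
  for (og in utils::head(missing_og, 5)) {
    gene_by_sp <- vapply(im$species, function(sp)
      resolved$gene[resolved$orthogroup == og & resolved$species == sp][1], "")
    expressed <- vapply(im$species, function(sp)
      gene_by_sp[[sp]] %in% rownames(zs[[sp]]$x), logical(1))
    expect_false(all(expressed))
  }
  # per-species sub-rows inherit the z-score moments
  for (sp in im$species) {
    sel <- im$col_meta$species == sp
    sub <- im$x[, sel]
    nonconst <- apply(sub, 1, sd) > 0
    expect_true(all(abs(rowMeans(sub[nonconst, ])) < 1e-10))
    expect_true(all(abs(apply(sub[nonconst, ], 1, sd) - 1) < 1e-10))
  }
  # planted module peaks survive integration
  mod_ogs <- intersect(im$row_meta$orthogroup,
                       names(sim$truth$archetype)[
                         grepl("^module:", sim$truth$archetype)])
  sel1 <- im$col_meta$species == "sp1"
  hits <- vapply(mod_ogs, function(og) {
    prof <- im$x[og, sel1][order(im$col_meta$ap_rank[sel1])]
    abs(which.max(prof) - sim$truth$peak[og, "sp1"]) <= 2
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  expect_error(integrate_species(zs[1:2], resolved[resolved$species == "sp1", ]),
               "missing")
})

test_that("integrated columns group by AP position, not species", {
  fix <- module_integrated(n_genes_per_module = 15, noise = 0.3, seed = 33)
  im <- fix$im
  d <- stats::as.dist(1 - cor(im$x))
  cl <- stats::cutree(stats::hclust(d, method = "average"), k = 3)
  sp_lab <- im$col_meta$species
  ap_lab <- cut(im$col_meta$ap_rank / ave(im$col_meta$ap_rank,
                                          im$col_meta$species, FUN = max),
                breaks = c(0, 1 / 3, 2 / 3, 1), labels = FALSE)
  ari_sp <- mclust::adjustedRandIndex(cl, sp_lab)
  ari_ap <- mclust::adjustedRandIndex(cl, ap_lab)
  expect_lt(ari_sp, ari_ap)
})
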