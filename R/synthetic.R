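#' Configuration for the multi-species gut simulator
#'
#' Describes a comparative study design: several bilaterian species, each with
#' an ordered series of gut segments sampled in replicate, profiled by bulk
#' RNA-seq, linked by an orthology table with occasional within-species
#' paralogy. Expression archetypes are planted so every downstream stage of
#' the pipeline has a known truth to recover: an anterior "block" of uniformly
#' high expression ending at a planted boundary, posterior "gradient" genes
#' ramping over the post-boundary segments, unimodal AP modules conserved
#' across species up to positional jitter, terminal genes peaking at one or
#' both gut ends (the end drawn independently per species), and flat nulls.
#'
#' @param n_species number of species.
#' @param segments_per_species integer vector (length `n_species`) of gut
#'   segments per species; each must be >= 4 (>= 6 emulates real designs).
#' @param replicates biological replicates per segment (each replicate is one
#'   batch).
#' @param n_orthogroups total orthogroups simulated.
#' @param tf_fraction fraction of orthogroups flagged as transcription
#'   factors. All module orthogroups are TFs; random non-module orthogroups
#'   top the set up to this fraction.
#' @param module_spec data.frame with columns `module`, `center` (relative AP
#'   position in \[0,1\]), `width` (relative bump width), `n_genes`,
#'   `jitter_sd` (per-species positional jitter, relative units).
#' @param boundary_rel relative position of the block/gradient boundary in
#'   (0,1); scalar or one value per species.
#' @param frac_block,frac_gradient,frac_terminal fractions of orthogroups
#'   assigned to each archetype; remaining (non-module) orthogroups are null.
#' @param nb_dispersion c(meanlog, sdlog) of the log-normal law the gene-wise
#'   negative-binomial dispersion is drawn from; meanlog = -Inf gives the
#'   Poisson limit.
#' @param libsize_sigma sd of log-normal library-size factors.
#' @param batch_sd sd of log-normal gene-by-replicate batch factors.
#' @param paralog_rate fraction of orthogroups carrying an extra paralog in
#'   one species.
#' @param seq_len ancestor protein length (residues).
#' @param mut_rate_ortho per-site substitution probability of each species'
#'   primary orthologue relative to the ancestor.
#' @param mut_rate_extra additional per-site substitution probability of
#'   extra paralogs (they diverge faster than the ancestor-like copy).
#' @param seed integer master seed; all substreams derive from it, so a fixed
#'   seed + config reproduces counts, sequences and truth exactly.
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(n_species = 5,
                         segments_per_species = c(10, 8, 6, 9, 7),
                         replicates = 3,
                         n_orthogroups = 2000,
                         tf_fraction = 0.15,
                         module_spec = default_module_spec(),
                         boundary_rel = 0.45,
                         frac_block = 0.12,
                         frac_gradient = 0.12,
                         frac_terminal = 0.06,
                         nb_dispersion = c(meanlog = log(0.08), sdlog = 0.4),
                         libsize_sigma = 0.3,
                         batch_sd = 0.15,
                         paralog_rate = 0.3,
                         seq_len = 300,
                         mut_rate_ortho = 0.1,
                         mut_rate_extra = 0.3,
                         seed = 1L) {
  cfg <- list(n_species = as.integer(n_species),
              segments_per_species = as.integer(segments_per_species),
              replicates = as.integer(replicates),
              n_orthogroups = as.integer(n_orthogroups),
              tf_fraction = tf_fraction,
              module_spec = as.data.frame(module_spec),
              boundary_rel = rep_len(boundary_rel, n_species),
              frac_block = frac_block, frac_gradient = frac_gradient,
              frac_terminal = frac_terminal,
              nb_dispersion = nb_dispersion,
              libsize_sigma = libsize_sigma, batch_sd = batch_sd,
              paralog_rate = paralog_rate, seq_len = as.integer(seq_len),
              mut_rate_ortho = mut_rate_ortho, mut_rate_extra = mut_rate_extra,
              seed = as.integer(seed))
  if (length(cfg$segments_per_species) != cfg$n_species)
    stop("segments_per_species must have one entry per species")
  if (any(cfg$segments_per_species < 4))
    stop("each species needs at least 4 segments")
  fr <- c(cfg$frac_block, cfg$frac_gradient, cfg$frac_terminal,
          cfg$tf_fraction, cfg$paralog_rate,
          cfg$mut_rate_ortho, cfg$mut_rate_extra)
  if (any(fr < 0 | fr > 1)) stop("all proportions must lie in [0, 1]")
  if (cfg$frac_block + cfg$frac_gradient + cfg$frac_terminal > 1)
    stop("archetype fractions must sum to at most 1")
  if (any(cfg$boundary_rel <= 0 | cfg$boundary_rel >= 1))
    stop("boundary_rel must lie strictly inside (0, 1)")
  n_module <- sum(cfg$module_spec$n_genes)
  n_arch <- round(cfg$n_orthogroups *
                    (cfg$frac_block + cfg$frac_gradient + cfg$frac_terminal))
  if (n_module + n_arch > cfg$n_orthogroups)
    stop("module genes plus archetype fractions exceed n_orthogroups")
  if (any(cfg$module_spec$center < 0 | cfg$module_spec$center > 1))
    stop("module centers must lie in [0, 1]")
  class(cfg) <- "synth_config"
  cfg
}

#' Default conserved AP module layout
#'
#' Five modules spanning the axis from anterior to posterior, mirroring the
#' study design the simulator emulates (five main AP gene modules).
#' @export
default_module_spec <- function() {
  data.frame(module = 1:5,
             center = c(0.06, 0.28, 0.5, 0.72, 0.94),
             width = 0.12,
             n_genes = 40,
             jitter_sd = 0.05)
}

.species_ids <- function(cfg) sprintf("sp%d", seq_len(cfg$n_species))
.og_ids <- function(cfg) sprintf("OG%06d", seq_len(cfg$n_orthogroups))

# deterministic substream: each generator stage reseeds from the master seed
.with_substream <- function(cfg, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((cfg$seed + offset) %% .Machine$integer.max)
  expr
}

# archetype label per orthogroup: block / gradient / terminal / module:k / null
.assign_archetypes <- function(cfg) {
  n <- cfg$n_orthogroups
  n_block <- round(n * cfg$frac_block)
  n_grad <- round(n * cfg$frac_gradient)
  n_term <- round(n * cfg$frac_terminal)
  mod_lab <- rep(sprintf("module:%d", cfg$module_spec$module),
                 cfg$module_spec$n_genes)
  lab <- c(rep("block", n_block), rep("gradient", n_grad),
           rep("terminal", n_term), mod_lab)
  c(lab, rep("null", n - length(lab)))
}

#' Noiseless mean expression profiles plus planted truth
#'
#' Builds, for every species, the orthogroup x segment matrix of programmed
#' mean expression implied by each orthogroup's archetype, together with the
#' complete `synth_truth` record (archetypes, boundaries, per-species peak
#' positions, TF flags) downstream stages are scored against.
#'
#' @param cfg a [synth_config()].
#' @return list with `means` (list of matrices, one per species) and `truth`.
#' @export
make_profiles <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  .with_substream(cfg, 1L, {
    ogs <- .og_ids(cfg)
    sps <- .species_ids(cfg)
    arch <- .assign_archetypes(cfg)
    names(arch) <- ogs
    n_og <- cfg$n_orthogroups
    baseline <- stats::rlnorm(n_og, meanlog = log(200), sdlog = 0.8)
    lo <- 0.05

    boundary <- integer(cfg$n_species)
    names(boundary) <- sps
    peaks <- matrix(NA_real_, n_og, cfg$n_species, dimnames = list(ogs, sps))
    ends <- matrix(NA_character_, n_og, cfg$n_species, dimnames = list(ogs, sps))
    centers_rel <- matrix(NA_real_, n_og, cfg$n_species,
                          dimnames = list(ogs, sps))

    is_mod <- grepl("^module:", arch)
    mod_idx <- as.integer(sub("module:", "", arch[is_mod]))
    mod_center <- cfg$module_spec$center[mod_idx]
    mod_width <- cfg$module_spec$width[mod_idx]
    mod_jit <- cfg$module_spec$jitter_sd[mod_idx]
    term_ogs <- which(arch == "terminal")
    grad_pow <- stats::runif(n_og, 0.7, 1.4)   # per-gene ramp curvature
    grad_onset <- stats::runif(n_og)           # relative onset inside the posterior

    means <- vector("list", cfg$n_species)
    names(means) <- sps
    for (s in seq_len(cfg$n_species)) {
      n_seg <- cfg$segments_per_species[s]
      b <- 1L + as.integer(round(cfg$boundary_rel[s] * (n_seg - 1)))
      b <- max(2L, min(n_seg - 1L, b))
      boundary[s] <- b
      pos <- seq_len(n_seg)
      shape <- matrix(1, n_og, n_seg, dimnames = list(ogs, NULL))

      # logistic step steep enough that block genes are effectively at the
      # floor from segment b onward (<2% residual amplitude): the planted
      # boundary must be low *after* b, not half-way down
      blk <- arch == "block"
      shape[blk, ] <- rep(lo + (1 - lo) * stats::plogis((b - 0.5 - pos) * 8),
                          each = sum(blk))
      # gradient genes ramp monotonically over the post-boundary segments,
      # each from its own onset position: the stagger is what makes
      # posterior segment-segment similarity decay with AP distance
      grd <- arch == "gradient"
      for (i in which(grd)) {
        # onsets start one segment before the boundary so the first
        # posterior segment already carries gradient signal (the planted
        # boundary must be identifiable); anterior segments stay at floor
        onset <- (b - 1) + grad_onset[i] * (n_seg - b)
        ramp <- pmax(0, (pos - onset) / (n_seg - onset))
        shape[i, ] <- lo + (1 - lo) * ifelse(pos < b, 0, ramp^grad_pow[i])
      }

      if (any(is_mod)) {
        jit <- stats::rnorm(sum(is_mod), 0, mod_jit)
        ctr_rel <- pmin(1, pmax(0, mod_center + jit))
        centers_rel[is_mod, s] <- ctr_rel
        ctr_pos <- 1 + ctr_rel * (n_seg - 1)
        sdw <- pmax(0.75, mod_width * n_seg)
        shape[is_mod, ] <- lo + (1 - lo) *
          exp(-(outer(ctr_pos, pos, "-"))^2 / (2 * sdw^2))
      }

      if (length(term_ogs)) {
        end_draw <- sample(c("anterior", "posterior", "both"),
                           length(term_ogs), replace = TRUE)
        ends[term_ogs, s] <- end_draw
        sdt <- max(0.75, 0.08 * n_seg)
        bump_a <- exp(-(pos - 1)^2 / (2 * sdt^2))
        bump_p <- exp(-(pos - n_seg)^2 / (2 * sdt^2))
        for (j in seq_along(term_ogs)) {
          bump <- switch(end_draw[j],
                         anterior = bump_a, posterior = bump_p,
                         both = pmax(bump_a, bump_p))
          shape[term_ogs[j], ] <- lo + (1 - lo) * bump
        }
      }
      # null rows stay flat (shape 1)
      m <- shape * baseline
      nonnull <- arch != "null"
      peaks[nonnull, s] <- apply(shape[nonnull, , drop = FALSE], 1, which.max)
      means[[s]] <- m
    }

    tf <- rep(FALSE, n_og)
    tf[is_mod] <- TRUE
    n_extra <- max(0L, round(cfg$tf_fraction * n_og) - sum(tf))
    pool <- which(!tf)
    if (n_extra > 0 && length(pool))
      tf[sample(pool, min(n_extra, length(pool)))] <- TRUE
    names(tf) <- ogs

    truth <- structure(list(archetype = arch, boundary = boundary,
                            peak = peaks, terminal_end = ends,
                            module_center_rel = centers_rel,
                            tf = tf, baseline = baseline,
                            batch = NULL, ancestor_like = NULL),
                       class = "synth_truth")
    list(means = means, truth = truth)
  })
}

#' Sample negative-binomial counts from programmed means
#'
#' Adds the three nuisance layers real bulk designs carry: log-normal library
#' sizes, gene-by-replicate multiplicative batch effects, and gene-wise
#' negative-binomial overdispersion. Replicate id doubles as batch id.
#'
#' @param profiles output of [make_profiles()].
#' @param cfg the same [synth_config()].
#' @return list with `datasets` (one [expression_dataset()] per species, raw
#'   stage) and `truth` updated with the drawn batch factors.
#' @export
sample_counts <- function(profiles, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  .with_substream(cfg, 2L, {
    sps <- .species_ids(cfg)
    n_og <- cfg$n_orthogroups
    phi <- if (is.finite(cfg$nb_dispersion[[1]]))
      stats::rlnorm(n_og, cfg$nb_dispersion[[1]], cfg$nb_dispersion[[2]])
    else rep(0, n_og)
    datasets <- vector("list", cfg$n_species)
    names(datasets) <- sps
    batch_truth <- vector("list", cfg$n_species)
    names(batch_truth) <- sps
    for (s in seq_len(cfg$n_species)) {
      m <- profiles$means[[s]]
      n_seg <- ncol(m)
      reps <- cfg$replicates
      lib <- exp(stats::rnorm(n_seg * reps, 0, cfg$libsize_sigma))
      bat <- matrix(exp(stats::rnorm(n_og * reps, 0, cfg$batch_sd)),
                    n_og, reps)
      cols <- expand.grid(rep = seq_len(reps), seg = seq_len(n_seg))
      cols <- cols[order(cols$seg, cols$rep), ]
      mu <- m[, cols$seg, drop = FALSE] * bat[, cols$rep, drop = FALSE]
      mu <- sweep(mu, 2, lib, "*")
      cnt <- matrix(0L, n_og, ncol(mu))
      for (g in seq_len(n_og)) {
        cnt[g, ] <- if (phi[g] > 0)
          stats::rnbinom(ncol(mu), mu = mu[g, ], size = 1 / phi[g])
        else stats::rpois(ncol(mu), mu[g, ])
      }
      storage.mode(cnt) <- "integer"
      # counts are indexed by the species' primary gene id (extra paralogs
      # exist in the proteome and orthology table but are not quantified)
      rownames(cnt) <- sprintf("%s_%s", sps[s], rownames(m))
      sample_id <- sprintf("%s_S%02d_r%d", sps[s], cols$seg, cols$rep)
      colnames(cnt) <- sample_id
      meta <- data.frame(sample = sample_id,
                         segment = sprintf("S%02d", cols$seg),
                         ap_rank = as.integer(cols$seg),
                         replicate = sprintf("r%d", cols$rep))
      datasets[[s]] <- expression_dataset(cnt, meta, sps[s], stage = "raw")
      rownames(bat) <- rownames(m)
      colnames(bat) <- sprintf("r%d", seq_len(reps))
      batch_truth[[s]] <- bat
    }
    truth <- profiles$truth
    truth$batch <- batch_truth
    list(datasets = datasets, truth = truth)
  })
}

.AA20 <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")

.mutate_seq <- function(chars, rate) {
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    repl <- sample(.AA20, sum(hit), replace = TRUE)
    # substitute to a *different* residue so `rate` is the realized rate
    same <- repl == chars[hit]
    while (any(same)) {
      repl[same] <- sample(.AA20, sum(same), replace = TRUE)
      same <- repl == chars[hit]
    }
    chars[hit] <- repl
  }
  chars
}

#' Simulate ancestor-derived protein sequences and the orthology table
#'
#' Each orthogroup receives one random ancestor protein; every species carries
#' a primary orthologue mutated from it at `mut_rate_ortho`, and a
#' `paralog_rate` fraction of orthogroups carry one extra, faster-evolving
#' paralog (rate `mut_rate_ortho + mut_rate_extra`) in one random species —
#' the 1-to-many case the best-ancestral-orthologue resolution must undo.
#'
#' @param cfg a [synth_config()].
#' @param truth a `synth_truth` (updated in the return value with the id of
#'   the ancestor-like gene per orthogroup and species).
#' @return list with `sequences` (named list of [Biostrings::AAStringSet]
#'   per species), `orthology` (an `orthology_table`) and `truth`.
#' @export
make_sequences <- function(cfg, truth) {
  stopifnot(inherits(cfg, "synth_config"))
  .with_substream(cfg, 3L, {
    ogs <- .og_ids(cfg)
    sps <- .species_ids(cfg)
    n_og <- cfg$n_orthogroups
    anc <- replicate(n_og, sample(.AA20, cfg$seq_len, replace = TRUE),
                     simplify = FALSE)
    has_extra <- stats::runif(n_og) < cfg$paralog_rate
    extra_sp <- sample.int(cfg$n_species, n_og, replace = TRUE)

    seqs <- lapply(sps, function(s) character(0))
    names(seqs) <- sps
    tbl <- vector("list", n_og)
    names(tbl) <- ogs
    anc_like <- matrix(NA_character_, n_og, cfg$n_species,
                       dimnames = list(ogs, sps))
    for (i in seq_len(n_og)) {
      members <- vector("list", cfg$n_species)
      names(members) <- sps
      for (s in seq_len(cfg$n_species)) {
        gid <- sprintf("%s_%s", sps[s], ogs[i])  # primary gene id
        seqs[[s]][gid] <- paste(.mutate_seq(anc[[i]], cfg$mut_rate_ortho),
                                collapse = "")
        members[[s]] <- gid
        anc_like[i, s] <- gid
        if (has_extra[i] && extra_sp[i] == s) {
          pid <- paste0(gid, "_p2")
          seqs[[s]][pid] <- paste(
            .mutate_seq(anc[[i]], cfg$mut_rate_ortho + cfg$mut_rate_extra),
            collapse = "")
          members[[s]] <- c(members[[s]], pid)
        }
      }
      tbl[[i]] <- members
    }
    sequences <- lapply(seqs, Biostrings::AAStringSet)
    truth$ancestor_like <- anc_like
    truth$ancestor_seq <- stats::setNames(
      vapply(anc, paste, "", collapse = ""), ogs)
    list(sequences = sequences,
         orthology = orthology_table(tbl, species = sps),
         truth = truth)
  })
}

#' Run the whole generator
#'
#' Convenience wrapper chaining [make_profiles()], [sample_counts()] and
#' [make_sequences()]; everything downstream of the wet lab, in one call.
#'
#' @param cfg a [synth_config()].
#' @return list with `datasets`, `orthology`, `sequences`, `truth`, `means`
#'   and the echoed `config`.
#' @export
simulate_gut_study <- function(cfg) {
  prof <- make_profiles(cfg)
  cnt <- sample_counts(prof, cfg)
  seq <- make_sequences(cfg, cnt$truth)
  list(datasets = cnt$datasets, orthology = seq$orthology,
       sequences = seq$sequences, truth = seq$truth,
       means = prof$means, config = cfg)
}

#' Write a simulated study to disk
#'
#' Exports counts (TSV and MatrixMarket), sample metadata, the orthology
#' table in OrthoFinder's `Orthogroups.tsv` dialect, per-species protein
#' FASTA, and the planted truth as JSON.
#'
#' @param sim output of [simulate_gut_study()].
#' @param dir output directory (created if absent).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(sim$datasets)) {
    ds <- sim$datasets[[s]]
    write_counts_tsv(ds$x, file.path(dir, paste0(s, "_counts.tsv")),
                     stage_comment = ds$stage)
    write_counts_mm(ds$x, file.path(dir, paste0(s, "_counts.mtx")))
    write_metadata_tsv(ds$meta, file.path(dir, paste0(s, "_meta.tsv")))
    Biostrings::writeXStringSet(sim$sequences[[s]],
                                file.path(dir, paste0(s, "_proteins.fasta")))
  }
  write_orthogroups(sim$orthology, file.path(dir, "Orthogroups.tsv"))
  truth <- sim$truth
  truth_json <- list(archetype = as.list(truth$archetype),
                     boundary = as.list(truth$boundary),
                     tf = as.list(truth$tf),
                     peak = apply(truth$peak, 1, as.list),
                     ancestor_like = apply(truth$ancestor_like, 1, as.list))
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
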