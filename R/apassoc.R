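#' Smooth-trend association of a profile with AP position
#'
#' Tests whether a gene's expression profile varies along the gut by ordinary
#' least squares on an orthogonal polynomial basis of AP rank (default cubic,
#' reduced automatically when segments are few) with an exact F-test against
#' the intercept-only model. With 5-10 support points per species this is a
#' deterministic, parameter-light stand-in for spline-based trend models, and
#' is invariant to affine transforms of the profile.
#'
#' @param profile numeric vector of (z-scored) values, one per segment.
#' @param ap_ranks integer AP ranks, same length.
#' @param degree polynomial degree (capped at n - 2).
#' @return list with `statistic` (F), `p_value`, `r_squared`, `fitted`
#'   (fitted profile, for peak localization) and `degree` used.
#' @export
fit_ap_trend <- function(profile, ap_ranks, degree = 3) {
  n <- length(profile)
  stopifnot(length(ap_ranks) == n)
  if (stats::var(profile) == 0)
    return(list(statistic = 0, p_value = 1, r_squared = 0,
                fitted = rep(mean(profile), n), degree = 0L))
  degree <- max(1L, min(as.integer(degree), n - 2L))
  fit <- stats::lm(profile ~ poly(ap_ranks, degree))
  # noiseless profiles fit perfectly; summary.lm warns, harmlessly
  s <- suppressWarnings(summary(fit))
  fs <- s$fstatistic
  p <- stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
  list(statistic = unname(fs[1]), p_value = unname(p),
       r_squared = s$r.squared, fitted = unname(stats::fitted(fit)),
       degree = degree)
}

#' Classify a fitted profile as terminal or internal
#'
#' Locates the primary peak of the fitted AP profile. The gene is `anterior`
#' if the peak falls in the first tercile of relative AP position,
#' `posterior` in the last tercile, `both` if a secondary local maximum in
#' the opposite tercile reaches at least `secondary_ratio` of the primary
#' peak's amplitude above the profile mean, and `internal` otherwise.
#'
#' @param fitted numeric fitted profile over segments (AP order).
#' @param ap_ranks integer AP ranks.
#' @param secondary_ratio amplitude fraction a secondary peak must reach.
#' @return one of `"anterior"`, `"posterior"`, `"both"`, `"internal"`.
#' @export
classify_terminal <- function(fitted, ap_ranks, secondary_ratio = 0.5) {
  n <- length(fitted)
  ord <- order(ap_ranks)
  f <- fitted[ord]
  rel <- (seq_len(n) - 1) / (n - 1)
  locmax <- which(vapply(seq_len(n), function(i) {
    left <- if (i > 1) f[i] >= f[i - 1] else TRUE
    right <- if (i < n) f[i] >= f[i + 1] else TRUE
    left && right
  }, logical(1)))
  amp <- f - mean(f)
  primary <- locmax[which.max(f[locmax])]
  lab <- if (rel[primary] <= 1 / 3) "anterior"
  else if (rel[primary] >= 2 / 3) "posterior"
  else "internal"
  if (lab %in% c("anterior", "posterior")) {
    opp <- if (lab == "anterior") locmax[rel[locmax] >= 2 / 3]
    else locmax[rel[locmax] <= 1 / 3]
    opp <- setdiff(opp, primary)
    if (length(opp) && amp[primary] > 0 &&
        max(amp[opp]) >= secondary_ratio * amp[primary])
      lab <- "both"
  }
  lab
}

#' Screen for conserved AP-associated orthogroups
#'
#' Fits the AP trend test per orthogroup within every species, adjusts
#' p-values by Benjamini-Hochberg within each species, and flags orthogroups
#' associated (q below threshold) in all species (or at least `min_species`
#' of them) as conserved AP-associated. Each orthogroup also receives a
#' per-species terminal classification from its fitted profile, and a
#' cross-species terminal flag: terminal at some end in every species, but
#' not the same single end everywhere — the signature of terminus markers
#' that swap ends across lineages.
#'
#' @param im an [integrate_species()] result.
#' @param q_threshold BH-adjusted significance threshold.
#' @param tf_only restrict the screen to TF-flagged orthogroups.
#' @param min_species number of species an orthogroup must be associated in
#'   (default: all).
#' @param degree polynomial degree for [fit_ap_trend()].
#' @param secondary_ratio passed to [classify_terminal()].
#' @return object of class `ap_association`: `stats` (long data.frame:
#'   orthogroup x species with F, p, q, R-squared, peak rank, terminal
#'   class), `conserved` (character vector of conserved orthogroup ids),
#'   `terminal` (character vector of cross-species terminal orthogroups),
#'   and the thresholds used.
#' @export
screen_conserved <- function(im, q_threshold = 0.05, tf_only = FALSE,
                             min_species = NULL, degree = 3,
                             secondary_ratio = 0.5) {
  species <- im$species
  if (is.null(min_species)) min_species <- length(species)
  ogs <- im$row_meta$orthogroup
  if (tf_only) {
    if (all(is.na(im$row_meta$tf)))
      stop("tf_only requested but the integrated matrix has no TF flags")
    ogs <- ogs[im$row_meta$tf %in% TRUE]
  }
  rows <- list()
  for (sp in species) {
    sel <- im$col_meta$species == sp
    ranks <- im$col_meta$ap_rank[sel]
    sub <- im$x[ogs, sel, drop = FALSE]
    ps <- numeric(length(ogs))
    for (i in seq_along(ogs)) {
      ft <- fit_ap_trend(sub[i, ], ranks, degree = degree)
      term <- classify_terminal(ft$fitted, ranks, secondary_ratio)
      rows[[length(rows) + 1]] <- data.frame(
        orthogroup = ogs[i], species = sp, statistic = ft$statistic,
        p_value = ft$p_value, r_squared = ft$r_squared,
        peak_rank = ranks[order(ranks)][which.max(ft$fitted[order(ranks)])],
        terminal_class = term)
      ps[i] <- ft$p_value
    }
  }
  stats_df <- do.call(rbind, rows)
  stats_df$q_value <- NA_real_
  for (sp in species) {
    sel <- stats_df$species == sp
    stats_df$q_value[sel] <- stats::p.adjust(stats_df$p_value[sel],
                                             method = "BH")
  }
  assoc <- with(stats_df, tapply(q_value < q_threshold, orthogroup, sum))
  conserved <- names(assoc)[assoc >= min_species]
  term_tab <- with(stats_df,
                   tapply(terminal_class, orthogroup, function(x) x,
                          simplify = FALSE))
  terminal <- names(term_tab)[vapply(term_tab, function(tc) {
    all(tc %in% c("anterior", "posterior", "both")) &&
      !all(tc == "anterior") && !all(tc == "posterior")
  }, logical(1))]
  structure(list(stats = stats_df,
                 conserved = sort(conserved), terminal = sort(terminal),
                 q_threshold = q_threshold, min_species = min_species,
                 species = species),
            class = "ap_association")
}

#' @export
print.ap_association <- function(x, ...) {
  cat(sprintf("ap_association: %d orthogroups x %d species tested; %d conserved AP-associated (q < %g in >= %d species); %d cross-species terminal\n",
              length(unique(x$stats$orthogroup)), length(x$species),
              length(x$conserved), x$q_threshold, x$min_species,
              length(x$terminal)))
  invisible(x)
}
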