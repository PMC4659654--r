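# Genome-size statistics: per-repeat-class linear correlation with monoploid
# genome size, and the average contribution of each class to pairwise
# genome-size differences between species.

#' Correlation of repeat abundance with genome size
#'
#' Ordinary least squares of absolute repeat amount (Mbp/1Cx) on monoploid
#' genome size per repeat class across species; returns the coefficient of
#' determination and the regression F-test probability.  Classes observed in
#' fewer than 3 species are flagged undefined.
#'
#' @param abundance abundance table (`species`, `repeat_class`,
#'   `mbp_per_1Cx`).
#' @param profiles `species_profiles` for the species involved.
#' @return data frame: `repeat_class`, `n_species`, `r_squared`, `p_value`,
#'   `abundance_min`, `abundance_max` (Mbp/1Cx extremes across species).
#' @export
correlate_with_genome_size <- function(abundance, profiles) {
  out <- list()
  for (cl in unique(abundance$repeat_class)) {
    rec <- abundance[abundance$repeat_class == cl, , drop = FALSE]
    g <- profiles$genome_size_1Cx[match(rec$species, profiles$code)] / 1e9
    y <- rec$mbp_per_1Cx
    ok <- !is.na(g) & !is.na(y)
    n <- sum(ok)
    if (n < 3) {
      out[[cl]] <- data.frame(repeat_class = cl, n_species = n,
                              r_squared = NA_real_, p_value = NA_real_,
                              abundance_min = suppressWarnings(min(y[ok])),
                              abundance_max = suppressWarnings(max(y[ok])),
                              stringsAsFactors = FALSE)
      next
    }
    if (stats::var(y[ok]) == 0) {
      r2 <- 0
      p <- NA_real_
    } else {
      fit <- stats::lm(y[ok] ~ g[ok])
      # summary.lm warns on exact fits (R^2 = 1); those are legitimate here
      sm <- suppressWarnings(summary(fit))
      r2 <- sm$r.squared
      p <- if (nrow(sm$coefficients) >= 2)
        stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                  lower.tail = FALSE) else NA_real_
    }
    out[[cl]] <- data.frame(repeat_class = cl, n_species = n,
                            r_squared = unname(r2), p_value = unname(p),
                            abundance_min = min(y[ok]),
                            abundance_max = max(y[ok]),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Average contribution of repeat classes to pairwise genome-size differences
#'
#' For every unordered species pair, oriented so that the first genome is the
#' larger, the contribution of a class is
#' `100 * (A_i - A_j) / (G_i - G_j)` with abundances and genome sizes in the
#' same units; the per-class statistic is the unweighted mean over pairs.
#' Negative values mean the class is on average larger in the smaller
#' genome.  Pairs with equal genome sizes are excluded and counted.
#'
#' @param abundance abundance table (`species`, `repeat_class`,
#'   `mbp_per_1Cx`).
#' @param profiles `species_profiles`.
#' @param weighted if `TRUE`, pairs are weighted by their genome-size
#'   difference (the default is the plain mean over pairs).
#' @return data frame: `repeat_class`, `avg_contribution_pct`, `n_pairs`,
#'   `n_degenerate_pairs`.
#' @export
pairwise_contribution <- function(abundance, profiles, weighted = FALSE) {
  species <- sort(unique(abundance$species))
  if (length(species) < 2) stop("need at least 2 species")
  g <- setNames(profiles$genome_size_1Cx[match(species, profiles$code)] / 1e6,
                species)  # Mbp, same unit as abundance
  prs <- utils::combn(species, 2)
  out <- list()
  for (cl in unique(abundance$repeat_class)) {
    rec <- abundance[abundance$repeat_class == cl, , drop = FALSE]
    a <- setNames(rec$mbp_per_1Cx, rec$species)[species]
    a[is.na(a)] <- 0
    contrib <- numeric(0)
    wts <- numeric(0)
    degenerate <- 0L
    for (k in seq_len(ncol(prs))) {
      s1 <- prs[1, k]; s2 <- prs[2, k]
      if (g[s1] == g[s2]) {
        degenerate <- degenerate + 1L
        next
      }
      if (g[s1] < g[s2]) { tmp <- s1; s1 <- s2; s2 <- tmp }
      dg <- g[s1] - g[s2]
      contrib <- c(contrib, 100 * (a[s1] - a[s2]) / dg)
      wts <- c(wts, dg)
    }
    avg <- if (length(contrib) == 0) NA_real_
           else if (weighted) sum(contrib * wts) / sum(wts)
           else mean(contrib)
    out[[cl]] <- data.frame(repeat_class = cl,
                            avg_contribution_pct = avg,
                            n_pairs = length(contrib),
                            n_degenerate_pairs = degenerate,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Combined per-class genome-size statistics table
#'
#' One row per repeat class with the correlation statistics, abundance
#' extremes and the average pairwise contribution, plus a closing
#' `all repeats` row computed on summed abundances.
#'
#' @inheritParams correlate_with_genome_size
#' @return data frame shaped like a per-class statistics table.
#' @export
contribution_table <- function(abundance, profiles) {
  corr <- correlate_with_genome_size(abundance, profiles)
  contrib <- pairwise_contribution(abundance, profiles)
  res <- merge(corr, contrib[c("repeat_class", "avg_contribution_pct")],
               by = "repeat_class")
  total <- stats::aggregate(mbp_per_1Cx ~ species, data = abundance,
                            FUN = sum)
  total$repeat_class <- "all repeats"
  tc <- correlate_with_genome_size(total, profiles)
  tp <- pairwise_contribution(total, profiles)
  all_row <- merge(tc, tp[c("repeat_class", "avg_contribution_pct")],
                   by = "repeat_class")
  res <- rbind(res[order(-res$r_squared), , drop = FALSE], all_row)
  rownames(res) <- NULL
  res
}
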