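# Population-vector correlation analysis of the ensemble spatial code.

#' Stack directional rate curves into a population matrix
#'
#' A population vector (PV) is the set of firing rates of all place cells
#' at one spatial bin. Left-lap and right-lap curves are stacked along
#' the bin axis (left block first), giving a (2 * bins) x cells matrix
#' whose rows are population vectors.
#'
#' @param cells list of [compute_rate_curves()] results (one per place
#'   cell, possibly pooled across animals within a group).
#' @return numeric matrix (2 * bins) x cells, with attribute `n_bins`
#'   (bins per direction block).
#' @export
build_population_vectors <- function(cells) {
  stopifnot(length(cells) >= 1L)
  nb <- length(cells[[1]]$left$rate)
  cols <- lapply(cells, function(cv) {
    if (length(cv$left$rate) != nb || length(cv$right$rate) != nb)
      stop("all cells must share the same spatial binning")
    c(cv$left$rate, cv$right$rate)
  })
  pv <- do.call(cbind, cols)
  rownames(pv) <- c(paste0("L", seq_len(nb)), paste0("R", seq_len(nb)))
  attr(pv, "n_bins") <- nb
  pv
}

#' Spearman correlation matrix of population vectors
#'
#' Pairwise Spearman rank correlation between all pairs of spatial-bin
#' population vectors (rows of the PV matrix), across the concatenated
#' left/right blocks. With the left block first, quadrants II (left x
#' left) and III (right x right) hold same-direction correlations and
#' quadrants I/IV (left x right and its transpose) opposite-direction
#' correlations. Bins with a constant population vector (no variation
#' across cells) yield undefined correlations and are masked `NA`.
#'
#' @param pv matrix from [build_population_vectors()].
#' @return symmetric (2 * bins) x (2 * bins) correlation matrix, with
#'   attribute `n_bins`.
#' @export
pv_correlation_matrix <- function(pv) {
  if (ncol(pv) < 2L) stop("need at least 2 cells for PV correlations")
  cc <- suppressWarnings(stats::cor(t(pv), method = "spearman",
                                    use = "pairwise.complete.obs"))
  sds <- apply(pv, 1L, stats::sd, na.rm = TRUE)
  bad <- is.na(sds) | sds == 0
  cc[bad, ] <- NA_real_
  cc[, bad] <- NA_real_
  attr(cc, "n_bins") <- attr(pv, "n_bins")
  cc
}

#' Distance-averaged PV correlation profile
#'
#' Averages correlation-matrix entries as a function of track distance
#' between the two bins. For the same-direction quadrants (left x left
#' pooled with right x right) the profile is over absolute distance
#' |i - j| >= 0. For the opposite-direction quadrants the signed offset
#' (left bin minus right bin) is retained, so an asymmetric central peak
#' — e.g. from prospective coding — stays visible; entries of quadrant I
#' and its transpose quadrant IV are pooled.
#'
#' @param corr matrix from [pv_correlation_matrix()].
#' @param quadrant_set `"same"` or `"opposite"` direction pairs.
#' @param bin_cm spatial bin size in cm (default 1), used to scale the
#'   distance axis.
#' @return data.frame with `distance_cm`, `mean_corr`, `sem_corr`, `n`;
#'   attribute `entries` holds the per-distance correlation values (for
#'   per-distance group tests).
#' @export
distance_profile <- function(corr, quadrant_set = c("same", "opposite"),
                             bin_cm = 1) {
  quadrant_set <- match.arg(quadrant_set)
  nb <- attr(corr, "n_bins")
  stopifnot(!is.null(nb), nrow(corr) == 2L * nb)
  iL <- seq_len(nb)
  iR <- nb + seq_len(nb)
  if (quadrant_set == "same") {
    ds <- 0:(nb - 1L)
    entries <- lapply(ds, function(d) {
      i <- seq_len(nb - d)
      v <- c(corr[cbind(iL[i], iL[i + d])], corr[cbind(iR[i], iR[i + d])])
      if (d > 0L)  # off-diagonal pairs appear once per ordered pair; keep one
        v <- v
      v[!is.na(v)]
    })
  } else {
    ds <- -(nb - 1L):(nb - 1L)
    entries <- lapply(ds, function(d) {
      # offset d = left-bin index minus right-bin index
      j <- seq_len(nb)
      i <- j + d
      ok <- i >= 1L & i <= nb
      v <- corr[cbind(iL[i[ok]], iR[j[ok]])]
      v[!is.na(v)]
    })
  }
  out <- data.frame(
    distance_cm = ds * bin_cm,
    mean_corr = vapply(entries, function(v) if (length(v)) mean(v) else NA_real_,
                       numeric(1)),
    sem_corr = vapply(entries, function(v)
      if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
      numeric(1)),
    n = lengths(entries))
  attr(out, "entries") <- entries
  attr(out, "quadrant_set") <- quadrant_set
  out
}

#' Per-distance comparison of two PV correlation profiles
#'
#' Two-sided Wilcoxon rank-sum test on the correlation-entry populations
#' of two groups, one test per distance bin; bins empty in either group
#' are skipped.
#'
#' @param profile_a,profile_b [distance_profile()] results on the same
#'   distance grid.
#' @return data.frame with `distance_cm`, `n_a`, `n_b`, `statistic`, `p`.
#' @export
compare_profiles <- function(profile_a, profile_b) {
  stopifnot(identical(profile_a$distance_cm, profile_b$distance_cm))
  ea <- attr(profile_a, "entries")
  eb <- attr(profile_b, "entries")
  rows <- lapply(seq_along(ea), function(k) {
    a <- ea[[k]]; b <- eb[[k]]
    if (length(a) < 1L || length(b) < 1L) return(NULL)
    if (stats::var(c(a, b)) == 0) {
      # degenerate bin (e.g. the all-ones diagonal): no evidence either way
      return(data.frame(distance_cm = profile_a$distance_cm[k],
                        n_a = length(a), n_b = length(b),
                        statistic = NA_real_, p = 1))
    }
    w <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    data.frame(distance_cm = profile_a$distance_cm[k],
               n_a = length(a), n_b = length(b),
               statistic = unname(w$statistic), p = w$p.value)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(distance_cm = numeric(), n_a = integer(),
                      n_b = integer(), statistic = numeric(), p = numeric())
  out
}
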