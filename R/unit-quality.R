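# Post-sorting quality control and pyramidal-cell classification.

#' Construct a spike train for one sorted unit
#'
#' @param unit_id identifier.
#' @param t spike times in seconds, sorted ascending.
#' @param amp per-spike peak amplitude: numeric vector (one channel) or
#'   matrix with one column per recording channel (arbitrary units).
#' @param features per-spike feature matrix (fixed dimension, e.g. 8 =
#'   two features per tetrode channel), used for cluster-quality metrics.
#' @param width_us mean spike width of the unit, microseconds.
#' @return object of class `spike_train`.
#' @export
spike_train <- function(unit_id, t, amp = NULL, features = NULL,
                        width_us = NA_real_) {
  t <- as.numeric(t)
  if (is.unsorted(t)) stop("spike times must be sorted ascending")
  if (!is.null(amp)) {
    amp <- as.matrix(amp)
    if (nrow(amp) != length(t)) stop("amp must have one row per spike")
  }
  if (!is.null(features)) {
    features <- as.matrix(features)
    if (nrow(features) != length(t)) stop("features must have one row per spike")
  }
  structure(list(unit_id = unit_id, t = t, amp = amp, features = features,
                 width_us = width_us),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> unit %s: %d spikes", x$unit_id, length(x$t)))
  if (length(x$t)) cat(sprintf(" over %.1f s", diff(range(x$t))))
  cat("\n")
  invisible(x)
}

#' Fraction of spikes violating a minimum inter-spike interval
#'
#' The number of inter-spike intervals shorter than `min_isi_ms` divided
#' by the number of spikes (not the number of intervals).
#'
#' @param t spike times, seconds, sorted.
#' @param min_isi_ms refractory bound in ms (default 2).
#' @return fraction in \[0, 1\]; `NA` with a warning if fewer than 2 spikes.
#' @export
isi_violation_fraction <- function(t, min_isi_ms = 2) {
  if (length(t) < 2L) {
    warning("ISI violation fraction undefined for < 2 spikes")
    return(NA_real_)
  }
  sum(diff(t) * 1000 < min_isi_ms) / length(t)
}

#' Isolation distance of a sorted cluster
#'
#' Mahalanobis-based cluster-quality measure: with n spikes in the
#' cluster, the squared Mahalanobis distance (with respect to the cluster
#' mean and covariance) of the n-th closest non-cluster ("noise") spike.
#' Large values mean the cluster is well separated from the rest of the
#' events on the tetrode.
#'
#' @param cluster_features n x d feature matrix of the cluster's spikes.
#' @param noise_features m x d feature matrix of all other events.
#' @param ridge_frac ridge regularization added to a (near-)singular
#'   covariance, as a fraction of the mean diagonal (default 1e-6).
#' @return nonnegative scalar; `Inf` with a warning when fewer noise
#'   spikes than cluster spikes exist.
#' @export
isolation_distance <- function(cluster_features, noise_features,
                               ridge_frac = 1e-6) {
  cf <- as.matrix(cluster_features)
  nf <- as.matrix(noise_features)
  n <- nrow(cf)
  stopifnot(ncol(cf) == ncol(nf), n > ncol(cf))
  if (nrow(nf) < n) {
    warning("fewer noise spikes than cluster spikes; isolation distance = Inf")
    return(Inf)
  }
  S <- stats::cov(cf)
  d2 <- tryCatch(stats::mahalanobis(nf, colMeans(cf), S),
                 error = function(e) NULL)
  if (is.null(d2) || !all(is.finite(d2))) {
    warning("singular cluster covariance; applying ridge regularization")
    S <- S + diag(ridge_frac * mean(diag(S)) + 1e-12, ncol(S))
    d2 <- stats::mahalanobis(nf, colMeans(cf), S)
  }
  sort(d2)[n]
}

#' Apply unit inclusion rules and pyramidal-cell classification
#'
#' A unit is excluded when its refractory violation fraction exceeds
#' 0.5%, it fired fewer than 50 spikes, or its isolation distance is
#' below 10. Included units are classified as pyramidal when the mean
#' spike width exceeds 200 microseconds and the complex spike index is at
#' least 5; all other included units are labelled "other".
#'
#' @param qc a list or one-row data.frame with fields
#'   `isi_violation_frac`, `n_spikes`, `isolation_distance`, `csi`,
#'   `width_us`.
#' @param max_isi_violation,min_spikes,min_isolation,min_width_us,min_csi
#'   rule thresholds.
#' @return `qc` with `status` ("included"/"excluded") and `cell_class`
#'   ("pyramidal"/"other"/NA for excluded units) filled in.
#' @export
classify_unit <- function(qc, max_isi_violation = 0.005, min_spikes = 50,
                          min_isolation = 10, min_width_us = 200,
                          min_csi = 5) {
  excl <- isTRUE(qc$isi_violation_frac > max_isi_violation) ||
    isTRUE(qc$n_spikes < min_spikes) ||
    isTRUE(qc$isolation_distance < min_isolation) ||
    is.na(qc$isi_violation_frac)
  qc$status <- if (excl) "excluded" else "included"
  qc$cell_class <- if (excl) NA_character_
    else if (isTRUE(qc$width_us > min_width_us) && isTRUE(qc$csi >= min_csi))
      "pyramidal" else "other"
  qc
}

#' Quality-control table for a set of units
#'
#' Computes per-unit QC metrics and applies [classify_unit()]. The noise
#' set for each unit's isolation distance is the pooled features of all
#' other units (all non-cluster events available after sorting).
#'
#' @param spikes list of [spike_train()] objects with feature matrices.
#' @param csi optional named numeric vector of complex spike indices per
#'   unit (from [complex_spike_index()]); computed from amplitudes when
#'   omitted.
#' @param ... thresholds passed to [classify_unit()].
#' @return data.frame, one row per unit, columns `unit_id`, `n_spikes`,
#'   `isi_violation_frac`, `isolation_distance`, `csi`, `width_us`,
#'   `status`, `cell_class`.
#' @export
unit_qc_table <- function(spikes, csi = NULL, ...) {
  ids <- vapply(spikes, function(s) as.character(s$unit_id), character(1))
  rows <- lapply(seq_along(spikes), function(i) {
    s <- spikes[[i]]
    iso <- NA_real_
    if (!is.null(s$features) && length(spikes) > 1L) {
      noise <- do.call(rbind, lapply(spikes[-i], function(z) z$features))
      if (!is.null(noise) && nrow(s$features) > ncol(s$features))
        iso <- suppressWarnings(isolation_distance(s$features, noise))
    }
    ci <- if (!is.null(csi)) unname(csi[ids[i]])
          else if (!is.null(s$amp) && length(s$t) >= 2L)
            complex_spike_index(s$t, s$amp)$csi else NA_real_
    viol <- suppressWarnings(isi_violation_fraction(s$t))
    classify_unit(data.frame(
      unit_id = ids[i], n_spikes = length(s$t),
      isi_violation_frac = viol, isolation_distance = iso,
      csi = ci, width_us = s$width_us, stringsAsFactors = FALSE), ...)
  })
  do.call(rbind, rows)
}
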