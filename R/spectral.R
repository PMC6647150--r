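## Welch power-spectral-density estimation for the process comparisons
## (shifted vs linearized; norm of the transformed process vs the two
## radial reductions).

#' Welch power spectral density estimate
#'
#' Averaged-overlapping-segment periodogram: the series (or each series in
#' a list of segments) is split into segments of \code{segment} samples
#' with 50\% overlap, each segment is mean-removed, tapered by a Hann
#' window and its one-sided periodogram computed; segment periodograms are
#' averaged.  The frequency axis is in cycles per time unit, and the
#' normalization is such that the integral of the PSD over frequency
#' approximates the series variance (Parseval).
#'
#' @param series numeric vector, or a list of numeric vectors (disjoint
#'   segments of one process, e.g. subthreshold stretches) pooled into one
#'   estimate.
#' @param dt sampling interval.
#' @param segment segment length in samples (default 1024).
#' @param overlap fractional overlap between consecutive segments
#'   (default 0.5).
#' @return An object of class \code{"psd_estimate"}: list with
#'   \code{frequencies}, \code{power}, \code{n_segments}, \code{dt},
#'   \code{segment}, \code{normalization} (\code{NA} until rescaled by
#'   \code{\link{psd_compare}}).
#' @export
psd_estimate <- function(series, dt, segment = 1024L, overlap = 0.5) {
  pieces <- if (is.list(series)) series else list(series)
  pieces <- lapply(pieces, as.numeric)
  if (max(vapply(pieces, length, 1L)) < segment)
    stop("series too short: need at least ", segment, " samples")
  win <- 0.5 * (1 - cos(2 * pi * seq(0, segment - 1) / segment))  # Hann
  wnorm <- sum(win^2)
  step <- max(1L, floor(segment * (1 - overlap)))
  acc <- numeric(segment %/% 2 + 1L)
  n_seg <- 0L
  for (x in pieces) {
    n <- length(x)
    if (n < segment) next
    starts <- seq(1L, n - segment + 1L, by = step)
    for (s0 in starts) {
      seg <- x[s0:(s0 + segment - 1L)]
      seg <- (seg - mean(seg)) * win
      pg <- abs(stats::fft(seg))^2 * dt / wnorm
      half <- pg[seq_len(segment %/% 2 + 1L)]
      ## one-sided: double everything except DC and Nyquist
      half[2:(segment %/% 2)] <- 2 * half[2:(segment %/% 2)]
      acc <- acc + half
      n_seg <- n_seg + 1L
    }
  }
  structure(list(frequencies = seq(0, segment %/% 2) / (segment * dt),
                 power = acc / n_seg, n_segments = n_seg,
                 dt = dt, segment = segment, normalization = NA_real_),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  fpeak <- x$frequencies[which.max(x$power)]
  cat(sprintf(
    "PSD estimate: %d segments of %d samples, peak at %.5g cycles/time\n",
    x$n_segments, x$segment, fpeak))
  invisible(x)
}

#' Normalize PSDs to a common maximum and compute pairwise gaps
#'
#' Rescales every estimate so its maximum equals \code{common_max} (an
#' arbitrary display constant; shapes are what is compared), then computes
#' the matrix of pairwise normalized L2 gaps
#' \code{||p_i - p_j|| / mean(||p_i||, ||p_j||)} over the common frequency
#' grid.  Normalization is idempotent.
#'
#' @param psd_list list of \code{\link{psd_estimate}} objects on identical
#'   frequency grids.
#' @param common_max the common maximum (default 40).
#' @return A list with \code{psds} (rescaled estimates) and \code{gaps}
#'   (symmetric matrix of normalized L2 gaps).
#' @export
psd_compare <- function(psd_list, common_max = 40) {
  stopifnot(length(psd_list) >= 2)
  f0 <- psd_list[[1]]$frequencies
  for (p in psd_list[-1])
    if (!isTRUE(all.equal(p$frequencies, f0)))
      stop("incompatible frequency grids")
  scaled <- lapply(psd_list, function(p) {
    p$power <- p$power / max(p$power) * common_max
    p$normalization <- common_max
    p
  })
  k <- length(scaled)
  gaps <- matrix(0, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    pi <- scaled[[i]]$power; pj <- scaled[[j]]$power
    g <- sqrt(sum((pi - pj)^2)) /
      mean(c(sqrt(sum(pi^2)), sqrt(sum(pj^2))))
    gaps[i, j] <- gaps[j, i] <- g
  }
  list(psds = scaled, gaps = gaps)
}

#' Extract subthreshold stretches of a trajectory
#'
#' Returns the runs of the membrane-potential path that stay below
#' \code{level} (i.e. away from spike excursions) and are at least
#' \code{min_length} samples long, for pooled spectral estimation of the
#' subthreshold fluctuations.
#'
#' @param traj an \code{"fhn_trajectory"}.
#' @param level exclusion level on \code{v} (default -0.5, well below the
#'   firing threshold and above the subthreshold fluctuation band).
#' @param min_length minimum run length in samples (default 1024).
#' @param component which component to extract, \code{"v"} or \code{"w"}.
#' @param center subtract a reference value (e.g. \code{v_e}) from the
#'   extracted runs; default 0.
#' @return A list of numeric vectors, suitable for
#'   \code{\link{psd_estimate}}.
#' @export
subthreshold_segments <- function(traj, level = -0.5, min_length = 1024L,
                                  component = c("v", "w"), center = 0) {
  component <- match.arg(component)
  below <- traj$v < level
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_length
  x <- traj[[component]]
  lapply(which(keep), function(i) x[starts[i]:ends[i]] - center)
}
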