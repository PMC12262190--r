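#' Split an Rg series into two analysis intervals
#'
#' Intervals are (lo, hi) pairs in nanoseconds when the series carries
#' time metadata, otherwise fractions of the frame range in [0, 1].
#' Half-open semantics: a frame belongs to an interval when
#' lo <= t < hi. Intervals must not overlap and must lie inside the
#' series span.
#'
#' @param series An \code{rg_series}.
#' @param interval_a,interval_b Length-2 numeric vectors.
#' @return List of two \code{rg_series}.
#' @export
split_intervals <- function(series, interval_a, interval_b) {
  stopifnot(inherits(series, "rg_series"))
  iv <- function(x) {
    if (length(x) != 2L || x[2L] <= x[1L]) stop("intervals must be (lo, hi) with lo < hi")
    as.numeric(x)
  }
  a <- iv(interval_a); b <- iv(interval_b)
  if (max(a[1L], b[1L]) < min(a[2L], b[2L]))
    stop("intervals overlap")
  n <- length(series$rg)
  if (is.null(series$time_ns)) {
    if (min(a, b) < 0 || max(a, b) > 1)
      stop("index-fraction intervals must lie inside [0, 1]")
    pos <- (seq_len(n) - 1L) / n
  } else {
    span <- range(series$time_ns)
    # allow the trailing edge to close at the nominal end of the sampling
    # window (one frame spacing past the last recorded time)
    step <- if (length(series$time_ns) > 1L) stats::median(diff(series$time_ns))
            else 0
    if (min(a, b) < span[1L] || max(a, b) > span[2L] + step + 1e-9)
      stop("interval lies outside the series time span")
    pos <- series$time_ns
  }
  take <- function(x) {
    sel <- pos >= x[1L] & pos < x[2L]
    if (!any(sel)) stop("interval (", x[1L], ", ", x[2L], ") selects no frames")
    structure(list(rg = series$rg[sel],
                   time_ns = if (is.null(series$time_ns)) NULL
                             else series$time_ns[sel]),
              class = "rg_series")
  }
  list(take(a), take(b))
}

#' Histogram-intersection overlap of two Rg samples
#'
#' Both samples are binned on one common grid of \code{n_bins} equal bins
#' spanning the union of their ranges; each histogram is normalised to
#' sum 1 and the overlap is the total shared probability mass,
#' sum over bins of min(p, q). 1 means the normalised histograms are
#' identical on the common binning, 0 means disjoint support. Two
#' identical constant series (zero-width range) overlap fully by
#' convention.
#'
#' @param series_a,series_b \code{rg_series} objects or bare numeric
#'   vectors.
#' @param n_bins Number of bins (default 50, the standard convergence
#'   protocol).
#' @return Overlap fraction in [0, 1].
#' @examples
#' overlap_coefficient(rnorm(1000, 10), rnorm(1000, 10))
#' @export
overlap_coefficient <- function(series_a, series_b, n_bins = 50L) {
  a <- if (inherits(series_a, "rg_series")) series_a$rg else as.numeric(series_a)
  b <- if (inherits(series_b, "rg_series")) series_b$rg else as.numeric(series_b)
  if (!length(a) || !length(b)) stop("both series must be non-empty")
  if (n_bins < 2L) stop("n_bins must be >= 2")
  r <- range(c(a, b))
  if (r[2L] - r[1L] < 1e-12) return(1)   # degenerate: identical constants
  breaks <- seq(r[1L], r[2L], length.out = n_bins + 1L)
  binit <- function(x) {
    ix <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L),
               n_bins)
    tabulate(ix, nbins = n_bins) / length(x)
  }
  sum(pmin(binit(a), binit(b)))
}

#' Radius-of-gyration convergence report
#'
#' The sampling-convergence diagnostic: compute Rg for every frame, split
#' the series into two independent intervals, histogram each on a common
#' 50-bin grid and score the histogram intersection. Sampling is called
#' convergent when the overlap reaches the threshold (default 0.90). A
#' degenerate pair occupying fewer than 2 bins is never reported as a
#' pass.
#'
#' @param traj A \code{backbone_trajectory} or an \code{rg_series}.
#' @param intervals List of two (lo, hi) intervals for
#'   \code{\link{split_intervals}}; \code{NULL} (default) splits the
#'   series into its first and second halves (by time when time metadata
#'   is present, else by frame index).
#' @param threshold Overlap required to pass (default 0.90).
#' @param n_bins Histogram bins (default 50).
#' @return Object of class \code{overlap_report}: \code{overlap},
#'   \code{pass}, \code{threshold}, \code{n_bins}, \code{intervals},
#'   \code{n_frames} (per interval), \code{n_occupied},
#'   \code{degenerate}.
#' @export
convergence_report <- function(traj, intervals = NULL,
                               threshold = 0.90, n_bins = 50L) {
  series <- if (inherits(traj, "backbone_trajectory")) rg_series(traj)
            else traj
  stopifnot(inherits(series, "rg_series"))
  if (is.null(intervals)) {
    intervals <- if (is.null(series$time_ns)) list(c(0, 0.5), c(0.5, 1))
    else {
      sp <- range(series$time_ns)
      mid <- (sp[1L] + sp[2L]) / 2
      list(c(sp[1L], mid), c(mid, sp[2L] + 1e-9))
    }
  }
  halves <- split_intervals(series, intervals[[1L]], intervals[[2L]])
  ov <- overlap_coefficient(halves[[1L]], halves[[2L]], n_bins = n_bins)
  r <- range(c(halves[[1L]]$rg, halves[[2L]]$rg))
  n_occ <- if (r[2L] - r[1L] < 1e-12) 1L else {
    breaks <- seq(r[1L], r[2L], length.out = n_bins + 1L)
    ix <- findInterval(c(halves[[1L]]$rg, halves[[2L]]$rg), breaks,
                       rightmost.closed = TRUE)
    length(unique(pmin(pmax(ix, 1L), n_bins)))
  }
  degenerate <- n_occ < 2L
  structure(list(overlap = ov,
                 pass = !degenerate && ov >= threshold,
                 threshold = threshold, n_bins = as.integer(n_bins),
                 intervals = intervals,
                 n_frames = c(length(halves[[1L]]$rg), length(halves[[2L]]$rg)),
                 n_occupied = n_occ, degenerate = degenerate,
                 halves = halves),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap_report: %.1f%% overlap (%d bins, %d + %d frames)\n",
              100 * x$overlap, x$n_bins, x$n_frames[1L], x$n_frames[2L]))
  cat(sprintf("  threshold %.0f%%: %s%s\n", 100 * x$threshold,
              if (x$pass) "PASS (convergent sampling)" else "FAIL",
              if (x$degenerate) " [degenerate: <2 occupied bins]" else ""))
  invisible(x)
}

#' Plot the two interval histograms behind an overlap report
#'
#' @param x An \code{overlap_report}.
#' @param ... Passed to \code{\link[graphics]{hist}}.
#' @export
plot.overlap_report <- function(x, ...) {
  a <- x$halves[[1L]]$rg; b <- x$halves[[2L]]$rg
  breaks <- seq(min(a, b), max(a, b), length.out = x$n_bins + 1L)
  ha <- graphics::hist(a, breaks = breaks, plot = FALSE)
  hb <- graphics::hist(b, breaks = breaks, plot = FALSE)
  ylim <- c(0, max(ha$density, hb$density))
  graphics::plot(ha, freq = FALSE, col = grDevices::adjustcolor("steelblue", 0.5),
                 border = NA, ylim = ylim, xlab = "Rg (Angstrom)",
                 main = sprintf("Rg interval overlap: %.1f%%", 100 * x$overlap),
                 ...)
  graphics::plot(hb, freq = FALSE, col = grDevices::adjustcolor("tomato", 0.5),
                 border = NA, add = TRUE)
  invisible(x)
}
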