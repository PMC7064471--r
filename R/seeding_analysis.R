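# Aggregation of simulation output into the reported quantities:
# seeding efficiency, lateral attachment bins, replicate comparison.

#' Cell seeding efficiency
#'
#' `Phi = 100 * N_a / N_i`: the percentage of injected cells that ended
#' attached (live) to the scaffold.
#'
#' @param n_attached Attached (live) cell count.
#' @param n_injected Injected cell count, > 0.
#' @return Efficiency in percent.
#' @export
seeding_efficiency <- function(n_attached, n_injected) {
  if (any(n_injected <= 0)) stop("n_injected must be > 0")
  if (any(n_attached < 0)) stop("n_attached must be >= 0")
  100 * n_attached / n_injected
}

#' Lateral attachment bins from the injection side
#'
#' Attached particles are histogrammed by distance from the injection-side
#' face of the scaffold in half-open bins `[a, b)`; the default is six
#' 1.3-mm bins spanning the 7.8 mm next to the inlet.  Live (stick +
#' spread) and dead (dead-attached) particles are counted separately.
#' Particles outside all bins are reported in the `overflow` attribute.
#'
#' @param particles Data frame with columns `x` (m, well frame) and
#'   `status` (as from a `seeding_result`).
#' @param bin_edges Strictly increasing bin edges, mm (default
#'   `seq(0, 7.8, by = 1.3)`).
#' @param origin Position of the injection-side scaffold face, m
#'   (default 0: `x` already measured from the face).
#' @return Data frame `bin_lo_mm, bin_hi_mm, live, dead` with attribute
#'   `overflow`.
#' @export
lateral_bin_counts <- function(particles, bin_edges = seq(0, 7.8, by = 1.3),
                               origin = 0) {
  if (any(diff(bin_edges) <= 0)) stop("bin edges must be strictly increasing")
  att <- particles[particles$status %in%
                     c("attached", "attached_spread", "dead_attached"), ,
                   drop = FALSE]
  d_mm <- (att$x - origin) * 1000
  nb <- length(bin_edges) - 1
  idx <- findInterval(d_mm, bin_edges, left.open = FALSE,
                      rightmost.closed = FALSE)
  live <- att$status %in% c("attached", "attached_spread")
  inb <- idx >= 1 & idx <= nb & d_mm < bin_edges[nb + 1]
  out <- data.frame(bin_lo_mm = bin_edges[-(nb + 1)],
                    bin_hi_mm = bin_edges[-1],
                    live = tabulate(idx[inb & live], nbins = nb),
                    dead = tabulate(idx[inb & !live], nbins = nb))
  attr(out, "overflow") <- sum(!inb)
  out
}

#' Compare replicate bin counts between two groups
#'
#' Two-sample Welch t test on per-replicate counts, used to compare
#' simulated replicates (different seeds) between designs or bins.
#'
#' @param replicate_counts_a,replicate_counts_b Numeric vectors (>= 2
#'   replicates each).
#' @return List with `statistic`, `p_value`, `estimate` (group means).
#' @export
compare_bins <- function(replicate_counts_a, replicate_counts_b) {
  a <- as.numeric(replicate_counts_a); b <- as.numeric(replicate_counts_b)
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 replicates per group")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      return(list(statistic = 0, p_value = 1, estimate = c(mean(a), mean(b))))
    }
    stop("degenerate input: zero variance in both groups")
  }
  tt <- t.test(a, b)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       estimate = unname(tt$estimate))
}

#' Seeding efficiency curve and plateau summary
#'
#' `Phi(t)` from the recorded series plus plateau detection: the onset is
#' the first time the efficiency slope falls below `dphi_threshold`
#' (%/s) over a trailing window after attachment has started; the steady
#' value is the final efficiency.
#'
#' @param result A `seeding_result`.
#' @param dphi_threshold Slope threshold, percent per second (default 1).
#' @param window Trailing window for the slope estimate, s (default 0.2).
#' @return Data frame `t, efficiency` with attributes `plateau_onset` (s,
#'   NA if never reached) and `steady_value` (%).
#' @export
efficiency_curve <- function(result, dphi_threshold = 1, window = 0.2) {
  s <- result$series
  out <- data.frame(t = s$t, efficiency = s$efficiency)
  onset <- NA_real_
  if (nrow(out) >= 2) {
    for (i in seq(2, nrow(out))) {
      j <- which(out$t >= out$t[i] - window)[1]
      if (j >= i || out$efficiency[i] <= 0) next
      slope <- (out$efficiency[i] - out$efficiency[j]) /
        (out$t[i] - out$t[j])
      if (slope < dphi_threshold) { onset <- out$t[i]; break }
    }
  }
  attr(out, "plateau_onset") <- onset
  attr(out, "steady_value") <- out$efficiency[nrow(out)]
  out
}
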