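ion_indices <- function(trajectory, species = NULL) {
  if (is.null(trajectory$ion_coords)) return(integer(0))
  n <- dim(trajectory$ion_coords)[1]
  if (is.null(species) || is.null(trajectory$ions)) return(seq_len(n))
  which(trajectory$ions$species %in% species)
}

#' Radial distribution function between charged sites and cations
#'
#' Histogram of minimum-image reference-target distances, normalized per
#' bin by the ideal-gas expectation (target number density times shell
#' volume) per reference per frame, so that an unstructured ion field gives
#' `g(r) = 1` beyond excluded volume. Defaults follow common practice for
#' polyanion-counterion analysis: a 3 nm range over 200 bins with the
#' polymer's negatively charged sites as references.
#'
#' @param trajectory a [poly_trajectory()] with an ion block.
#' @param topology matching [poly_topology()].
#' @param species ion species to include (default all).
#' @param r_max analysis range, nm. If it exceeds half the shortest box
#'   edge it is truncated with a warning (the minimum image is ambiguous
#'   beyond that).
#' @param n_bins number of equal-width bins over `[0, r_max]`.
#' @return List of class `rdf_profile`: `bin_centers`, `g` (both length
#'   `n_bins`), `r_max`, `n_bins`, `reference_count`, `target_count`,
#'   `empty` flag.
#' @export
compute_rdf <- function(trajectory, topology, species = NULL,
                        r_max = 3.0, n_bins = 200L) {
  cs <- charged_sites(topology)
  if (length(cs) == 0L) stop("topology has no charged sites")
  half_box <- min(trajectory$box) / 2
  requested_bw <- r_max / n_bins
  if (r_max > half_box) {
    warning("r_max exceeds half the shortest box edge; truncating to ",
            signif(half_box, 4), " nm")
    n_bins <- max(1L, floor(half_box / requested_bw))
    r_max <- n_bins * requested_bw
  }
  tgt <- ion_indices(trajectory, species)
  edges <- seq(0, r_max, length.out = n_bins + 1L)
  centers <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  if (length(tgt) == 0L) {
    return(structure(
      list(bin_centers = centers, g = rep(0, n_bins), r_max = r_max,
           n_bins = n_bins, reference_count = length(cs), target_count = 0L,
           empty = TRUE),
      class = "rdf_profile"))
  }
  counts <- numeric(n_bins)
  for (i in seq_len(trajectory$n_frames)) {
    ref_xyz <- matrix(trajectory$polymer[cs, , i], ncol = 3)
    tgt_xyz <- matrix(trajectory$ion_coords[tgt, , i], ncol = 3)
    d <- min_image_dist(ref_xyz, tgt_xyz, trajectory$box)
    d <- d[d < r_max]
    if (length(d) > 0) {
      h <- tabulate(pmin(n_bins, floor(d / requested_bw) + 1L), n_bins)
      counts <- counts + h
    }
  }
  vol_box <- prod(trajectory$box)
  rho <- length(tgt) / vol_box
  shell_vol <- 4 / 3 * pi * diff(edges^3)
  expected <- length(cs) * trajectory$n_frames * rho * shell_vol
  structure(
    list(bin_centers = centers, g = counts / expected, r_max = r_max,
         n_bins = n_bins, reference_count = length(cs),
         target_count = length(tgt), empty = FALSE),
    class = "rdf_profile"
  )
}

# site x ion minimum-image distance matrix for one frame
site_ion_dist <- function(trajectory, topology, i, tgt) {
  cs <- charged_sites(topology)
  min_image_dist(matrix(trajectory$polymer[cs, , i], ncol = 3),
                 matrix(trajectory$ion_coords[tgt, , i], ncol = 3),
                 trajectory$box)
}

#' Per-frame bound-cation counts
#'
#' A cation counts as bound in a frame when at least one polymer charged
#' site lies within `cutoff` (minimum image) of it.
#'
#' @param trajectory a [poly_trajectory()] with an ion block.
#' @param topology matching [poly_topology()].
#' @param cutoff binding cutoff, nm (default 0.5).
#' @param species ion species to include (default all).
#' @return Integer vector of per-frame bound counts.
#' @export
count_bound <- function(trajectory, topology, cutoff = 0.5, species = NULL) {
  cs <- charged_sites(topology)
  if (length(cs) == 0L) stop("topology has no charged sites")
  tgt <- ion_indices(trajectory, species)
  if (length(tgt) == 0L) return(rep(0L, trajectory$n_frames))
  vapply(seq_len(trajectory$n_frames), function(i) {
    d <- site_ion_dist(trajectory, topology, i, tgt)
    sum(apply(d <= cutoff, 2, any))
  }, integer(1))
}

#' Per-frame charge-neutralization fraction
#'
#' Fraction of the polymer's negatively charged sites that have at least
#' one cation within `cutoff` (minimum image).
#'
#' @inheritParams count_bound
#' @return Numeric vector in `[0, 1]`, one value per frame.
#' @export
neutralized_fraction <- function(trajectory, topology, cutoff = 0.5,
                                 species = NULL) {
  cs <- charged_sites(topology)
  if (length(cs) == 0L) stop("topology has no charged sites")
  tgt <- ion_indices(trajectory, species)
  if (length(tgt) == 0L) return(rep(0, trajectory$n_frames))
  vapply(seq_len(trajectory$n_frames), function(i) {
    d <- site_ion_dist(trajectory, topology, i, tgt)
    mean(apply(d <= cutoff, 1, any))
  }, numeric(1))
}

#' Per-frame cation-bridging fraction
#'
#' A charged site is bridged when it shares a within-cutoff cation with at
#' least one other charged site, i.e. some cation is simultaneously within
#' `cutoff` of this site and of a different site. The fraction is the
#' number of bridged sites divided by the number of neutralized sites in
#' the same frame; frames with no neutralized site yield `NA` (0/0 is
#' recorded as missing, not as zero).
#'
#' @inheritParams count_bound
#' @return Numeric vector in `[0, 1]` (or `NA`), one value per frame.
#' @export
bridging_fraction <- function(trajectory, topology, cutoff = 0.5,
                              species = NULL) {
  cs <- charged_sites(topology)
  if (length(cs) == 0L) stop("topology has no charged sites")
  tgt <- ion_indices(trajectory, species)
  vapply(seq_len(trajectory$n_frames), function(i) {
    if (length(tgt) == 0L) return(NA_real_)
    adj <- site_ion_dist(trajectory, topology, i, tgt) <= cutoff
    neut <- apply(adj, 1, any)
    if (!any(neut)) return(NA_real_)
    ion_degree <- colSums(adj)
    bridged <- apply(adj[, ion_degree >= 2, drop = FALSE], 1, any) & neut
    sum(bridged) / sum(neut)
  }, numeric(1))
}

#' Summary of ion-interaction statistics
#'
#' @inheritParams count_bound
#' @return List of class `ion_stats`: per-frame vectors `bound`,
#'   `neutralized`, `bridged` plus their time means and standard
#'   deviations, and the cutoff used.
#' @export
ion_interaction_series <- function(trajectory, topology, cutoff = 0.5,
                                   species = NULL) {
  bound <- count_bound(trajectory, topology, cutoff, species)
  neut <- neutralized_fraction(trajectory, topology, cutoff, species)
  brid <- bridging_fraction(trajectory, topology, cutoff, species)
  structure(
    list(bound = bound, neutralized = neut, bridged = brid,
         mean_bound = mean(bound), sd_bound = stats::sd(bound),
         mean_neutralized = mean(neut), sd_neutralized = stats::sd(neut),
         mean_bridged = mean(brid, na.rm = TRUE),
         sd_bridged = stats::sd(brid[!is.na(brid)]),
         binding_cutoff = cutoff),
    class = "ion_stats"
  )
}

# maximal runs of TRUE in a logical vector -> data frame start/length
runs_of <- function(x, gap_tolerance = 0L) {
  if (gap_tolerance > 0L && any(x)) {
    # bridge FALSE gaps of length <= gap_tolerance between TRUE runs
    r <- rle(x)
    idx <- which(!r$values & r$lengths <= gap_tolerance)
    inner <- idx[idx > 1 & idx < length(r$values)]
    r$values[inner] <- TRUE
    x <- inverse.rle(r)
  }
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], length = r$lengths[keep],
             end = ends[keep])
}

#' Cation residence time from survival probability
#'
#' Binding events are maximal runs of consecutive frames in which an ion
#' sits within `proximity_cutoff` (minimum image) of any polymer charged
#' site; by default the definition is continuous (a single excursion frame
#' ends the event; `gap_tolerance` frames of excursion may be forgiven for
#' the intermittent variant). Events still in progress at the final frame
#' are right-censored: they are not counted as completed events, but they
#' remain in the survival risk set up to their observed duration
#' (Kaplan-Meier product-limit estimator). Simply discarding them biases
#' the fitted residence time downward by roughly `tau / T_traj`, which is
#' material whenever the trajectory is shorter than ~50 residence times.
#' The survival curve `S(t)` (non-increasing, `S(0) = 1`) is fitted as
#' `log S(t) = -t / tau` by weighted least squares through the origin
#' (weights = number of events at risk at each lag), over lags with
#' `S > 0.01`.
#'
#' @param trajectory a [poly_trajectory()] with an ion block.
#' @param topology matching [poly_topology()].
#' @param proximity_cutoff nm (default 0.75).
#' @param species ion species to include (default all).
#' @param gap_tolerance frames of excursion tolerated inside one event
#'   (default 0, the strict continuous definition).
#' @return List of class `residence_fit`: `tau` (ns), `survival_lags`
#'   (ns), `survival` (non-increasing, starts at 1), `n_events`,
#'   `censored_count`, `fit_rms` (RMS residual of the log-linear fit) and
#'   `durations_ns` of the completed events.
#' @export
residence_time <- function(trajectory, topology, proximity_cutoff = 0.75,
                           species = NULL, gap_tolerance = 0L) {
  cs <- charged_sites(topology)
  if (length(cs) == 0L) stop("topology has no charged sites")
  tgt <- ion_indices(trajectory, species)
  n_frames <- trajectory$n_frames
  # per-frame proximity matrix, ions x frames
  near <- matrix(FALSE, length(tgt), n_frames)
  for (i in seq_len(n_frames)) {
    d <- site_ion_dist(trajectory, topology, i, tgt)
    near[, i] <- apply(d <= proximity_cutoff, 2, any)
  }
  durations <- integer(0); cens_durations <- integer(0)
  for (j in seq_along(tgt)) {
    ev <- runs_of(near[j, ], gap_tolerance)
    if (nrow(ev) == 0L) next
    running <- ev$end == n_frames
    cens_durations <- c(cens_durations, ev$length[running])
    durations <- c(durations, ev$length[!running])
  }
  censored <- length(cens_durations)
  if (length(durations) == 0L) {
    stop("no completed binding events: trajectory too short or cutoff too ",
         "tight for a residence-time estimate")
  }
  if (length(durations) < 10L) {
    warning("only ", length(durations),
            " completed binding events; residence-time fit is unreliable")
  }
  dt_ns <- trajectory$frame_time / 1000
  max_k <- max(durations)
  lags <- (0:max_k) * dt_ns
  # Kaplan-Meier product limit over the frame-lag grid: censored events
  # stay at risk up to their observed duration
  at_risk <- vapply(0:max_k, function(k) {
    sum(durations >= k) + sum(cens_durations >= k)
  }, numeric(1))
  survival <- numeric(max_k + 1L)
  survival[1] <- 1
  s_run <- 1
  for (k in seq_len(max_k)) {
    deaths <- sum(durations == k)
    if (at_risk[k + 1L] > 0) s_run <- s_run * (1 - deaths / at_risk[k + 1L])
    survival[k + 1L] <- s_run
  }
  use <- survival > 0.01
  t_u <- lags[use]; s_u <- survival[use]; w <- at_risk[use]
  # log S = -t/tau through the origin, weighted least squares
  beta <- sum(w * t_u * (-log(s_u))) / sum(w * t_u^2)
  tau <- 1 / beta
  fit_rms <- sqrt(mean((log(s_u) + beta * t_u)^2))
  structure(
    list(tau = tau, survival_lags = lags, survival = survival,
         n_events = length(durations), censored_count = censored,
         fit_rms = fit_rms, proximity_cutoff = proximity_cutoff,
         durations_ns = durations * dt_ns),
    class = "residence_fit"
  )
}

#' @export
print.residence_fit <- function(x, ...) {
  cat(sprintf(
    "residence_fit: tau = %.3f ns from %d events (%d censored)\n",
    x$tau, x$n_events, x$censored_count))
  invisible(x)
}

#' Hydration numbers of bound cations by coordination shell
#'
#' Each ion is assigned, frame by frame, to the distance window containing
#' its minimum-image distance to the nearest polymer charged site; the
#' windows default to midpoint boundaries between the canonical
#' counterion-shell positions near 0.25, 0.5 and 0.7 nm. For every
#' assigned ion the water-proxy sites within `water_cutoff` are counted,
#' and per-window means and standard deviations are returned. Ions whose
#' nearest-site distance falls outside all windows are excluded and
#' counted as unassigned.
#'
#' @param trajectory a [poly_trajectory()] with ion and water blocks.
#' @param topology matching [poly_topology()].
#' @param peak_windows list of `c(lo, hi)` half-open windows, nm.
#' @param water_cutoff first-shell water cutoff, nm (default 0.38).
#' @param species ion species to include (default all).
#' @return List of class `hydration_result`: data frame `per_peak`
#'   (`window_lo`, `window_hi`, `n`, `mean`, `sd`), `unassigned` count and
#'   the cutoff used.
#' @export
hydration_numbers <- function(trajectory, topology,
                              peak_windows = list(c(0.15, 0.375),
                                                  c(0.375, 0.60),
                                                  c(0.60, 0.80)),
                              water_cutoff = 0.38, species = NULL) {
  if (is.null(trajectory$water_coords)) {
    stop("trajectory has no water-proxy block")
  }
  cs <- charged_sites(topology)
  if (length(cs) == 0L) stop("topology has no charged sites")
  tgt <- ion_indices(trajectory, species)
  lo <- vapply(peak_windows, `[`, numeric(1), 1)
  hi <- vapply(peak_windows, `[`, numeric(1), 2)
  if (is.unsorted(lo) || any(hi[-length(hi)] > lo[-1] + 1e-12)) {
    stop("peak windows must be disjoint and ordered")
  }
  counts <- vector("list", length(peak_windows))
  unassigned <- 0L
  for (i in seq_len(trajectory$n_frames)) {
    d_site <- site_ion_dist(trajectory, topology, i, tgt)
    nearest <- apply(d_site, 2, min)
    wat <- matrix(trajectory$water_coords[, , i], ncol = 3)
    ion_xyz <- matrix(trajectory$ion_coords[tgt, , i], ncol = 3)
    d_w <- min_image_dist(ion_xyz, wat, trajectory$box)
    n_w <- rowSums(d_w <= water_cutoff)
    for (j in seq_along(tgt)) {
      k <- which(nearest[j] >= lo & nearest[j] < hi)
      if (length(k) == 1L) {
        counts[[k]] <- c(counts[[k]], n_w[j])
      } else {
        unassigned <- unassigned + 1L
      }
    }
  }
  per_peak <- data.frame(
    window_lo = lo, window_hi = hi,
    n = vapply(counts, length, integer(1)),
    mean = vapply(counts, function(v) if (length(v)) mean(v) else NA_real_,
                  numeric(1)),
    sd = vapply(counts, function(v) if (length(v) > 1) stats::sd(v) else
      NA_real_, numeric(1))
  )
  structure(
    list(per_peak = per_peak, unassigned = unassigned,
         water_cutoff = water_cutoff),
    class = "hydration_result"
  )
}
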