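#' Specification for a synthetic bead-chain system
#'
#' Defines a bead-chain polyanion plus an ion field with planted, fully
#' known structure, used as ground truth for every estimator in the
#' package. Three chain regimes are available: `rod` (every frame the same
#' straight, uniformly spaced chain), `fjc` (each frame an independent
#' freely-jointed chain with uniform random unit bond vectors) and
#' `globule` (each frame `n_monomers` successive positions drawn uniformly
#' inside a ball, a collapsed-regime stand-in with a closed-form size
#' ratio of about 2).
#'
#' @param model `"rod"`, `"fjc"` or `"globule"`.
#' @param n_monomers monomers per chain (default 30, the chain length all
#'   systems in the study share).
#' @param bond_length backbone bond length, nm.
#' @param charges_per_monomer planted charged sites per monomer (0 gives an
#'   uncharged chain).
#' @param charge_radial_offset perpendicular distance of charged sites from
#'   the local backbone direction, nm.
#' @param globule_radius ball radius for the globule model, nm.
#' @param n_frames frames to generate.
#' @param frame_time ps between frames.
#' @param box orthorhombic box edge (scalar or length 3), nm.
#' @param ion_model `"uniform"` (ions i.i.d. uniform in the box every frame)
#'   or `"planted_bound"` (each ion alternates bound/unbound episodes with
#'   exponentially distributed durations; while bound it sits uniformly in
#'   `binding_shell` of one charged site, while unbound it sits uniformly in
#'   the box at more than 1 nm from every charged site).
#' @param n_monovalent,n_divalent ion counts per species. Divalents default
#'   to half the monovalent count (equal total positive charge).
#' @param dwell_tau_bound,dwell_tau_unbound mean bound/unbound episode
#'   durations, ns.
#' @param binding_shell `c(r_min, r_max)` of the planted binding shell, nm;
#'   must sit inside (0, 0.5].
#' @param waters_per_ion water-proxy sites planted within 0.38 nm of each
#'   ion (0 disables the water block).
#' @param n_decoy_waters additional waters placed beyond 0.5 nm of all ions.
#' @param seed integer RNG seed recorded in all outputs.
#' @return Validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(model = c("fjc", "rod", "globule"),
                           n_monomers = 30L,
                           bond_length = 0.5,
                           charges_per_monomer = 1L,
                           charge_radial_offset = 0.25,
                           globule_radius = 1.0,
                           n_frames = 100L,
                           frame_time = 10,
                           box = 30,
                           ion_model = c("uniform", "planted_bound"),
                           n_monovalent = 0L,
                           n_divalent = NULL,
                           dwell_tau_bound = 2.0,
                           dwell_tau_unbound = 2.0,
                           binding_shell = c(0.2, 0.45),
                           waters_per_ion = 0L,
                           n_decoy_waters = 0L,
                           seed = 1L) {
  model <- match.arg(model)
  ion_model <- match.arg(ion_model)
  if (is.null(n_divalent)) n_divalent <- n_monovalent %/% 2L
  if (length(box) == 1) box <- rep(box, 3)
  spec <- list(
    model = model, n_monomers = as.integer(n_monomers),
    bond_length = bond_length,
    charges_per_monomer = as.integer(charges_per_monomer),
    charge_radial_offset = charge_radial_offset,
    globule_radius = globule_radius,
    n_frames = as.integer(n_frames), frame_time = frame_time,
    box = as.numeric(box), ion_model = ion_model,
    n_monovalent = as.integer(n_monovalent),
    n_divalent = as.integer(n_divalent),
    dwell_tau_bound = dwell_tau_bound,
    dwell_tau_unbound = dwell_tau_unbound,
    binding_shell = binding_shell,
    waters_per_ion = as.integer(waters_per_ion),
    n_decoy_waters = as.integer(n_decoy_waters),
    seed = as.integer(seed)
  )
  if (spec$n_monomers < 2L) stop("n_monomers must be >= 2")
  if (spec$bond_length <= 0) stop("bond_length must be > 0")
  if (spec$charges_per_monomer < 0L) stop("charges_per_monomer must be >= 0")
  if (any(spec$box <= 0)) stop("box edges must be > 0")
  if (spec$frame_time <= 0) stop("frame_time must be > 0")
  if (spec$model == "rod" &&
      min(spec$box) <= 2 * spec$bond_length * spec$n_monomers) {
    stop("rod model requires box > 2 x contour length")
  }
  if (spec$model == "globule" && spec$globule_radius < spec$bond_length / 2) {
    stop("infeasible spec: globule radius smaller than half a bond length")
  }
  bs <- spec$binding_shell
  if (length(bs) != 2 || bs[1] <= 0 || bs[2] > 0.5 || bs[1] >= bs[2]) {
    stop("binding_shell must be [r_min, r_max] inside (0, 0.5] nm")
  }
  if (spec$dwell_tau_bound <= 0 || spec$dwell_tau_unbound <= 0) {
    stop("dwell times must be > 0 ns")
  }
  class(spec) <- "synthetic_spec"
  spec
}

# uniform random unit vectors, n x 3
runif_sphere <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

# n points uniform in a spherical shell [r_min, r_max) around the origin
runif_shell <- function(n, r_min, r_max) {
  u <- stats::runif(n)
  r <- (r_min^3 + u * (r_max^3 - r_min^3))^(1 / 3)
  runif_sphere(n) * r
}

# unit perpendicular to each row of a matrix of tangent vectors
perp_direction <- function(tangent) {
  ez <- c(0, 0, 1); ex <- c(1, 0, 0)
  t(apply(tangent, 1, function(tv) {
    tv <- tv / sqrt(sum(tv^2))
    ref <- if (abs(tv[3]) > 0.99) ex else ez
    p <- c(tv[2] * ref[3] - tv[3] * ref[2],
           tv[3] * ref[1] - tv[1] * ref[3],
           tv[1] * ref[2] - tv[2] * ref[1])
    p / sqrt(sum(p^2))
  }))
}

# backbone positions -> full atom coordinate matrix with charged sites
place_sites <- function(backbone, spec) {
  n <- nrow(backbone)
  if (spec$charges_per_monomer == 0L) return(backbone)
  # local backbone direction: forward/backward differences at the ends,
  # central differences inside
  tangent <- matrix(NA_real_, n, 3)
  tangent[1, ] <- backbone[2, ] - backbone[1, ]
  tangent[n, ] <- backbone[n, ] - backbone[n - 1, ]
  if (n > 2) tangent[2:(n - 1), ] <- backbone[3:n, ] - backbone[1:(n - 2), ]
  perp <- perp_direction(tangent)
  atoms_per_mono <- 1L + spec$charges_per_monomer
  coords <- matrix(NA_real_, n * atoms_per_mono, 3)
  for (m in seq_len(n)) {
    base <- (m - 1L) * atoms_per_mono
    coords[base + 1L, ] <- backbone[m, ]
    for (c_i in seq_len(spec$charges_per_monomer)) {
      # successive charges fan out along +/- perp to stay distinguishable
      sgn <- if (c_i %% 2L == 1L) 1 else -1
      coords[base + 1L + c_i, ] <- backbone[m, ] +
        sgn * spec$charge_radial_offset * perp[m, ]
    }
  }
  coords
}

synthetic_topology <- function(spec) {
  n <- spec$n_monomers
  atoms_per_mono <- 1L + spec$charges_per_monomer
  atoms <- data.frame(
    atom_id = seq_len(n * atoms_per_mono),
    atom_label = rep(c("BB", rep("SC", spec$charges_per_monomer)), n),
    chain_id = "A",
    monomer_index = rep(0:(n - 1L), each = atoms_per_mono),
    role = rep(c("backbone_anchor",
                 rep("charged_site", spec$charges_per_monomer)), n),
    formal_charge = rep(c(0, rep(-1, spec$charges_per_monomer)), n),
    stringsAsFactors = FALSE
  )
  top <- poly_topology(atoms, dx = spec$bond_length,
                       metadata = list(model = spec$model, seed = spec$seed))
  # extended reference conformation: straight rod along x, centred in box
  bb <- cbind((0:(n - 1)) * spec$bond_length, 0, 0)
  bb <- sweep(bb, 2, spec$box / 2 - c(sum(range(bb[, 1])) / 2, 0, 0), "+")
  attr(top, "reference") <- place_sites(bb, spec)
  top
}

#' Generate a synthetic chain trajectory with its topology
#'
#' @param spec a [synthetic_spec()].
#' @return List with elements `topology` ([poly_topology()], carrying the
#'   extended reference conformation as attribute `reference`) and
#'   `trajectory` ([poly_trajectory()], polymer block only).
#' @export
generate_chain <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  top <- synthetic_topology(spec)
  n <- spec$n_monomers
  atoms_per_mono <- 1L + spec$charges_per_monomer
  centre <- spec$box / 2
  arr <- array(NA_real_, c(n * atoms_per_mono, 3, spec$n_frames))
  if (spec$model == "rod") {
    ref <- attr(top, "reference")
    for (i in seq_len(spec$n_frames)) arr[, , i] <- ref
  } else if (spec$model == "fjc") {
    for (i in seq_len(spec$n_frames)) {
      bonds <- runif_sphere(n - 1L) * spec$bond_length
      bb <- rbind(c(0, 0, 0), apply(bonds, 2, cumsum))
      if (n == 2L) bb <- rbind(c(0, 0, 0), bonds)
      bb <- sweep(bb, 2, centre - colMeans(bb), "+")
      arr[, , i] <- place_sites(bb, spec)
    }
  } else { # globule
    for (i in seq_len(spec$n_frames)) {
      bb <- runif_shell(n, 0, spec$globule_radius)
      bb <- sweep(bb, 2, centre, "+")
      arr[, , i] <- place_sites(bb, spec)
    }
  }
  traj <- poly_trajectory(arr, box = spec$box, frame_time = spec$frame_time)
  list(topology = top, trajectory = traj)
}

# sample n points uniform in box at min-image distance > excl from all sites
sample_far_points <- function(n, box, sites, excl) {
  sites <- matrix(sites, ncol = 3)
  out <- matrix(NA_real_, 0, 3)
  while (nrow(out) < n) {
    m <- max(16L, ceiling((n - nrow(out)) * 1.6))
    cand <- cbind(stats::runif(m, 0, box[1]), stats::runif(m, 0, box[2]),
                  stats::runif(m, 0, box[3]))
    if (nrow(sites) > 0) {
      dmin <- apply(min_image_dist(cand, sites, box), 1, min)
      cand <- cand[dmin > excl, , drop = FALSE]
    }
    out <- rbind(out, cand)
  }
  out[seq_len(n), , drop = FALSE]
}

#' Generate an ion field for a chain trajectory
#'
#' With `ion_model = "uniform"` ions are independent and uniform in the box
#' every frame. With `"planted_bound"` each ion alternates bound and
#' unbound episodes whose durations are exponential with means
#' `dwell_tau_bound` / `dwell_tau_unbound` (ns); during a bound episode the
#' ion sits uniformly within `binding_shell` of one randomly chosen charged
#' site (tracking that site's motion), and while unbound it sits uniformly
#' in the box at more than 1 nm (minimum image) from every charged site.
#' The planted truth — every bound episode with its host site, frame range
#' and continuous duration — is returned alongside the coordinates.
#'
#' @param spec a [synthetic_spec()] with `n_monovalent`/`n_divalent` set.
#' @param topology,trajectory output of [generate_chain()].
#' @return The trajectory with `ions` and `ion_coords` filled in, plus an
#'   attribute `truth`: a data frame with columns `ion_id`, `site_index`
#'   (topology row of the host charged site), `start_frame`, `end_frame`,
#'   `duration_ns` (continuous planted duration) and `censored` (episode
#'   still running at the last frame).
#' @export
generate_ion_field <- function(spec, topology, trajectory) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1000003L)
  ions <- ion_set(spec$n_monovalent, spec$n_divalent)
  n_ions <- nrow(ions)
  n_frames <- trajectory$n_frames
  if (n_ions == 0L) {
    trajectory$ions <- ions
    trajectory$ion_coords <- array(NA_real_, c(0, 3, n_frames))
    attr(trajectory, "truth") <- data.frame(
      ion_id = integer(0), site_index = integer(0),
      start_frame = integer(0), end_frame = integer(0),
      duration_ns = numeric(0), censored = logical(0))
    return(trajectory)
  }
  box <- trajectory$box
  arr <- array(NA_real_, c(n_ions, 3, n_frames))
  cs <- charged_sites(topology)
  if (spec$ion_model == "uniform" || length(cs) == 0L) {
    for (i in seq_len(n_frames)) {
      arr[, , i] <- cbind(stats::runif(n_ions, 0, box[1]),
                          stats::runif(n_ions, 0, box[2]),
                          stats::runif(n_ions, 0, box[3]))
    }
    trajectory$ions <- ions
    trajectory$ion_coords <- arr
    attr(trajectory, "truth") <- data.frame(
      ion_id = integer(0), site_index = integer(0),
      start_frame = integer(0), end_frame = integer(0),
      duration_ns = numeric(0), censored = logical(0))
    return(trajectory)
  }
  dt_ns <- spec$frame_time / 1000   # ps -> ns
  t_total <- n_frames * dt_ns
  # rod chains are static, letting ion placement vectorize across frames
  static_chain <- spec$model == "rod"
  sites0 <- matrix(trajectory$polymer[cs, , 1], ncol = 3)
  truth <- vector("list", n_ions)
  for (j in seq_len(n_ions)) {
    # alternating unbound/bound timeline, starting unbound
    t_cur <- 0; bound <- FALSE
    segs <- list()
    while (t_cur < t_total) {
      dur <- stats::rexp(1, rate = 1 / if (bound) spec$dwell_tau_bound else
        spec$dwell_tau_unbound)
      segs[[length(segs) + 1L]] <- c(t_cur, min(t_cur + dur, t_total),
                                     as.numeric(bound), dur)
      t_cur <- t_cur + dur
      bound <- !bound
    }
    frame_times <- (seq_len(n_frames) - 1) * dt_ns
    state <- integer(n_frames)      # 0 unbound, else episode id
    host <- integer(0); ep_meta <- list()
    for (s in segs) {
      if (s[3] == 1) {
        sel <- which(frame_times >= s[1] & frame_times < s[2])
        site <- cs[sample.int(length(cs), 1L)]
        if (length(sel) > 0) {
          ep <- length(ep_meta) + 1L
          state[sel] <- ep
          ep_meta[[ep]] <- list(site = site,
                                start = sel[1], end = sel[length(sel)],
                                duration = s[4],
                                censored = (s[2] >= t_total && s[1] + s[4] > t_total))
        }
      }
    }
    # unbound frames: uniform, > 1 nm from every charged site (min image)
    unb <- which(state == 0L)
    if (length(unb) > 0) {
      if (static_chain) {
        arr[j, , unb] <- t(sample_far_points(length(unb), box, sites0, 1.0))
      } else {
        for (i in unb) {
          arr[j, , i] <- sample_far_points(
            1L, box, matrix(trajectory$polymer[cs, , i], ncol = 3), 1.0)
        }
      }
    }
    # bound frames: uniform in the binding shell of the host site
    for (ep in seq_along(ep_meta)) {
      sel <- which(state == ep)
      off <- runif_shell(length(sel), spec$binding_shell[1],
                         spec$binding_shell[2])
      site <- ep_meta[[ep]]$site
      if (static_chain) {
        arr[j, , sel] <- t(sweep(off, 2, trajectory$polymer[site, , 1], "+"))
      } else {
        for (k in seq_along(sel)) {
          arr[j, , sel[k]] <- trajectory$polymer[site, , sel[k]] + off[k, ]
        }
      }
    }
    if (length(ep_meta) > 0) {
      truth[[j]] <- data.frame(
        ion_id = j,
        site_index = vapply(ep_meta, function(e) e$site, integer(1)),
        start_frame = vapply(ep_meta, function(e) e$start, numeric(1)),
        end_frame = vapply(ep_meta, function(e) e$end, numeric(1)),
        duration_ns = vapply(ep_meta, function(e) e$duration, numeric(1)),
        censored = vapply(ep_meta, function(e) e$censored, logical(1)))
    }
  }
  trajectory$ions <- ions
  trajectory$ion_coords <- arr
  truth <- do.call(rbind, truth[!vapply(truth, is.null, logical(1))])
  if (is.null(truth)) {
    truth <- data.frame(ion_id = integer(0), site_index = integer(0),
                        start_frame = integer(0), end_frame = integer(0),
                        duration_ns = numeric(0), censored = logical(0))
  }
  attr(trajectory, "truth") <- truth
  trajectory
}

#' Plant water-proxy shells around ions
#'
#' Places exactly `waters_per_ion` water-proxy sites uniformly within
#' 0.38 nm of every ion in every frame, plus `n_decoy_waters` decoys at
#' more than 0.5 nm (minimum image) from all ions, giving hydration-number
#' estimators an exact planted target.
#'
#' @param spec a [synthetic_spec()].
#' @param trajectory a [poly_trajectory()] with an ion block.
#' @return The trajectory with `water_coords` filled in.
#' @export
generate_water_shell <- function(spec, trajectory) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 2000003L)
  if (is.null(trajectory$ion_coords)) stop("trajectory has no ion block")
  n_ions <- dim(trajectory$ion_coords)[1]
  n_w <- n_ions * spec$waters_per_ion + spec$n_decoy_waters
  if (n_w == 0L) return(trajectory)
  arr <- array(NA_real_, c(n_w, 3, trajectory$n_frames))
  for (i in seq_len(trajectory$n_frames)) {
    row <- 1L
    if (spec$waters_per_ion > 0L) {
      for (j in seq_len(n_ions)) {
        off <- runif_shell(spec$waters_per_ion, 0, 0.3799)
        arr[row:(row + spec$waters_per_ion - 1L), , i] <-
          sweep(off, 2, trajectory$ion_coords[j, , i], "+")
        row <- row + spec$waters_per_ion
      }
    }
    if (spec$n_decoy_waters > 0L) {
      arr[row:(row + spec$n_decoy_waters - 1L), , i] <-
        sample_far_points(spec$n_decoy_waters, trajectory$box,
                          matrix(trajectory$ion_coords[, , i], ncol = 3),
                          0.501)
    }
  }
  trajectory$water_coords <- arr
  trajectory
}

#' Generate a complete synthetic system
#'
#' Convenience wrapper running [generate_chain()], [generate_ion_field()]
#' and [generate_water_shell()] in sequence.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `topology`, `trajectory` (ions and waters attached) and
#'   `truth` (the planted bound-episode record).
#' @export
generate_system <- function(spec) {
  chain <- generate_chain(spec)
  traj <- generate_ion_field(spec, chain$topology, chain$trajectory)
  traj <- generate_water_shell(spec, traj)
  list(topology = chain$topology, trajectory = traj,
       truth = attr(traj, "truth"))
}
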