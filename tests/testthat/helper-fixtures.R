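# shared builders for tiny, fully-known test systems

# bead chain of n backbone anchors (optionally one charged site per bead)
toy_topology <- function(n = 5, dx = 0.5, with_charges = FALSE) {
  apm <- if (with_charges) 2L else 1L
  atoms <- data.frame(
    atom_id = seq_len(n * apm),
    atom_label = rep(if (with_charges) c("BB", "SC") else "BB", n),
    chain_id = "A",
    monomer_index = rep(0:(n - 1L), each = apm),
    role = rep(if (with_charges) c("backbone_anchor", "charged_site") else
      "backbone_anchor", n),
    formal_charge = rep(if (with_charges) c(0, -1) else 0, n),
    stringsAsFactors = FALSE
  )
  poly_topology(atoms, dx = dx)
}

# trajectory from a list of per-frame coordinate matrices
traj_from_frames <- function(frames, box = 20, frame_time = 10,
                             ions = NULL, ion_frames = NULL,
                             water_frames = NULL) {
  stackf <- function(lst) {
    if (is.null(lst)) return(NULL)
    arr <- array(NA_real_, c(nrow(lst[[1]]), 3, length(lst)))
    for (i in seq_along(lst)) arr[, , i] <- lst[[i]]
    arr
  }
  poly_trajectory(stackf(frames), box = box, frame_time = frame_time,
                  ions = ions, ion_coords = stackf(ion_frames),
                  water_coords = stackf(water_frames))
}

# straight rod coordinates along x: n beads spaced b apart, from origin
rod_coords <- function(n, b = 0.5, origin = c(0, 0, 0)) {
  sweep(cbind((0:(n - 1)) * b, 0, 0), 2, origin, "+")
}

# random rigid transform applied to an n x 3 matrix
random_rigid <- function(x, seed = 1) {
  set.seed(seed)
  a <- stats::rnorm(3); b <- stats::rnorm(3)
  u1 <- a / sqrt(sum(a^2))
  v <- b - sum(b * u1) * u1; u2 <- v / sqrt(sum(v^2))
  u3 <- c(u1[2] * u2[3] - u1[3] * u2[2],
          u1[3] * u2[1] - u1[1] * u2[3],
          u1[1] * u2[2] - u1[2] * u2[1])
  rot <- cbind(u1, u2, u3)
  shift <- stats::runif(3, -1, 1)
  sweep(x %*% rot, 2, shift, "+")
}

# small random site/ion configurations for oracle comparisons
random_config <- function(seed, max_sites = 25, max_ions = 25, box = 4) {
  set.seed(seed)
  ns <- sample(2:max_sites, 1); ni <- sample(0:max_ions, 1)
  list(
    sites = matrix(stats::runif(3 * ns, 0, box), ncol = 3),
    ions = if (ni > 0) matrix(stats::runif(3 * ni, 0, box), ncol = 3) else
      matrix(numeric(0), ncol = 3),
    box = rep(box, 3)
  )
}

# wrap a static site/ion configuration as topology + one-frame trajectory
config_system <- function(cfg) {
  ns <- nrow(cfg$sites)
  atoms <- data.frame(
    atom_id = seq_len(2 * ns), atom_label = rep(c("BB", "SC"), ns),
    chain_id = "A", monomer_index = rep(0:(ns - 1L), each = 2),
    role = rep(c("backbone_anchor", "charged_site"), ns),
    formal_charge = rep(c(0, -1), ns), stringsAsFactors = FALSE
  )
  top <- poly_topology(atoms, dx = 0.5, n_monomers = max(ns, 2L))
  coords <- matrix(NA_real_, 2 * ns, 3)
  coords[seq(1, 2 * ns, 2), ] <- cfg$sites   # anchors share site positions
  coords[seq(2, 2 * ns, 2), ] <- cfg$sites
  ni <- nrow(cfg$ions)
  tr <- traj_from_frames(list(coords), box = cfg$box[1],
                         ions = ion_set(n_monovalent = ni),
                         ion_frames = if (ni > 0) list(cfg$ions) else NULL)
  list(top = top, tr = tr)
}

# independent least-squares superposition (Kabsch via SVD), used only as a
# cross-check oracle in tests
kabsch_oracle <- function(x, ref) {
  cx <- colMeans(x); cr <- colMeans(ref)
  xc <- sweep(x, 2, cx); rc <- sweep(ref, 2, cr)
  s <- svd(t(xc) %*% rc)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(xc %*% t(rot), 2, cr, "+")
}

# two-pass superposition of a list of frames (mean, fit, re-mean, fit),
# returning the flattened frames-by-3K coordinate matrix
superpose_oracle <- function(frames) {
  mean_of <- function(lst) Reduce(`+`, lst) / length(lst)
  fitted <- lapply(frames, kabsch_oracle, ref = mean_of(frames))
  fitted <- lapply(fitted, kabsch_oracle, ref = mean_of(fitted))
  t(vapply(fitted, function(x) as.numeric(t(x)),
           numeric(3 * nrow(frames[[1]]))))
}

# brute-force minimum-image distance between two points
brute_min_image <- function(p, q, box) {
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- q + c(i, j, k) * box - p
    best <- min(best, sqrt(sum(d^2)))
  }
  best
}
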