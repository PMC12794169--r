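#' Per-frame end-to-end distance
#'
#' Euclidean distance between the first and last backbone anchor of each
#' chain, in nm. For multi-chain topologies the per-chain values are
#' averaged within each frame. The chain should be made whole first
#' ([make_whole_trajectory()]) if the coordinates are wrapped.
#'
#' @param trajectory a [poly_trajectory()].
#' @param topology matching [poly_topology()].
#' @return Numeric vector, one value per frame (nm).
#' @export
end_to_end <- function(trajectory, topology) {
  chains <- unique(topology$atoms$chain_id)
  per_chain <- lapply(chains, function(ch) {
    anch <- backbone_anchors(topology, chain = ch)
    if (length(anch) < 2L) {
      stop("chain '", ch, "' has fewer than two backbone anchors")
    }
    a <- matrix(trajectory$polymer[anch[1], , ], nrow = 3)
    b <- matrix(trajectory$polymer[anch[length(anch)], , ], nrow = 3)
    sqrt(colSums((b - a)^2))
  })
  rowMeans(do.call(cbind, per_chain))
}

#' Per-frame radius of gyration
#'
#' Mass-weighted root-mean-square distance of all polymer atoms from their
#' mass-weighted centroid, per frame.
#'
#' @param trajectory a [poly_trajectory()].
#' @param topology matching [poly_topology()].
#' @param mass per-atom masses; default unit mass for every atom.
#' @return Numeric vector, one value per frame (nm).
#' @export
radius_of_gyration <- function(trajectory, topology,
                               mass = rep(1, nrow(topology$atoms))) {
  if (length(mass) != nrow(topology$atoms)) {
    stop("mass vector length must equal the atom count")
  }
  if (any(!is.finite(mass)) || any(mass <= 0)) {
    stop("masses must be positive")
  }
  w <- mass / sum(mass)
  vapply(seq_len(trajectory$n_frames), function(i) {
    x <- trajectory$polymer[, , i, drop = FALSE][, , 1, drop = TRUE]
    x <- matrix(x, ncol = 3)
    ctr <- colSums(x * w)
    sqrt(sum(w * rowSums(sweep(x, 2, ctr)^2)))
  }, numeric(1))
}

#' Compactness series of a trajectory
#'
#' Bundles the per-frame end-to-end distance and radius of gyration with
#' the contour-length-normalized end-to-end distance and the ensemble
#' means used for the size ratio.
#'
#' @inheritParams radius_of_gyration
#' @return List of class `conformation_series`: `ree`, `rg`,
#'   `ree_normalized` (per frame), `mean_sq_ree`, `mean_sq_rg` (nm^2) and
#'   `size_ratio`.
#' @export
conformation_series <- function(trajectory, topology,
                                mass = rep(1, nrow(topology$atoms))) {
  ree <- end_to_end(trajectory, topology)
  rg <- radius_of_gyration(trajectory, topology, mass)
  lc <- contour_length(topology)
  msr <- mean(ree^2); msg <- mean(rg^2)
  structure(
    list(ree = ree, rg = rg, ree_normalized = ree / lc,
         mean_sq_ree = msr, mean_sq_rg = msg,
         size_ratio = if (msg > 0) msr / msg else NA_real_,
         frame_time = trajectory$frame_time),
    class = "conformation_series"
  )
}

#' Ensemble size ratio
#'
#' `<Ree^2> / <Rg^2>`, the ratio of the mean-squared end-to-end distance
#' to the mean-squared radius of gyration (means over frames taken before
#' dividing). It discriminates conformational regimes: about 12 for rigid
#' rods, about 6 for ideal random coils, below 4 for collapsed globules.
#'
#' @param series a [conformation_series()].
#' @return Dimensionless ratio.
#' @export
size_ratio <- function(series) {
  if (!is.finite(series$mean_sq_rg) || series$mean_sq_rg <= 0) {
    stop("degenerate ensemble: <Rg^2> is zero")
  }
  series$mean_sq_ree / series$mean_sq_rg
}

# ---- essential-dynamics PCA -----------------------------------------------

# Kabsch least-squares superposition of x (n x 3) onto ref (n x 3):
# returns the transformed copy of x
kabsch_fit <- function(x, ref) {
  cx <- colMeans(x); cr <- colMeans(ref)
  xc <- sweep(x, 2, cx); rc <- sweep(ref, 2, cr)
  sv <- svd(crossprod(xc, rc))
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(xc %*% t(rot), 2, cr, "+")
}

#' Backbone-flexibility PCA
#'
#' Essential-dynamics analysis of the backbone anchor atoms: frames from
#' all supplied replicate trajectories are pooled; each frame is rigid-body
#' superposed (least-squares rotation + translation) onto the pooled mean
#' structure in two passes (mean, superpose, re-mean, superpose); the
#' covariance matrix of the flattened 3K anchor coordinates is then
#' eigendecomposed. Rigid-body motion therefore carries no variance, and
#' the eigenvalue spectrum describes internal flexibility only.
#'
#' @param trajectories a single [poly_trajectory()] or a list of replicate
#'   trajectories with identical anchor counts.
#' @param topology matching [poly_topology()].
#' @param anchors row indices of the atoms to analyze; default the backbone
#'   anchors.
#' @return List of class `pca_result`: `eigenvalues` (nm^2, descending),
#'   `components` (3K x 3K orthonormal columns), `projections` (frames x 2,
#'   PC1/PC2 scores, with a `replicate` column), `variance_fraction_pc12`,
#'   `mean_structure` (K x 3) and `degenerate` (TRUE when all frames are
#'   identical up to rigid motion, in which case all eigenvalues are 0).
#' @export
pca_flexibility <- function(trajectories, topology,
                            anchors = backbone_anchors(topology)) {
  if (inherits(trajectories, "poly_trajectory")) {
    trajectories <- list(trajectories)
  }
  k <- length(anchors)
  if (k < 2L) stop("need at least two anchor atoms")
  frames <- list(); rep_id <- integer(0)
  for (r in seq_along(trajectories)) {
    tr <- trajectories[[r]]
    for (i in seq_len(tr$n_frames)) {
      x <- matrix(tr$polymer[, , i][anchors, ], ncol = 3)
      frames[[length(frames) + 1L]] <- x
      rep_id <- c(rep_id, r)
    }
  }
  n <- length(frames)
  if (n < 2L) stop("need at least two frames in total")
  mean_of <- function(lst) Reduce(`+`, lst) / length(lst)
  m0 <- mean_of(frames)
  fitted <- lapply(frames, kabsch_fit, ref = m0)
  m1 <- mean_of(fitted)
  fitted <- lapply(fitted, kabsch_fit, ref = m1)
  m1 <- mean_of(fitted)
  flat <- t(vapply(fitted, function(x) as.numeric(t(x)), numeric(3 * k)))
  centered <- sweep(flat, 2, colMeans(flat))
  covm <- crossprod(centered) / (n - 1)
  eig <- eigen(covm, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  total <- sum(ev)
  degenerate <- total < 1e-20
  proj <- centered %*% eig$vectors[, 1:2, drop = FALSE]
  projections <- data.frame(frame = seq_len(n), replicate = rep_id,
                            PC1 = proj[, 1], PC2 = proj[, 2])
  structure(
    list(eigenvalues = ev, components = eig$vectors,
         projections = projections,
         variance_fraction_pc12 = if (degenerate) 0 else
           sum(ev[1:2]) / total,
         mean_structure = m1, degenerate = degenerate),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  if (x$degenerate) {
    cat("pca_result: degenerate ensemble (no variance after superposition)\n")
  } else {
    cat(sprintf("pca_result: PC1+PC2 capture %.1f%% of variance\n",
                100 * x$variance_fraction_pc12))
    cat("  leading eigenvalues (nm^2):",
        paste(signif(utils::head(x$eigenvalues, 4), 4), collapse = ", "),
        "\n")
  }
  invisible(x)
}
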