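#' Contour length of the fully extended chain
#'
#' `Lc = N * dx`, the product of the monomer count and the monomer length.
#' Typical monomer lengths: 0.61-0.63 nm for single-stranded nucleotides,
#' 0.38 nm for amino-acid residues, 0.50-0.53 nm for saccharide units,
#' 0.33 nm for base-paired duplex DNA and 0.27 nm for phosphate units of
#' inorganic polyphosphate.
#'
#' @param topology a [poly_topology()].
#' @return Contour length in nm.
#' @export
contour_length <- function(topology) {
  if (is.null(topology$dx) || !is.finite(topology$dx) || topology$dx <= 0) {
    stop("monomer length dx is not configured on this topology")
  }
  topology$n_monomers * topology$dx
}

#' Linear charge density along the backbone
#'
#' `lambda_x = q_tot / Lc`: the total charge magnitude divided by the
#' contour length of the fully extended chain, in e/nm. Charge magnitudes
#' are used so densities are positive for polyanions.
#'
#' @param topology a [poly_topology()].
#' @return Linear charge density, e/nm.
#' @export
lambda_x <- function(topology) {
  q_total(topology) / contour_length(topology)
}

# first principal axis of a point cloud: unit vector + centroid
principal_axis <- function(points) {
  ctr <- colMeans(points)
  sv <- svd(sweep(points, 2, ctr))
  list(centre = ctr, axis = sv$v[, 1])
}

# perpendicular distance of points from the line (centre, axis)
axis_distance <- function(points, centre, axis) {
  rel <- sweep(matrix(points, ncol = 3), 2, centre)
  along <- rel %*% axis
  sqrt(pmax(0, rowSums(rel^2) - as.numeric(along)^2))
}

#' Radial charge density about the backbone axis
#'
#' `lambda_yz = (sum_i |q_i| / d_yz_i) / N`, where `d_yz_i` is the
#' perpendicular distance of charge `i` from the main axis of the fully
#' extended chain, in e/nm. The main axis is the first principal axis of
#' the backbone anchor atoms of the extended reference conformation, so
#' the descriptor is intrinsic to the chemistry, not to any sampled frame.
#'
#' @param topology a [poly_topology()].
#' @param reference `n_atoms x 3` coordinates (nm) of the fully extended
#'   conformation; defaults to the `reference` attribute the readers and
#'   the synthetic builder attach to the topology.
#' @param d_min singularity guard (nm): a charge closer than this to the
#'   axis is an error, since the formula diverges on the axis.
#' @return Radial charge density, e/nm.
#' @export
lambda_yz <- function(topology, reference = NULL, d_min = 0.01) {
  if (is.null(reference)) reference <- attr(topology, "reference")
  if (is.null(reference)) {
    stop("no reference conformation: pass `reference` or use a topology ",
         "built by read_topology()/generate_chain()")
  }
  cs <- charged_sites(topology)
  if (length(cs) == 0L) return(0)
  anchors <- backbone_anchors(topology)
  if (length(anchors) < 2L) stop("need >= 2 backbone anchors for the axis")
  ax <- principal_axis(reference[anchors, , drop = FALSE])
  d_yz <- axis_distance(reference[cs, , drop = FALSE], ax$centre, ax$axis)
  if (any(d_yz <= d_min)) {
    stop("degenerate geometry: charged site within ", d_min,
         " nm of the main axis")
  }
  q <- abs(topology$atoms$formal_charge[cs])
  sum(q / d_yz) / topology$n_monomers
}

#' Charge-density descriptors of a polyanion
#'
#' Computes both the linear charge density along the backbone
#' ([lambda_x()]) and the radial charge density about the backbone axis
#' ([lambda_yz()]) in one result object.
#'
#' @inheritParams lambda_yz
#' @return List of class `charge_density_result` with `lambda_x`,
#'   `lambda_yz`, `q_tot` (e), `contour_length` (nm) and `d_yz` (nm per
#'   charged site).
#' @export
charge_density <- function(topology, reference = NULL, d_min = 0.01) {
  if (is.null(reference)) reference <- attr(topology, "reference")
  lyz <- lambda_yz(topology, reference, d_min)
  cs <- charged_sites(topology)
  d_yz <- numeric(0)
  if (length(cs) > 0) {
    anchors <- backbone_anchors(topology)
    ax <- principal_axis(reference[anchors, , drop = FALSE])
    d_yz <- axis_distance(reference[cs, , drop = FALSE], ax$centre, ax$axis)
  }
  structure(
    list(lambda_x = lambda_x(topology), lambda_yz = lyz,
         q_tot = q_total(topology), contour_length = contour_length(topology),
         d_yz = d_yz),
    class = "charge_density_result"
  )
}

#' @export
print.charge_density_result <- function(x, ...) {
  cat(sprintf(
    "charge density: lambda_x = %.3f e/nm, lambda_yz = %.3f e/nm\n",
    x$lambda_x, x$lambda_yz))
  cat(sprintf("  q_tot = %g e over Lc = %.3f nm\n", x$q_tot,
              x$contour_length))
  invisible(x)
}
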