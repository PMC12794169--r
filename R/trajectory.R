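#' Construct a trajectory
#'
#' A `poly_trajectory` bundles per-frame coordinates (nm) for the polymer
#' atoms, the mobile ions and optional water-proxy sites, together with the
#' orthorhombic box edges and the time spacing between stored frames.
#' Coordinate blocks are `atoms x 3 x frames` arrays.
#'
#' @param polymer_coords numeric array `n_atoms x 3 x n_frames` (nm).
#' @param box numeric length-3 vector of box edge lengths (nm).
#' @param frame_time time between stored frames, ps.
#' @param ions optional [ion_set()] describing the ion block.
#' @param ion_coords optional array `n_ions x 3 x n_frames`.
#' @param water_coords optional array `n_waters x 3 x n_frames`.
#' @return Object of class `poly_trajectory`.
#' @export
poly_trajectory <- function(polymer_coords, box, frame_time = 1,
                            ions = NULL, ion_coords = NULL,
                            water_coords = NULL) {
  stopifnot(length(dim(polymer_coords)) == 3, dim(polymer_coords)[2] == 3)
  if (length(box) == 1) box <- rep(box, 3)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0)) {
    stop("box must be three positive edge lengths (nm)")
  }
  if (!is.finite(frame_time) || frame_time <= 0) {
    stop("frame_time must be positive (ps)")
  }
  n_frames <- dim(polymer_coords)[3]
  check_block <- function(x, label) {
    if (is.null(x)) return(NULL)
    stopifnot(length(dim(x)) == 3, dim(x)[2] == 3)
    if (dim(x)[3] != n_frames) {
      stop(label, " block has ", dim(x)[3], " frames, polymer has ", n_frames)
    }
    if (any(!is.finite(x))) stop("non-finite coordinate in ", label, " block")
    x
  }
  if (any(!is.finite(polymer_coords))) {
    stop("non-finite coordinate in polymer block")
  }
  ion_coords <- check_block(ion_coords, "ion")
  water_coords <- check_block(water_coords, "water")
  if (!is.null(ions) && !is.null(ion_coords) &&
      nrow(ions) != dim(ion_coords)[1]) {
    stop("ion table and ion coordinate block disagree on ion count")
  }
  structure(
    list(n_frames = n_frames, frame_time = frame_time, box = as.numeric(box),
         polymer = polymer_coords, ions = ions, ion_coords = ion_coords,
         water_coords = water_coords),
    class = "poly_trajectory"
  )
}

#' @export
print.poly_trajectory <- function(x, ...) {
  cat("poly_trajectory:", x$n_frames, "frames x", dim(x$polymer)[1],
      "polymer atoms")
  if (!is.null(x$ion_coords)) cat(",", dim(x$ion_coords)[1], "ions")
  if (!is.null(x$water_coords)) cat(",", dim(x$water_coords)[1], "waters")
  cat("\n  box:", paste(signif(x$box, 4), collapse = " x "),
      "nm; frame_time:", x$frame_time, "ps\n")
  invisible(x)
}

#' Frame accessor
#'
#' @param trajectory a [poly_trajectory()].
#' @param i frame index.
#' @param block one of `"polymer"`, `"ions"`, `"waters"`.
#' @return `n x 3` coordinate matrix (nm).
#' @export
frame_coords <- function(trajectory, i, block = "polymer") {
  x <- switch(block,
    polymer = trajectory$polymer,
    ions = trajectory$ion_coords,
    waters = trajectory$water_coords,
    stop("unknown block: ", block))
  if (is.null(x)) stop("trajectory has no ", block, " block")
  x[, , i, drop = FALSE][, , 1, drop = FALSE][, , 1]
}

# ---- minimum-image helpers -------------------------------------------------

#' Minimum-image pairwise distances in an orthorhombic box
#'
#' @param a,b coordinate matrices `n x 3` and `m x 3` (nm).
#' @param box length-3 edge vector (nm); `NULL` for open boundaries.
#' @return `n x m` matrix of distances (nm).
#' @export
min_image_dist <- function(a, b, box = NULL) {
  a <- matrix(a, ncol = 3); b <- matrix(b, ncol = 3)
  d2 <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], "-")
    if (!is.null(box)) dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

# minimum-image displacement, row-wise on an n x 3 matrix (or one vector)
min_image_vec <- function(d, box) {
  d <- rbind(d)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

# ---- periodic reconstruction ----------------------------------------------

#' Reconstruct chains broken across periodic boundaries
#'
#' Rebuilds each chain so that consecutive backbone anchors are joined by
#' their minimum-image displacement, walking anchors in monomer order and
#' translating each monomer's non-anchor atoms with the same lattice shift
#' (via minimum image relative to the rebuilt anchor). Internal geometry is
#' preserved up to whole-lattice translations; applying the operation twice
#' is a no-op.
#'
#' @param coords `n_atoms x 3` matrix for one frame (nm), atom order matching
#'   `topology$atoms`.
#' @param topology a [poly_topology()].
#' @param box length-3 box edge vector (nm).
#' @return `n_atoms x 3` matrix with contiguous chains.
#' @export
make_whole <- function(coords, topology, box) {
  if (length(box) == 1) box <- rep(box, 3)
  out <- coords
  half_min <- min(box) / 2
  for (ch in unique(topology$atoms$chain_id)) {
    anch <- backbone_anchors(topology, chain = ch)
    if (length(anch) < 2) next
    for (j in 2:length(anch)) {
      d <- out[anch[j], ] - out[anch[j - 1], ]
      d_mi <- d - box * round(d / box)
      if (sqrt(sum(d_mi^2)) > half_min) {
        stop("ambiguous reconstruction: anchor-anchor bond exceeds half the ",
             "shortest box edge after unwrapping")
      }
      out[anch[j], ] <- out[anch[j - 1], ] + d_mi
    }
    # carry each monomer's satellites along with its anchor
    in_chain <- which(topology$atoms$chain_id == ch)
    anchor_of <- match(topology$atoms$monomer_index[in_chain],
                       topology$atoms$monomer_index[anch])
    for (ii in seq_along(in_chain)) {
      a <- in_chain[ii]
      if (topology$atoms$role[a] == "backbone_anchor") next
      ref <- anch[anchor_of[ii]]
      if (is.na(ref)) next
      d <- coords[a, ] - coords[ref, ]
      d_mi <- d - box * round(d / box)
      out[a, ] <- out[ref, ] + d_mi
    }
  }
  out
}

#' Apply make_whole to every frame of a trajectory
#'
#' @param trajectory a [poly_trajectory()].
#' @param topology matching [poly_topology()].
#' @return The trajectory with reconstructed polymer coordinates.
#' @export
make_whole_trajectory <- function(trajectory, topology) {
  for (i in seq_len(trajectory$n_frames)) {
    trajectory$polymer[, , i] <-
      make_whole(trajectory$polymer[, , i], topology, trajectory$box)
  }
  trajectory
}

# ---- extended XYZ exchange format -----------------------------------------

#' Write a trajectory as extended multi-frame XYZ
#'
#' Plain-text exchange format: per frame, an atom-count line, then a comment
#' line `box bx by bz time t` (nm, ps), then one `label x y z` line per atom
#' (nm, six decimals). Atom order is polymer block, then ions, then waters.
#'
#' @param trajectory a [poly_trajectory()].
#' @param topology the matching [poly_topology()] (supplies polymer labels).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(trajectory, topology, path) {
  labels <- topology$atoms$atom_label
  if (!is.null(trajectory$ion_coords)) {
    labels <- c(labels, ifelse(trajectory$ions$species == "divalent_cation",
                               "CAT2", "CAT1"))
  }
  if (!is.null(trajectory$water_coords)) {
    labels <- c(labels, rep("W", dim(trajectory$water_coords)[1]))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(trajectory$n_frames)) {
    xyz <- trajectory$polymer[, , i]
    if (!is.null(trajectory$ion_coords)) {
      xyz <- rbind(xyz, trajectory$ion_coords[, , i])
    }
    if (!is.null(trajectory$water_coords)) {
      xyz <- rbind(xyz, trajectory$water_coords[, , i])
    }
    writeLines(as.character(nrow(xyz)), con)
    writeLines(sprintf("box %.6f %.6f %.6f time %.6f",
                       trajectory$box[1], trajectory$box[2],
                       trajectory$box[3],
                       (i - 1) * trajectory$frame_time), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", labels, xyz[, 1], xyz[, 2],
                       xyz[, 3]), con)
  }
  invisible(path)
}

#' Read a trajectory from extended multi-frame XYZ or multi-model PDB
#'
#' For XYZ the comment line must carry the box record written by
#' [write_trajectory_xyz()]; the first `nrow(topology$atoms)` atoms of each
#' frame are the polymer, the next `nrow(ions)` the ions, the remainder
#' water proxies. Multi-model PDB files (Angstrom, converted to nm) are
#' accepted for polymer-only trajectories; box and frame time must then be
#' supplied.
#'
#' @param path input file.
#' @param topology a [poly_topology()].
#' @param ions optional [ion_set()] declaring the ion block.
#' @param format `"xyz"` or `"pdb"`; guessed from the extension by default.
#' @param box,frame_time required for PDB input (nm, ps).
#' @return A [poly_trajectory()].
#' @export
read_trajectory <- function(path, topology, ions = NULL, format = NULL,
                            box = NULL, frame_time = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  }
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE)
    xyz <- pdb$xyz  # frames x 3n, Angstrom
    n_at <- ncol(xyz) / 3
    if (n_at != nrow(topology$atoms)) {
      stop("PDB frame has ", n_at, " atoms; topology declares ",
           nrow(topology$atoms))
    }
    if (is.null(box) || is.null(frame_time)) {
      stop("box and frame_time must be given for PDB trajectories")
    }
    n_frames <- nrow(xyz)
    arr <- array(NA_real_, c(n_at, 3, n_frames))
    for (i in seq_len(n_frames)) {
      arr[, , i] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE) / 10
    }
    return(poly_trajectory(arr, box = box, frame_time = frame_time))
  }
  lines <- readLines(path)
  n_poly <- nrow(topology$atoms)
  n_ions <- if (is.null(ions)) 0L else nrow(ions)
  frames_poly <- list(); frames_ion <- list(); frames_wat <- list()
  box_rec <- NULL; times <- numeric(0)
  pos <- 1L; fr <- 0L
  while (pos <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[pos])) {
      stop("malformed XYZ: expected atom count at line ", pos)
    }
    n_at <- as.integer(lines[pos])
    if (pos + 1L + n_at > length(lines)) {
      stop("malformed XYZ: frame ", fr + 1L, " truncated")
    }
    cm <- strsplit(trimws(lines[pos + 1L]), "\\s+")[[1]]
    if (length(cm) < 4 || cm[1] != "box") {
      stop("malformed XYZ: frame ", fr + 1L, " lacks 'box bx by bz' comment")
    }
    bx <- as.numeric(cm[2:4])
    if (is.null(box_rec)) box_rec <- bx
    t_i <- if (length(cm) >= 6 && cm[5] == "time") as.numeric(cm[6]) else NA
    body <- lines[(pos + 2L):(pos + 1L + n_at)]
    parts <- strsplit(trimws(body), "\\s+")
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(xyz))) {
      stop("non-finite coordinate in XYZ frame ", fr + 1L)
    }
    if (n_at < n_poly + n_ions) {
      stop("XYZ frame ", fr + 1L, " has ", n_at,
           " atoms; need at least ", n_poly + n_ions)
    }
    fr <- fr + 1L
    frames_poly[[fr]] <- xyz[seq_len(n_poly), , drop = FALSE]
    if (n_ions > 0) {
      frames_ion[[fr]] <- xyz[n_poly + seq_len(n_ions), , drop = FALSE]
    }
    if (n_at > n_poly + n_ions) {
      frames_wat[[fr]] <- xyz[(n_poly + n_ions + 1L):n_at, , drop = FALSE]
    }
    times <- c(times, t_i)
    pos <- pos + 2L + n_at
  }
  if (fr == 0L) stop("empty XYZ file")
  dt <- if (fr >= 2 && all(is.finite(times))) diff(times)[1] else 1
  stack <- function(lst) {
    if (length(lst) < fr || length(lst) == 0) return(NULL)
    arr <- array(NA_real_, c(nrow(lst[[1]]), 3, fr))
    for (i in seq_len(fr)) arr[, , i] <- lst[[i]]
    arr
  }
  poly_trajectory(
    stack(frames_poly), box = box_rec, frame_time = max(dt, 1e-12),
    ions = ions, ion_coords = stack(frames_ion),
    water_coords = stack(frames_wat)
  )
}
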