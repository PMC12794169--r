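#' Construct a polymer topology
#'
#' A `poly_topology` holds the static description of a polyanion model:
#' one row per atom with its chain, monomer assignment, structural role and
#' formal charge, together with the monomer length `dx` used to define the
#' contour length of the fully extended chain.
#'
#' @param atoms data frame with columns `atom_id` (integer), `atom_label`
#'   (character), `chain_id` (character), `monomer_index` (0-based integer),
#'   `role` (one of `"backbone_anchor"`, `"charged_site"`, `"other"`) and
#'   `formal_charge` (elementary charge units; charged sites on the polymer
#'   must be strictly negative).
#' @param dx monomer length in nm (> 0).
#' @param n_monomers number of monomers `N`; defaults to
#'   `max(monomer_index) + 1`.
#' @param metadata optional named list (system name, provenance of `dx`, ...).
#'
#' @return An object of class `poly_topology`: a list with elements `atoms`,
#'   `dx`, `n_monomers` and `metadata`.
#'
#' @details Formal charges live here, not in the coordinate file: standard
#' PDB records carry no usable formal charge, so a sidecar table is the
#' source of truth (see [read_topology()]).
#'
#' @seealso [read_topology()], [charged_sites()], [backbone_anchors()],
#'   [q_total()], [contour_length()]
#' @export
poly_topology <- function(atoms, dx, n_monomers = NULL, metadata = list()) {
  required <- c("atom_id", "atom_label", "chain_id", "monomer_index",
                "role", "formal_charge")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("topology atoms table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  atoms$atom_id <- as.integer(atoms$atom_id)
  atoms$monomer_index <- as.integer(atoms$monomer_index)
  if (anyDuplicated(atoms$atom_id)) stop("duplicate atom_id in topology")
  ok_roles <- c("backbone_anchor", "charged_site", "other")
  if (!all(atoms$role %in% ok_roles)) {
    stop("role must be one of: ", paste(ok_roles, collapse = ", "))
  }
  if (is.null(n_monomers)) n_monomers <- max(atoms$monomer_index) + 1L
  n_monomers <- as.integer(n_monomers)
  if (n_monomers < 2L) stop("topology needs N >= 2 monomers")
  if (any(atoms$monomer_index < 0L | atoms$monomer_index >= n_monomers)) {
    stop("monomer_index out of range [0, N)")
  }
  if (!is.numeric(dx) || length(dx) != 1L || !is.finite(dx) || dx <= 0) {
    stop("monomer length dx must be a single positive number (nm)")
  }
  cs <- atoms$role == "charged_site"
  if (any(cs & atoms$formal_charge == 0)) {
    stop("charged_site atoms must carry a nonzero formal charge")
  }
  if (any(cs & atoms$formal_charge > 0)) {
    stop("polymer charged sites must be negative")
  }
  # backbone anchors must be ordered by monomer index within each chain
  for (ch in unique(atoms$chain_id)) {
    mi <- atoms$monomer_index[atoms$role == "backbone_anchor" &
                                atoms$chain_id == ch]
    if (is.unsorted(mi)) {
      stop("backbone anchors of chain '", ch,
           "' are not ordered by monomer_index")
    }
  }
  structure(
    list(atoms = atoms, dx = dx, n_monomers = n_monomers,
         metadata = metadata),
    class = "poly_topology"
  )
}

#' @export
print.poly_topology <- function(x, ...) {
  cat("poly_topology:", nrow(x$atoms), "atoms,", x$n_monomers,
      "monomers, dx =", x$dx, "nm\n")
  cat("  chains:", paste(unique(x$atoms$chain_id), collapse = ", "), "\n")
  cat("  charged sites:", sum(x$atoms$role == "charged_site"),
      " (q_tot =", q_total(x), "e)\n")
  invisible(x)
}

#' Atom selections on a topology
#'
#' Row indices (into `topology$atoms` and into the trajectory's polymer
#' coordinate block, which shares the same atom order) of the charged sites
#' and of the backbone anchor atoms.
#'
#' @param topology a [poly_topology()].
#' @param chain optional chain id to restrict to.
#' @return Integer vector of row indices.
#' @export
charged_sites <- function(topology, chain = NULL) {
  sel <- topology$atoms$role == "charged_site"
  if (!is.null(chain)) sel <- sel & topology$atoms$chain_id == chain
  which(sel)
}

#' @rdname charged_sites
#' @export
backbone_anchors <- function(topology, chain = NULL) {
  sel <- topology$atoms$role == "backbone_anchor"
  if (!is.null(chain)) sel <- sel & topology$atoms$chain_id == chain
  idx <- which(sel)
  idx[order(topology$atoms$chain_id[idx], topology$atoms$monomer_index[idx])]
}

#' Total charge magnitude of the polymer
#'
#' Sum of absolute formal charges over the charged sites, in elementary
#' charge units. This is the q_tot entering the linear charge density.
#'
#' @param topology a [poly_topology()].
#' @return Numeric scalar (e).
#' @export
q_total <- function(topology) {
  sum(abs(topology$atoms$formal_charge[charged_sites(topology)]))
}

#' Ion records
#'
#' A small table describing the mobile cations of a system; species are
#' labelled by valence only (the analyses never need element identity).
#'
#' @param n_monovalent number of +1 cations (e.g. Na+).
#' @param n_divalent number of +2 cations (e.g. Ca2+).
#' @return data frame of class `ion_set` with columns `ion_id`, `species`,
#'   `formal_charge`.
#' @export
ion_set <- function(n_monovalent = 0L, n_divalent = 0L) {
  n1 <- as.integer(n_monovalent); n2 <- as.integer(n_divalent)
  if (n1 < 0L || n2 < 0L) stop("ion counts must be non-negative")
  ions <- data.frame(
    ion_id = seq_len(n1 + n2),
    species = rep(c("monovalent_cation", "divalent_cation"), c(n1, n2)),
    formal_charge = rep(c(1, 2), c(n1, n2)),
    stringsAsFactors = FALSE
  )
  class(ions) <- c("ion_set", "data.frame")
  ions
}

#' Read a polymer topology from a PDB file plus a charge sidecar
#'
#' PDB files do not carry reliable formal charges, so the chemistry lives in
#' a sidecar CSV with columns `atom_id`, `monomer_index`, `role`,
#' `formal_charge`; the PDB supplies labels, chain ids and the reference
#' coordinates. Coordinates are converted from Angstrom to nm and attached
#' as the `reference` attribute (used as the extended reference conformation
#' by [lambda_yz()] when none is given explicitly).
#'
#' @param coords_path path to a PDB file (Angstrom).
#' @param charges_path path to the sidecar CSV.
#' @param dx monomer length in nm.
#' @param metadata optional named list.
#' @return A [poly_topology()] with a `reference` attribute (atoms x 3
#'   matrix, nm).
#' @export
read_topology <- function(coords_path, charges_path, dx, metadata = list()) {
  pdb <- bio3d::read.pdb(coords_path)
  at <- pdb$atom
  side <- utils::read.csv(charges_path, stringsAsFactors = FALSE)
  need <- c("atom_id", "monomer_index", "role", "formal_charge")
  if (!all(need %in% names(side))) {
    stop("sidecar must have columns: ", paste(need, collapse = ", "))
  }
  ids <- seq_len(nrow(at))
  missing_ids <- setdiff(ids, side$atom_id)
  if (length(missing_ids) > 0) {
    stop("sidecar is missing atom(s): ", paste(missing_ids, collapse = ", "))
  }
  side <- side[match(ids, side$atom_id), ]
  atoms <- data.frame(
    atom_id = ids,
    atom_label = trimws(at$elety),
    chain_id = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    monomer_index = as.integer(side$monomer_index),
    role = side$role,
    formal_charge = side$formal_charge,
    stringsAsFactors = FALSE
  )
  top <- poly_topology(atoms, dx = dx, metadata = metadata)
  ref <- cbind(at$x, at$y, at$z) / 10  # Angstrom -> nm
  attr(top, "reference") <- ref
  top
}

#' Write the sidecar charge table for a topology
#'
#' @param topology a [poly_topology()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_charge_sidecar <- function(topology, path) {
  utils::write.csv(
    topology$atoms[, c("atom_id", "monomer_index", "role", "formal_charge")],
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
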