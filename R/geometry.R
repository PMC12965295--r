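.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

#' Magnesium center of a chlorin
#'
#' Position of the central MG atom; when the magnesium is unmodelled, the
#' centroid of the four macrocycle nitrogens NA/NB/NC/ND is used instead.
#' This point anchors both the Mg-Mg donor-acceptor distance and the
#' point-dipole placement of the Qy transition.
#'
#' @param p a chlorin `pigment_instance` (class CHL_A or CHL_B).
#' @param registry a [default_registry()] (for the macrocycle atom names).
#' @return length-3 numeric, Angstrom.
#' @export
magnesium_center <- function(p, registry = default_registry()) {
  stopifnot(inherits(p, "pigment_instance"))
  if (!p$pigment_class %in% CHLORIN_CLASSES) {
    stop("magnesium_center expects a chlorin, got ", p$pigment_class)
  }
  m <- pigment_coords(p, "MG")
  if (nrow(m) == 1) return(unname(m[1, ]))
  n4 <- pigment_coords(p, registry$macrocycle_n)
  if (nrow(n4) == 4) return(unname(colMeans(n4)))
  stop("degenerate chlorin ", pigment_id(p),
       ": no MG and fewer than 4 macrocycle nitrogens")
}

#' Qy transition dipole of a chlorin
#'
#' Unit vector along the macrocycle NB -> ND axis (the conventional direction
#' of the chlorophyll Qy transition; configurable to NA -> NC via the
#' registry), anchored at the magnesium center. The sign of the direction is
#' immaterial downstream: the orientation factor kappa^2 is even in each
#' dipole.
#'
#' @inheritParams magnesium_center
#' @return object of class `transition_dipole`: list with `anchor` (Angstrom)
#'   and unit `direction`.
#' @export
qy_dipole <- function(p, registry = default_registry()) {
  atoms <- pigment_coords(p, registry$qy_atoms)
  if (nrow(atoms) != 2) {
    stop("degenerate chlorin ", pigment_id(p), ": missing Qy atoms ",
         paste(registry$qy_atoms, collapse = "/"))
  }
  transition_dipole(magnesium_center(p, registry),
                    atoms[2, ] - atoms[1, ])
}

#' @rdname qy_dipole
#' @param anchor point the dipole sits at (Angstrom).
#' @param direction any non-zero 3-vector; stored normalised.
#' @export
transition_dipole <- function(anchor, direction) {
  stopifnot(length(anchor) == 3, length(direction) == 3)
  structure(list(anchor = as.numeric(anchor),
                 direction = unname(.unit(as.numeric(direction)))),
            class = "transition_dipole")
}

# Macrocycle atoms used for the ring-plane fit: the four nitrogens plus the
# methine/ring carbons (CHA..CHD, C1A..C4D naming).
.ring_atom_pattern <- "^(N[A-D]|C(H[A-D]|[1-4][A-D]))$"

#' Least-squares plane of a chlorin macrocycle
#'
#' Fits a plane through the macrocycle nitrogen and ring-carbon atoms by
#' singular value decomposition; the normal is the singular direction of
#' smallest variance. Its sign is fixed deterministically (positive z
#' component; if zero, positive y; then x).
#'
#' @inheritParams magnesium_center
#' @return object of class `ring_plane`: `centroid` (Angstrom), unit
#'   `normal`, and `rmsd_from_plane` (Angstrom).
#' @export
ring_plane <- function(p, registry = default_registry()) {
  stopifnot(inherits(p, "pigment_instance"))
  m <- pigment_coords(p)
  m <- m[grepl(.ring_atom_pattern, rownames(m)), , drop = FALSE]
  if (nrow(m) < 3) {
    stop("degenerate geometry for ", pigment_id(p),
         ": fewer than 3 macrocycle atoms")
  }
  centroid <- colMeans(m)
  centered <- sweep(m, 2, centroid)
  sv <- svd(centered)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) {
    stop("degenerate geometry for ", pigment_id(p), ": collinear ring atoms")
  }
  normal <- sv$v[, 3]
  for (i in c(3, 2, 1)) {
    if (abs(normal[i]) > 1e-12) {
      if (normal[i] < 0) normal <- -normal
      break
    }
  }
  rmsd <- sqrt(mean((centered %*% normal)^2))
  structure(list(centroid = unname(centroid), normal = unname(normal),
                 rmsd_from_plane = rmsd),
            class = "ring_plane")
}

#' Angle between two ring planes
#'
#' `acos(|n_a . n_b|)` in degrees, folded to `[0, 90]` so the answer does not
#' depend on the arbitrary sign of either normal.
#'
#' @param a,b `ring_plane` objects.
#' @return degrees in \eqn{[0, 90]}.
#' @export
interplane_angle <- function(a, b) {
  stopifnot(inherits(a, "ring_plane"), inherits(b, "ring_plane"))
  d <- abs(sum(a$normal * b$normal))
  acos(min(max(d, 0), 1)) * 180 / pi
}

#' Minimum interatomic distance between two residues
#'
#' Closest approach over all atom pairs, with the arg-min pair reported.
#'
#' @param a,b `pigment_instance` objects (any class).
#' @return list with `distance` (Angstrom), `atom_a`, `atom_b`.
#' @export
min_interatomic_distance <- function(a, b) {
  ma <- pigment_coords(a)
  mb <- pigment_coords(b)
  if (nrow(ma) == 0 || nrow(mb) == 0) stop("residue with no atoms")
  # squared cross-distance matrix via the expansion |u-v|^2 = |u|^2+|v|^2-2u.v
  d2 <- outer(rowSums(ma^2), rowSums(mb^2), "+") - 2 * ma %*% t(mb)
  d2[d2 < 0] <- 0
  idx <- arrayInd(which.min(d2), dim(d2))
  list(distance = sqrt(d2[idx]),
       atom_a = a$atoms$atom_name[idx[1]],
       atom_b = b$atoms$atom_name[idx[2]])
}

#' Dihedral angle of four points
#'
#' Torsion about the b-c axis, in degrees in \eqn{(-180, 180]}; 180 is the
#' trans (anti-periplanar) configuration, 0 is cis.
#'
#' @param p1,p2,p3,p4 length-3 numeric points.
#' @return degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / .vnorm(b2)
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Backbone dihedrals of a polyene chain
#'
#' For each bond `i` of the conjugated backbone (between atoms `i` and
#' `i + 1` in the supplied atom-name order), computes the torsion over atoms
#' `i - 1, i, i + 1, i + 2`. Bonds whose defining quadruple crosses a missing
#' atom are skipped and listed in the `gaps` attribute.
#'
#' @param p a carotenoid `pigment_instance` (BCAR or DDX).
#' @param chain_atom_names ordered backbone atom names; defaults to the
#'   registry entry for the residue code (C1..C30).
#' @param registry a [default_registry()].
#' @return data frame with `bond_index`, `dihedral_deg`; attribute `gaps`
#'   lists missing backbone atom names.
#' @export
polyene_dihedrals <- function(p, chain_atom_names = NULL,
                              registry = default_registry()) {
  stopifnot(inherits(p, "pigment_instance"))
  if (is.null(chain_atom_names)) {
    chain_atom_names <- registry$backbone[[p$residue_name]]
    if (is.null(chain_atom_names)) {
      stop("no backbone atom order registered for residue ", p$residue_name)
    }
  }
  present <- chain_atom_names %in% p$atoms$atom_name
  chain_atom_names_present <- chain_atom_names
  # truncate the naming to the modelled extent so short chains are fine
  last <- max(c(0L, which(present)))
  chain_atom_names_present <- chain_atom_names[seq_len(last)]
  present <- present[seq_len(last)]
  if (sum(present) < 4) stop("fewer than 4 backbone atoms in ", pigment_id(p))
  coords <- pigment_coords(p, chain_atom_names_present)
  n <- length(chain_atom_names_present)
  rows <- list()
  for (i in 2:(n - 2)) {
    quad <- i + (-1L:2L)
    if (all(present[quad])) {
      xyz <- coords[chain_atom_names_present[quad], , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        bond_index = i,
        dihedral_deg = dihedral_angle(xyz[1, ], xyz[2, ], xyz[3, ], xyz[4, ])
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "gaps") <- chain_atom_names_present[!present]
  out
}

#' Classify a polyene as all-trans or cis
#'
#' A bond is cis when its backbone dihedral magnitude is at most 90 degrees
#' (the boundary maps to cis); the molecule is all-trans when no bond is cis.
#' Positions are reported in the backbone bond numbering used by
#' [polyene_dihedrals()].
#'
#' @param dihedrals data frame from [polyene_dihedrals()].
#' @return object of class `isomer_label`: `configuration` (`"all-trans"` or
#'   `"cis"`) and integer `cis_positions`.
#' @export
classify_cis_trans <- function(dihedrals) {
  if (is.null(dihedrals) || nrow(dihedrals) == 0) {
    stop("empty dihedral table")
  }
  cis <- dihedrals$bond_index[abs(dihedrals$dihedral_deg) <= 90]
  structure(
    list(configuration = if (length(cis)) "cis" else "all-trans",
         cis_positions = as.integer(cis)),
    class = "isomer_label"
  )
}

#' @export
print.isomer_label <- function(x, ...) {
  if (x$configuration == "all-trans") {
    cat("all-trans\n")
  } else {
    cat(paste0(paste(x$cis_positions, collapse = ","), "-cis\n"))
  }
  invisible(x)
}

#' Orientation factor kappa^2 of two transition dipoles
#'
#' In the point-dipole approximation,
#' \eqn{\kappa = \hat\mu_D\cdot\hat\mu_A -
#'      3(\hat\mu_D\cdot\hat R)(\hat\mu_A\cdot\hat R)}
#' with \eqn{\hat R} the unit vector between the two anchors. Returns
#' \eqn{\kappa^2 \in [0, 4]}; symmetric under donor/acceptor swap and under
#' negating either dipole. Averages to 2/3 over isotropic orientations.
#'
#' @param d,a `transition_dipole` objects with distinct anchors.
#' @return numeric in \eqn{[0, 4]}.
#' @export
kappa_squared <- function(d, a) {
  stopifnot(inherits(d, "transition_dipole"), inherits(a, "transition_dipole"))
  r <- a$anchor - d$anchor
  rn <- .vnorm(r)
  if (rn < 1e-9) stop("coincident dipole anchors")
  rhat <- r / rn
  k <- sum(d$direction * a$direction) -
    3 * sum(d$direction * rhat) * sum(a$direction * rhat)
  k * k
}
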