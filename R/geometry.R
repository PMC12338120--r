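#' Resting lengths, angles, and interaction taxonomy of the microtubule lattice
#'
#' Five interaction strength classes parameterize the coarse-grained model:
#' lateral associations (in-lattice and across the seam share a class),
#' longitudinal associations, the pitch angle along a lateral helix turn, the
#' straight longitudinal angle, and the four angles of each quadrilateral
#' lattice cell (acute and obtuse corners share the `QuadAngles` class).
#' Resting values are fixed constants of the model.
#'
#' @format Named lists `mt_resting_lengths` (nm) and `mt_resting_angles`
#'   (degrees).
#' @name mt_resting
NULL

#' @rdname mt_resting
#' @export
mt_resting_lengths <- list(LatAssoc = 5.15639, LongAssoc = 5.0)

#' @rdname mt_resting
#' @export
mt_resting_angles <- list(LatAngle = 153.023, LongAngle = 180,
                          QuadAcute = 77.0694, QuadObtuse = 102.931)

# lateral successor of lattice position (r, j): next node along the helical
# chain of lateral bonds, crossing the seam to ring r + p.  Returns NULL when
# the chain leaves the tube.
lat_succ <- function(r, j, n, k, p) {
  if (j < k - 1) return(c(r, j + 1))
  if (r + p <= n - 1) return(c(r + p, 0))
  NULL
}

#' Build the 3D lattice geometry of an offset tube
#'
#' Places each monomer `(r, j)` on a helix: angle `2*pi*j/k`, axial height
#' `r*axial + j*offset*axial/k` (so every lateral step, including the
#' seam step, rises by `offset*axial/k`).  Bonds and angles are enumerated by
#' pattern matching over the lattice: lateral/longitudinal associations
#' (= the tube-graph edge set), the pitch angle at every interior node of the
#' lateral helix, the straight longitudinal angle along each protofilament,
#' and the two acute plus two obtuse corner angles of every quadrilateral
#' cell.  Boundary rings simply omit out-of-range interactions.
#'
#' Resting values default to the model's tabulated constants
#' ([mt_resting_lengths], [mt_resting_angles]); with `resting = "geometry"`
#' each interaction's resting value is instead read off the constructed
#' coordinates, making the built structure an exact mechanical equilibrium
#' (useful as a simulation initial condition).
#'
#' @param spec A [tube_spec()].
#' @param radius_nm Helix radius in nm (default 13, i.e. 26 nm diameter).
#' @param axial_spacing_nm Axial rise per ring in nm (default 5).
#' @param resting `"table"` (tabulated constants) or `"geometry"`
#'   (per-interaction values measured from the coordinates).
#' @return An object of class `lattice_geometry` with fields `coordinates`
#'   (n x 3, nm), `bonds` (i, j, type), `angles` (i, j, k, type; vertex is the
#'   middle id), per-interaction resting vectors `bond_r0` (nm) and
#'   `angle_phi0` (degrees), and type-level `resting_lengths` /
#'   `resting_angles` maps.
#' @export
build_lattice_geometry <- function(spec, radius_nm = 13, axial_spacing_nm = 5,
                                   resting = c("table", "geometry")) {
  if (!inherits(spec, "tube_spec")) stop("spec must be a tube_spec")
  resting <- match.arg(resting)
  n <- spec$n_rings; k <- spec$k_per_turn; p <- spec$offset
  if (k != 13 && resting == "table")
    warning("tabulated resting values describe the 13-protofilament template; ",
            "constructing k = ", k, " geometry anyway")
  id <- function(rj) rj[1] * k + rj[2] + 1L
  theta <- 2 * pi / k
  rise <- p * axial_spacing_nm / k

  coords <- matrix(0, n * k, 3)
  for (r in 0:(n - 1)) for (j in 0:(k - 1)) {
    coords[id(c(r, j)), ] <- c(radius_nm * cos(j * theta),
                               radius_nm * sin(j * theta),
                               r * axial_spacing_nm + j * rise)
  }

  bonds <- list(); btype <- character(0)
  angles <- list(); atype <- character(0)
  add_bond <- function(a, b, ty) {
    bonds[[length(bonds) + 1]] <<- c(id(a), id(b)); btype[length(btype) + 1] <<- ty
  }
  add_angle <- function(a, v, b, ty) {
    angles[[length(angles) + 1]] <<- c(id(a), id(v), id(b))
    atype[length(atype) + 1] <<- ty
  }

  for (r in 0:(n - 1)) for (j in 0:(k - 1)) {
    v <- c(r, j)
    if (r < n - 1) add_bond(v, c(r + 1, j), "LongAssoc")
    s <- lat_succ(r, j, n, k, p)
    if (!is.null(s)) add_bond(v, s, "LatAssoc")
    if (r >= 1 && r < n - 1)
      add_angle(c(r - 1, j), v, c(r + 1, j), "LongAngle")
    if (!is.null(s)) {
      ss <- lat_succ(s[1], s[2], n, k, p)
      if (!is.null(ss)) add_angle(v, s, ss, "LatAngle")
      # quadrilateral cell v -- s (lateral) and v -- u (longitudinal)
      if (r < n - 1 && s[1] < n - 1) {
        u <- c(r + 1, j); su <- c(s[1] + 1, s[2])
        add_angle(s, v, u, "QuadAcute")    # at v: lateral arm tilts toward +z
        add_angle(v, s, su, "QuadObtuse")
        add_angle(v, u, su, "QuadObtuse")
        add_angle(s, su, u, "QuadAcute")
      }
    }
  }
  bonds <- do.call(rbind, bonds)
  angles <- do.call(rbind, angles)

  bond_len <- function(b) sqrt(sum((coords[b[1], ] - coords[b[2], ])^2))
  angle_deg <- function(a) {
    v1 <- coords[a[1], ] - coords[a[2], ]; v2 <- coords[a[3], ] - coords[a[2], ]
    180 / pi * acos(min(1, max(-1, sum(v1 * v2) /
                                 sqrt(sum(v1^2) * sum(v2^2)))))
  }
  bond_class <- ifelse(btype == "LatAssoc", "LatAssoc", "LongAssoc")
  if (resting == "table") {
    bond_r0 <- unlist(mt_resting_lengths)[bond_class]
    angle_phi0 <- unlist(mt_resting_angles)[atype]
    rl <- mt_resting_lengths; ra <- mt_resting_angles
  } else {
    bond_r0 <- apply(bonds, 1, bond_len)
    angle_phi0 <- apply(angles, 1, angle_deg)
    rl <- lapply(split(bond_r0, bond_class), mean)
    ra <- lapply(split(angle_phi0, atype), mean)
  }

  structure(list(spec = spec, coordinates = coords,
                 bonds = cbind(bonds, type = match(btype, names(rl))),
                 bond_type = btype, angle_type = atype,
                 angles = cbind(angles, type = match(atype, names(ra))),
                 bond_r0 = unname(bond_r0), angle_phi0 = unname(angle_phi0),
                 resting_lengths = rl, resting_angles = ra),
            class = "lattice_geometry")
}

#' @export
print.lattice_geometry <- function(x, ...) {
  cat(sprintf("lattice geometry: %d nodes, %d bonds, %d angles\n",
              nrow(x$coordinates), nrow(x$bonds), nrow(x$angles)))
  invisible(x)
}

#' Graph induced by a lattice geometry's bond list
#'
#' The bond list of [build_lattice_geometry()] induces exactly the edge set of
#' [build_tube_graph()] on the same spec (seam edges carry the spec's seam
#' weight, other bonds weight 1).
#'
#' @param geom A `lattice_geometry`.
#' @return A `lattice_graph`.
#' @export
geometry_graph <- function(geom) {
  w <- rep(1, nrow(geom$bonds))
  # seam bonds are the lateral bonds joining column k-1 to column 0
  k <- geom$spec$k_per_turn
  col0 <- (geom$bonds[, 1] - 1) %% k
  col1 <- (geom$bonds[, 2] - 1) %% k
  seam <- geom$bond_type == "LatAssoc" &
    ((col0 == k - 1 & col1 == 0) | (col1 == k - 1 & col0 == 0))
  w[seam] <- geom$spec$seam_weight
  new_lattice_graph(nrow(geom$coordinates),
                    cbind(geom$bonds[, 1], geom$bonds[, 2], w), geom$spec)
}

#' Export a lattice geometry as a LAMMPS data file
#'
#' Best-effort writer of a LAMMPS `data` file (atoms, harmonic bonds and
#' angles with type ids) for visualization or external simulation.
#'
#' @param geom A `lattice_geometry`.
#' @param file Output path.
#' @param mass Per-atom mass to declare.
#' @return Invisibly, `file`.
#' @export
write_lammps_data <- function(geom, file, mass = 1) {
  nb_types <- length(geom$resting_lengths)
  na_types <- length(geom$resting_angles)
  co <- geom$coordinates
  lines <- c(
    "LAMMPS data file (coarse-grained offset-tube lattice)", "",
    sprintf("%d atoms", nrow(co)),
    sprintf("%d bonds", nrow(geom$bonds)),
    sprintf("%d angles", nrow(geom$angles)), "",
    "1 atom types",
    sprintf("%d bond types", nb_types),
    sprintf("%d angle types", na_types), "",
    sprintf("%g %g xlo xhi", min(co[, 1]) - 10, max(co[, 1]) + 10),
    sprintf("%g %g ylo yhi", min(co[, 2]) - 10, max(co[, 2]) + 10),
    sprintf("%g %g zlo zhi", min(co[, 3]) - 10, max(co[, 3]) + 10), "",
    "Masses", "", sprintf("1 %g", mass), "",
    "Atoms", "",
    sprintf("%d 1 1 %.6f %.6f %.6f", seq_len(nrow(co)),
            co[, 1], co[, 2], co[, 3]),
    "", "Bonds", "",
    sprintf("%d %d %d %d", seq_len(nrow(geom$bonds)), geom$bonds[, "type"],
            geom$bonds[, 1], geom$bonds[, 2]),
    "", "Angles", "",
    sprintf("%d %d %d %d %d", seq_len(nrow(geom$angles)),
            geom$angles[, "type"], geom$angles[, 1], geom$angles[, 2],
            geom$angles[, 3]))
  writeLines(lines, file)
  invisible(file)
}
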