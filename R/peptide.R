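# Internal extended-peptide builder used to generate the ALA-X-ALA
# reference tripeptides for relative-accessibility normalization.
# Atoms are placed by internal coordinates (bond, angle, torsion) with the
# standard NeRF construction; sidechains use idealized bond geometry with
# extended (trans) chi angles.  Chirality is irrelevant here: surface areas
# are mirror-invariant.

# place atom D given positions of A, B, C with |CD| = bond,
# angle(B,C,D) = angle_deg, torsion(A,B,C,D) = torsion_deg
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  th <- angle_deg * pi / 180
  ph <- torsion_deg * pi / 180
  bc <- c - b
  bc <- bc / vnorm(bc)
  ab <- b - a
  n <- cross3(ab, bc)
  n <- n / vnorm(n)
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

# idealized backbone internal coordinates (Engh-Huber-like)
BB_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8)

# sidechain internal-coordinate table: ref atoms a, b, c then new atom,
# bond (A), angle (deg, b-c-new), torsion (deg, a-b-c-new).
# "-C" refers to the residue's own backbone C; chi angles are trans (180)
# with branches at +/-60; sp2 groups planar (0/180 or +/-90 ring attach).
SIDECHAIN_ICS <- list(
  ALA = list(),
  GLY = NULL,  # no CB at all
  SER = list(c("N","CA","CB","OG","1.417","110.8","180")),
  CYS = list(c("N","CA","CB","SG","1.808","113.8","180")),
  THR = list(c("N","CA","CB","OG1","1.433","109.6","180"),
             c("N","CA","CB","CG2","1.521","110.5","-60")),
  VAL = list(c("N","CA","CB","CG1","1.527","110.5","180"),
             c("N","CA","CB","CG2","1.527","110.5","-60")),
  LEU = list(c("N","CA","CB","CG","1.530","116.3","180"),
             c("CA","CB","CG","CD1","1.521","110.7","180"),
             c("CA","CB","CG","CD2","1.521","110.7","60")),
  ILE = list(c("N","CA","CB","CG1","1.530","110.4","180"),
             c("N","CA","CB","CG2","1.521","110.5","-60"),
             c("CA","CB","CG1","CD1","1.513","113.8","180")),
  MET = list(c("N","CA","CB","CG","1.520","114.1","180"),
             c("CA","CB","CG","SD","1.803","112.7","180"),
             c("CB","CG","SD","CE","1.791","100.9","180")),
  ASP = list(c("N","CA","CB","CG","1.516","112.6","180"),
             c("CA","CB","CG","OD1","1.249","118.4","0"),
             c("CA","CB","CG","OD2","1.249","118.4","180")),
  ASN = list(c("N","CA","CB","CG","1.516","112.6","180"),
             c("CA","CB","CG","OD1","1.231","120.8","0"),
             c("CA","CB","CG","ND2","1.328","116.4","180")),
  GLU = list(c("N","CA","CB","CG","1.520","114.1","180"),
             c("CA","CB","CG","CD","1.516","112.6","180"),
             c("CB","CG","CD","OE1","1.249","118.4","0"),
             c("CB","CG","CD","OE2","1.249","118.4","180")),
  GLN = list(c("N","CA","CB","CG","1.520","114.1","180"),
             c("CA","CB","CG","CD","1.516","112.6","180"),
             c("CB","CG","CD","OE1","1.231","120.8","0"),
             c("CB","CG","CD","NE2","1.328","116.4","180")),
  LYS = list(c("N","CA","CB","CG","1.520","114.1","180"),
             c("CA","CB","CG","CD","1.520","111.3","180"),
             c("CB","CG","CD","CE","1.520","111.3","180"),
             c("CG","CD","CE","NZ","1.489","111.9","180")),
  ARG = list(c("N","CA","CB","CG","1.520","114.1","180"),
             c("CA","CB","CG","CD","1.520","111.3","180"),
             c("CB","CG","CD","NE","1.461","112.0","180"),
             c("CG","CD","NE","CZ","1.329","124.6","180"),
             c("CD","NE","CZ","NH1","1.326","120.0","0"),
             c("CD","NE","CZ","NH2","1.326","120.0","180")),
  HIS = list(c("N","CA","CB","CG","1.497","113.7","180"),
             c("CA","CB","CG","ND1","1.378","122.7","90"),
             c("CA","CB","CG","CD2","1.354","131.0","-90"),
             c("CB","CG","ND1","CE1","1.321","109.0","180"),
             c("CB","CG","CD2","NE2","1.374","107.2","180")),
  PHE = list(c("N","CA","CB","CG","1.502","113.8","180"),
             c("CA","CB","CG","CD1","1.384","120.7","90"),
             c("CA","CB","CG","CD2","1.384","120.7","-90"),
             c("CB","CG","CD1","CE1","1.382","120.7","180"),
             c("CB","CG","CD2","CE2","1.382","120.7","180"),
             c("CG","CD1","CE1","CZ","1.382","120.0","0")),
  TYR = list(c("N","CA","CB","CG","1.502","113.8","180"),
             c("CA","CB","CG","CD1","1.384","120.7","90"),
             c("CA","CB","CG","CD2","1.384","120.7","-90"),
             c("CB","CG","CD1","CE1","1.382","120.7","180"),
             c("CB","CG","CD2","CE2","1.382","120.7","180"),
             c("CG","CD1","CE1","CZ","1.382","120.0","0"),
             c("CD1","CE1","CZ","OH","1.376","119.9","180")),
  TRP = list(c("N","CA","CB","CG","1.498","113.6","180"),
             c("CA","CB","CG","CD1","1.365","126.9","90"),
             c("CA","CB","CG","CD2","1.433","126.8","-90"),
             c("CB","CG","CD1","NE1","1.374","110.2","180"),
             c("CB","CG","CD2","CE2","1.409","107.2","180"),
             c("CB","CG","CD2","CE3","1.398","133.9","0"),
             c("CG","CD2","CE2","CZ2","1.394","122.4","180"),
             c("CG","CD2","CE3","CZ3","1.382","118.6","180"),
             c("CD2","CE2","CZ2","CH2","1.368","117.5","180")),
  PRO = list(c("N","CA","CB","CG","1.495","104.5","30"),
             c("CA","CB","CG","CD","1.507","106.1","-35"))
)

#' Build an extended ALA-X-ALA tripeptide
#'
#' Constructs idealized all-atom coordinates for the tripeptide Ala-X-Ala in
#' a fully extended backbone conformation (phi = psi = omega = 180 degrees)
#' with extended sidechain rotamers.  These tripeptides define the
#' reference accessible areas for relative-accessibility percentages.
#'
#' @param x central residue, 3-letter code (one of the 20 standard residues).
#' @return an atom table (same columns as the `atoms` element of a
#'   [ComplexStructure][read_pdb]).
#' @export
build_tripeptide <- function(x) {
  x <- toupper(x)
  if (!x %in% STANDARD_AA3) stop("not a standard residue: ", x)
  g <- BB_GEOM
  res_names <- c("ALA", x, "ALA")
  atoms <- list()
  add <- function(resno, resname, name, pos) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      chain_id = "A", residue_number = resno, insertion_code = "",
      residue_name = resname, atom_name = name,
      element = substr(gsub("[0-9]", "", name), 1L, 1L),
      x = pos[1L], y = pos[2L], z = pos[3L], occupancy = 1, altloc = "",
      record = "ATOM", stringsAsFactors = FALSE)
  }
  get_pos <- function(resno, name) {
    for (a in atoms)
      if (a$residue_number == resno && a$atom_name == name)
        return(c(a$x, a$y, a$z))
    stop("atom not built yet: ", resno, " ", name)
  }
  # backbone, extended
  n_prev <- c(0, 0, 0)
  ca_prev <- c(g$n_ca, 0, 0)
  c_prev <- place_atom(c(0, -1, 0), n_prev, ca_prev, g$ca_c, g$ang_n_ca_c, 60)
  add(1L, res_names[1L], "N", n_prev)
  add(1L, res_names[1L], "CA", ca_prev)
  add(1L, res_names[1L], "C", c_prev)
  for (i in 2:3) {
    n_i <- place_atom(n_prev, ca_prev, c_prev, g$c_n, g$ang_ca_c_n, 180)  # psi
    o_prev <- place_atom(n_prev, ca_prev, c_prev, g$c_o, g$ang_ca_c_o, 0)
    add(i - 1L, res_names[i - 1L], "O", o_prev)
    ca_i <- place_atom(ca_prev, c_prev, n_i, g$n_ca, g$ang_c_n_ca, 180)   # omega
    c_i <- place_atom(c_prev, n_i, ca_i, g$ca_c, g$ang_n_ca_c, 180)       # phi
    add(i, res_names[i], "N", n_i)
    add(i, res_names[i], "CA", ca_i)
    add(i, res_names[i], "C", c_i)
    n_prev <- n_i; ca_prev <- ca_i; c_prev <- c_i
  }
  # terminal carbonyl oxygen (psi of last residue taken extended)
  add(3L, res_names[3L], "O",
      place_atom(get_pos(3L, "N"), get_pos(3L, "CA"), get_pos(3L, "C"),
                 g$c_o, g$ang_ca_c_o, 0))
  # sidechains: CB for all but GLY, then the residue-specific table
  for (i in 1:3) {
    rn <- res_names[i]
    if (is.null(SIDECHAIN_ICS[[rn]])) next   # GLY
    cb <- place_atom(get_pos(i, "C"), get_pos(i, "N"), get_pos(i, "CA"),
                     1.530, 110.4, 122.6)
    add(i, rn, "CB", cb)
    for (ic in SIDECHAIN_ICS[[rn]]) {
      pos <- place_atom(get_pos(i, ic[1L]), get_pos(i, ic[2L]),
                        get_pos(i, ic[3L]), as.numeric(ic[5L]),
                        as.numeric(ic[6L]), as.numeric(ic[7L]))
      add(i, rn, ic[4L], pos)
    }
  }
  do.call(rbind, atoms)
}

# cache for reference tables keyed by probe/n_points
.reference_cache <- new.env(parent = emptyenv())

#' Reference accessible areas from extended ALA-X-ALA tripeptides
#'
#' For each standard residue X, an extended ALA-X-ALA tripeptide is built
#' with [build_tripeptide()], its solvent-accessible surface is computed
#' with [shrake_rupley()], and the summed area of the central residue's
#' atoms is recorded.  Dividing an observed residue area by this value gives
#' the relative accessibility percentage.
#'
#' @param radii a radius set, see [default_radius_set()].
#' @param probe probe radius, Angstrom.
#' @param n_points sampling points per atom.
#' @return named numeric vector of 20 reference areas (Angstrom^2), names
#'   the 3-letter residue codes.
#' @export
build_reference <- function(radii = default_radius_set(), probe = 1.4,
                            n_points = 960L) {
  key <- paste0("p", probe, "_n", n_points, "_r",
                paste(radii$by_element, collapse = "_"), "_", radii$default)
  if (!is.null(.reference_cache[[key]])) return(.reference_cache[[key]])
  out <- setNames(numeric(20L), STANDARD_AA3)
  for (x in STANDARD_AA3) {
    tri <- build_tripeptide(x)
    ar <- shrake_rupley(as.matrix(tri[, c("x", "y", "z")]),
                        atom_radii(tri, radii), probe, n_points)
    out[x] <- sum(ar[tri$residue_number == 2L])
  }
  .reference_cache[[key]] <- out
  out
}
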