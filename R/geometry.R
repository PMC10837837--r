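# Internal 3D geometry: torsion angles and internal-coordinate atom placement
# used by the peptide builder and the secondary-structure assigner.

vnorm <- function(v) sqrt(sum(v^2))
unit <- function(v) v / vnorm(v)
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Dihedral angle (degrees, in (-180, 180]) of the path a-b-c-d.
dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2))
  ang * 180 / pi
}

# Place atom D given positions A, B, C, the bond length |CD|, the bond angle
# B-C-D and the torsion A-B-C-D (degrees). Standard internal-coordinate
# (NeRF) construction.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), -sin(ang) * sin(tor))
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cbind(bc, cross3(n, bc), n)
  as.numeric(c + m %*% d2)
}

atom_coords <- function(atoms, residue_index, atom_name) {
  i <- which(atoms$residue_index == residue_index & atoms$atom_name == atom_name)
  if (length(i) == 0) return(NULL)
  c(atoms$x[i[1]], atoms$y[i[1]], atoms$z[i[1]])
}
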