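# Cartesian geometry: XYZ I/O, distances, dihedral and virtual angles,
# van der Waals contacts, Cremer-Pople ring puckering, Karplus couplings.

#' Construct a labeled Cartesian structure
#'
#' @param element character vector of element symbols.
#' @param x,y,z numeric coordinates in Angstrom.
#' @param label unique atom labels; defaults to element symbol plus the
#'   atom's (1-based) position in the file, mirroring the numbering style of
#'   crystallographic/computational reports (e.g. `"O38"`, `"H48"`).
#' @param title optional title string.
#' @return An object of class `structure3d`: a list with a data frame
#'   `atoms` (`label`, `element`, `x`, `y`, `z`) and a `title`.
#' @export
structure3d <- function(element, x, y, z, label = NULL, title = "") {
  n <- length(element)
  stopifnot(n >= 1)
  if (length(x) == 1) x <- rep(x, n)
  if (length(y) == 1) y <- rep(y, n)
  if (length(z) == 1) z <- rep(z, n)
  stopifnot(length(x) == n, length(y) == n, length(z) == n)
  if (!all(is.finite(c(x, y, z))))
    stop("all coordinates must be finite")
  if (is.null(label)) label <- paste0(element, seq_len(n))
  if (anyDuplicated(label))
    stop("atom labels must be unique")
  structure(list(
    atoms = data.frame(label = as.character(label),
                       element = as.character(element),
                       x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                       stringsAsFactors = FALSE),
    title = title), class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat("<structure3d> ", nrow(x$atoms), " atoms",
      if (nzchar(x$title)) paste0(" - ", x$title), "\n", sep = "")
  print(utils::head(x$atoms, 10))
  if (nrow(x$atoms) > 10) cat("...\n")
  invisible(x)
}

coords_of <- function(s, labels) {
  idx <- match(labels, s$atoms$label)
  if (anyNA(idx))
    stop("unknown atom label(s): ",
         paste(labels[is.na(idx)], collapse = ", "))
  as.matrix(s$atoms[idx, c("x", "y", "z")])
}

#' Read / write XYZ files
#'
#' Standard XMOL dialect: an atom-count line, a comment line, then one
#' `element x y z` record per atom.  Coordinates round-trip to 6 decimals.
#'
#' @param con file path or connection.
#' @return `read_xyz()` returns a [structure3d()]; `write_xyz()` returns the
#'   structure invisibly.
#' @export
read_xyz <- function(con) {
  lines <- readLines(con)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (length(lines) < 3) stop("truncated XYZ file")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) stop("invalid atom count line: '", lines[1], "'")
  if (length(lines) < n + 2)
    stop("XYZ count is ", n, " but only ", length(lines) - 2,
         " atom records present")
  rec <- strsplit(trimws(lines[3:(n + 2)]), "[[:space:]]+")
  bad <- which(vapply(rec, length, 1L) < 4)
  if (length(bad)) stop("malformed XYZ record at atom ", bad[1])
  el <- vapply(rec, `[[`, "", 1)
  xyz <- t(vapply(rec, function(r) {
    v <- suppressWarnings(as.numeric(r[2:4]))
    if (anyNA(v)) stop("non-numeric coordinate in XYZ record: ",
                       paste(r, collapse = " "))
    v
  }, numeric(3)))
  structure3d(el, xyz[, 1], xyz[, 2], xyz[, 3], title = trimws(lines[2]))
}

#' @param s a [structure3d()].
#' @rdname read_xyz
#' @export
write_xyz <- function(s, con) {
  stopifnot(inherits(s, "structure3d"))
  a <- s$atoms
  lines <- c(nrow(a), s$title,
             sprintf("%-2s %12.6f %12.6f %12.6f", a$element, a$x, a$y, a$z))
  writeLines(lines, con)
  invisible(s)
}

#' Interatomic distance
#'
#' @param s a [structure3d()].
#' @param i,j atom labels.
#' @return Distance in Angstrom.
#' @export
atom_distance <- function(s, i, j) {
  p <- coords_of(s, c(i, j))
  sqrt(sum((p[1, ] - p[2, ])^2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

dihedral_xyz <- function(p) {
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    stop("undefined torsion: collinear atoms")
  ang <- atan2(sum(cross3(n1, n2) * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
  deg <- ang * 180 / pi
  if (deg <= -180) deg <- deg + 360   # range (-180, 180], boundary -> +180
  if (deg > 180) deg <- deg - 360
  if (isTRUE(all.equal(deg, -180))) deg <- 180
  deg
}

#' Dihedral (torsion) angle
#'
#' Torsion a-b-c-d with the IUPAC sign convention: viewed from b towards c, a
#' clockwise rotation carrying a onto d is positive.  Range (-180, 180], with
#' the boundary assigned to +180.
#'
#' @param s a [structure3d()].
#' @param a,b,c,d atom labels.
#' @return Angle in degrees.
#' @export
dihedral <- function(s, a, b, c, d) {
  labs <- c(a, b, c, d)
  if (anyDuplicated(labs)) stop("the four atoms must be distinct")
  dihedral_xyz(coords_of(s, labs))
}

#' Planar ("virtual") angle at the middle atom
#'
#' The angle a-b-c in degrees; the three atoms need not be bonded, which is
#' what makes the angle "virtual" in conformational reports.
#'
#' @param s a [structure3d()].
#' @param a,b,c atom labels.
#' @return Angle in degrees, in \[0, 180\].
#' @export
virtual_angle <- function(s, a, b, c) {
  if (anyDuplicated(c(a, b, c))) stop("the three atoms must be distinct")
  p <- coords_of(s, c(a, b, c))
  u <- p[1, ] - p[2, ]
  v <- p[3, ] - p[2, ]
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-10 || nv < 1e-10) stop("coincident atoms: angle undefined")
  acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
}

#' van der Waals contact test
#'
#' Compares an interatomic distance against the sum of the two van der Waals
#' radii; distances below the sum flag a close contact of the kind used to
#' rationalise coplanarity of an aryl ring with a flat (thio)urea system.
#'
#' @param s a [structure3d()].
#' @param i,j atom labels.
#' @param radii radii table, a data frame like [vdw_radii()].
#' @return List with `distance`, `threshold` (both Angstrom) and `is_contact`.
#' @export
#' @examples
#' # r(H) + r(O) = 1.17 + 1.52 = 2.69 A
#' vdw_radii()
vdw_contact <- function(s, i, j, radii = vdw_radii()) {
  if (identical(i, j)) stop("need two distinct atoms")
  el <- s$atoms$element[match(c(i, j), s$atoms$label)]
  r <- radii$radius[match(el, radii$element)]
  if (anyNA(r))
    stop("element(s) missing from radii table: ",
         paste(unique(el[is.na(r)]), collapse = ", "))
  d <- atom_distance(s, i, j)
  list(distance = d, threshold = sum(r), is_contact = d < sum(r))
}

#' Cremer-Pople puckering of a six-membered ring
#'
#' Computes the puckering amplitude Q, polar angle theta and azimuthal angle
#' phi from the Cremer-Pople mean-plane construction, and classifies the ring
#' as a chair.  With the ring atoms given in sequence starting at the ring
#' oxygen (O5, C1, C2, C3, C4, C5 for a pyranose), theta < 30 degrees is
#' labeled `"4C1"`, theta > 150 degrees `"1C4"`, anything between
#' `"nonchair"`; a ring with Q below `planar_tol` is `"planar"` (theta is
#' then undefined and returned as `NA`).
#'
#' @param s a [structure3d()].
#' @param ring six atom labels, in bonding order around the ring.
#' @param planar_tol amplitude below which the ring is reported planar (A).
#' @return List with `Q` (A), `theta`, `phi` (degrees) and `label`.
#' @export
ring_pucker <- function(s, ring, planar_tol = 1e-4) {
  if (length(ring) != 6)
    stop("ring_pucker() requires exactly six ring atoms")
  p <- coords_of(s, ring)
  p <- sweep(p, 2, colMeans(p))
  j <- 0:5
  R1 <- colSums(p * sin(2 * pi * j / 6))
  R2 <- colSums(p * cos(2 * pi * j / 6))
  nrm <- cross3(R1, R2)
  nrm <- nrm / sqrt(sum(nrm^2))
  zj <- as.numeric(p %*% nrm)
  q2c <- sqrt(2 / 6) * sum(zj * cos(4 * pi * j / 6))
  q2s <- -sqrt(2 / 6) * sum(zj * sin(4 * pi * j / 6))
  q2 <- sqrt(q2c^2 + q2s^2)
  q3 <- sqrt(1 / 6) * sum(zj * (-1)^j)
  Q <- sqrt(q2^2 + q3^2)
  if (Q < planar_tol)
    return(list(Q = Q, theta = NA_real_, phi = NA_real_, label = "planar"))
  theta <- acos(max(-1, min(1, q3 / Q))) * 180 / pi
  phi <- (atan2(q2s, q2c) * 180 / pi) %% 360
  label <- if (theta < 30) "4C1" else if (theta > 150) "1C4" else "nonchair"
  list(Q = Q, theta = theta, phi = phi, label = label)
}

#' Karplus vicinal coupling and antiperiplanar inference
#'
#' `karplus_j()` evaluates the three-term Karplus relation
#' J(theta) = A cos^2(theta) + B cos(theta) + C.  The default coefficients
#' (A = 9.4, B = -1.1, C = 0.4 Hz) are a generic H-C-C-H parametrisation and
#' are heuristic: conformational work of this kind argues only qualitatively,
#' from the fact that large vicinal couplings require a torsion near 180
#' degrees.  `antiperiplanar_check()` applies that qualitative rule: an
#' observed 3J above `threshold` (default 7.5 Hz) is taken as evidence of an
#' antiperiplanar arrangement.
#'
#' @param theta torsion angle in degrees.
#' @param A,B,C Karplus coefficients in Hz.
#' @return `karplus_j()`: coupling in Hz.
#' @export
#' @examples
#' karplus_j(180)    # 10.9 Hz
#' antiperiplanar_check(9.5)
karplus_j <- function(theta, A = 9.4, B = -1.1, C = 0.4) {
  ct <- cos(theta * pi / 180)
  A * ct^2 + B * ct + C
}

#' @param j_obs observed coupling constant in Hz (non-negative).
#' @param threshold coupling above which the arrangement is called
#'   antiperiplanar, in Hz.
#' @return `antiperiplanar_check()`: logical.
#' @rdname karplus_j
#' @export
antiperiplanar_check <- function(j_obs, threshold = 7.5) {
  stopifnot(all(j_obs >= 0))
  j_obs > threshold
}
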