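# Synthetic-data generation with declared ground truth: Fourier torsion
# potentials, variable-temperature exchange spectra, and an idealised
# 4C1 pyranose fragment carrying a planar (thio)urea arm.

#' Fourier torsion potential
#'
#' V(theta) = offset + sum_i A_i * (1 - cos(n_i * (theta - phi_i))), a
#' periodic potential whose stationary points are known by construction.  A
#' single n = 1 term with amplitude B/2 gives a minimum at phi and a barrier
#' of B at phi + 180.
#'
#' @param n integer harmonic orders (>= 1).
#' @param A amplitudes in kcal/mol.
#' @param phi phase angles in degrees.
#' @param offset constant energy offset in kcal/mol.
#' @return An object of class `fourier_potential`; callable via
#'   [eval_potential()].
#' @export
#' @examples
#' pot <- fourier_potential(n = 1, A = 5)    # minimum at 0, barrier 10 at 180
#' eval_potential(pot, c(0, 180))
fourier_potential <- function(n, A, phi = 0, offset = 0) {
  if (length(n) == 0) stop("empty term list")
  stopifnot(all(n >= 1), all(n == round(n)))
  phi <- rep_len(phi, length(n))
  A <- rep_len(A, length(n))
  structure(list(n = as.integer(n), A = A, phi = phi, offset = offset),
            class = "fourier_potential")
}

#' Evaluate a Fourier potential
#'
#' @param pot a [fourier_potential()].
#' @param theta angles in degrees.
#' @return Energies in kcal/mol.
#' @export
eval_potential <- function(pot, theta) {
  th <- theta * pi / 180
  out <- rep(pot$offset, length(th))
  for (i in seq_along(pot$n))
    out <- out + pot$A[i] * (1 - cos(pot$n[i] * (th - pot$phi[i] * pi / 180)))
  out
}

potential_deriv <- function(pot, theta) {
  th <- theta * pi / 180
  out <- numeric(length(th))
  for (i in seq_along(pot$n))
    out <- out + pot$A[i] * pot$n[i] *
      sin(pot$n[i] * (th - pot$phi[i] * pi / 180))
  out  # d/d(theta_rad)
}

potential_deriv2 <- function(pot, theta) {
  th <- theta * pi / 180
  out <- numeric(length(th))
  for (i in seq_along(pot$n))
    out <- out + pot$A[i] * pot$n[i]^2 *
      cos(pot$n[i] * (th - pot$phi[i] * pi / 180))
  out
}

# analytic stationary set of a Fourier potential: roots of V' located by
# sign-change bracketing + uniroot, classified by V''
potential_truth <- function(pot) {
  grid <- seq(0, 360, by = 0.05)
  d <- potential_deriv(pot, grid)
  roots <- numeric(0)
  for (i in seq_len(length(grid) - 1)) {
    if (d[i] == 0) roots <- c(roots, grid[i])
    else if (d[i] * d[i + 1] < 0)
      roots <- c(roots, stats::uniroot(function(t) potential_deriv(pot, t),
                                       c(grid[i], grid[i + 1]),
                                       tol = 1e-10)$root)
  }
  roots <- sort(unique(round(roots %% 360, 6)))
  kind <- ifelse(potential_deriv2(pot, roots) > 0, "min", "max")
  list(minima = data.frame(angle = roots[kind == "min"],
                           energy = eval_potential(pot, roots[kind == "min"])),
       maxima = data.frame(angle = roots[kind == "max"],
                           energy = eval_potential(pot, roots[kind == "max"])))
}

#' Sample a Fourier potential onto a periodic scan grid
#'
#' Emulates a relaxed torsional scan: samples the potential on a grid
#' (default the 15-degree full-turn protocol; a 280-degree start with
#' 20-degree steps reproduces the alternative protocol), optionally adds
#' seeded Gaussian noise, and returns the profile together with the analytic
#' stationary points as declared ground truth.
#'
#' @param pot a [fourier_potential()].
#' @param start first grid angle in degrees.
#' @param step grid step in degrees (must divide 360).
#' @param direction scan-direction metadata for the profile.
#' @param noise_sd standard deviation of Gaussian energy noise (kcal/mol;
#'   0 disables noise).
#' @param seed RNG seed used when noise is enabled.
#' @return List with `profile` (a [torsion_profile()]) and `truth` (list of
#'   data frames `minima`, `maxima` with exact angles/energies).
#' @export
#' @examples
#' mk <- make_potential(fourier_potential(n = 2, A = 1))
#' mk$truth$minima
make_potential <- function(pot, start = 0, step = 15,
                           direction = c("none", "clockwise",
                                         "counterclockwise"),
                           noise_sd = 0, seed = 0) {
  direction <- match.arg(direction)
  stopifnot(inherits(pot, "fourier_potential"))
  if (360 %% step != 0) stop("step must divide 360")
  ang <- (start + step * (0:(360 / step - 1)))
  en <- eval_potential(pot, ang)
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    en <- en + stats::rnorm(length(en), sd = noise_sd)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  list(profile = torsion_profile(ang, en, direction = direction),
       truth = potential_truth(pot))
}

#' Two-well potential with a declared interconversion barrier
#'
#' Convenience constructor for an asymmetric two-well landscape of the kind
#' produced by an N-C(aryl) rotation connecting two rotamers: a global
#' minimum at 0 degrees, a secondary minimum at 180 degrees lying `delta`
#' kcal/mol higher, and two equivalent saddles such that the barrier out of
#' the global minimum is exactly `barrier` kcal/mol.  Uses
#' V = A1 (1 - cos theta) + A2 (1 - cos 2 theta) with A1 = delta / 2 and A2
#' solved in closed form from the saddle energy
#' E_saddle = A1 + 2 A2 + A1^2 / (8 A2).
#'
#' @param barrier barrier from the global minimum, kcal/mol.
#' @param delta energy of the secondary minimum, kcal/mol (>= 0, smaller
#'   than `barrier`).
#' @return A [fourier_potential()] whose declared barrier equals `barrier`.
#' @export
#' @examples
#' pot <- two_well_potential(13.5, 1.5)
#' eval_potential(pot, 180)   # 1.5
two_well_potential <- function(barrier = 13.5, delta = 1.5) {
  stopifnot(barrier > delta, delta >= 0)
  A1 <- delta / 2
  # solve 2 A2^2 - (barrier - A1) A2 + A1^2 / 8 = 0, taking the larger root
  b <- barrier - A1
  disc <- b^2 - A1^2
  A2 <- (b + sqrt(disc)) / 4
  if (4 * A2 <= A1)
    stop("no two-well solution for this barrier/delta combination")
  fourier_potential(n = c(1, 2), A = c(A1, A2))
}

#' Simulate a variable-temperature exchange series
#'
#' Generates one two-site exchange spectrum per temperature: the exchange
#' rate at each temperature follows the Eyring relation for the supplied
#' barrier, and each spectrum is a [two_site_lineshape()].  The generating
#' truth is embedded in the returned series so downstream recovery can be
#' scored.
#'
#' @param dG activation free energy in kcal/mol.
#' @param sys an [exchange_system()].
#' @param temps temperatures in K (sorted, >= 3).  The default 1 K ladder
#'   spans 223-330 K, the practical range of a chloroform-d VT experiment.
#' @param grid frequency grid in Hz; defaults to a grid generously covering
#'   both sites.
#' @param noise_sd standard deviation of Gaussian intensity noise (relative
#'   to unit maximum; 0 disables noise).
#' @param seed RNG seed used when noise is enabled.
#' @return A [vt_series()] with `true_params = list(dG, sys)`.
#' @export
#' @examples
#' sys <- exchange_system(-1081.5, 1081.5)
#' vt <- make_vt_series(11.2, sys, temps = seq(250, 290, by = 2))
make_vt_series <- function(dG, sys, temps = seq(223, 330, by = 1),
                           grid = NULL, noise_sd = 0, seed = 0) {
  stopifnot(inherits(sys, "exchange_system"))
  if (length(temps) < 3) stop("need at least 3 temperatures")
  temps <- sort(temps)
  if (is.null(grid)) {
    center <- (sys$nuA + sys$nuB) / 2
    pad <- 0.75 * max(sys$delta_nu, 1) + 20 / (pi * sys$T2) + 50
    grid <- seq(center - pad, center + pad, length.out = 4096)
  }
  ints <- t(vapply(temps, function(T)
    two_site_lineshape(sys, eyring_rate(dG, T), grid),
    numeric(length(grid))))
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    ints <- ints + matrix(stats::rnorm(length(ints), sd = noise_sd),
                          nrow = nrow(ints))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  vt_series(temps, grid, ints, true_params = list(dG = dG, sys = sys))
}

# --- fragment builder -------------------------------------------------------

# place atom D given positions A, B, C, a bond length r (C-D), the angle
# theta at C (B-C-D, degrees) and the torsion phi (A-B-C-D, degrees): the
# standard internal-to-Cartesian (NeRF) construction.
place_atom <- function(A, B, C, r, theta, phi) {
  th <- theta * pi / 180
  ph <- phi * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A; ab <- ab / sqrt(sum(ab^2))
  n <- cross3(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10) stop("cannot place atom: reference atoms are collinear")
  n <- n / nn
  m <- cross3(n, bc)
  d2 <- c(-r * cos(th), r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Specification of a synthetic pyranose-(thio)urea fragment
#'
#' @param tau1 torsion X=C-N-C2 of the sugar-side bond (degrees).
#' @param tau2 torsion X=C-N-C(ipso) of the aryl-side bond (degrees).
#' @param tau_aryl torsion C(X)-N-C(ipso)-C(ortho) of the aryl axis
#'   (degrees); the reference ortho carbon carries the Cl substituent when
#'   `ortho_restricted`.
#' @param thio logical: thiourea (C=S) instead of urea (C=O).
#' @param ortho_restricted logical: decorate the ortho positions with Cl and
#'   CH3 (the atropisomerism-inducing pattern) instead of hydrogens.
#' @return An object of class `fragment_spec`.
#' @export
fragment_spec <- function(tau1 = 0, tau2 = 0, tau_aryl = 40, thio = FALSE,
                          ortho_restricted = TRUE) {
  structure(list(tau1 = wrap180(tau1), tau2 = wrap180(tau2),
                 tau_aryl = wrap180(tau_aryl), thio = thio,
                 ortho_restricted = ortho_restricted),
            class = "fragment_spec")
}

#' Build an idealised 4C1 pyranose fragment with a (thio)urea arm
#'
#' Constructs, from ideal internal coordinates, a chair six-membered ring
#' (O5, C1...C5; a 4C1 chair by construction, with C4 above and C1 below the
#' ring mean plane), an equatorial nitrogen at C2 with its axial H-2
#' antiperiplanar to the NH, and a planar sp2 (thio)urea arm terminating in
#' an N-aryl ring, placed at the requested torsions.  Measured-back torsions
#' reproduce the specification to numerical precision, which makes the
#' fragment a ground-truth fixture for descriptor assignment and puckering
#' analysis.
#'
#' @param spec a [fragment_spec()].
#' @return A [structure3d()] with labels `O5`, `C1`-`C5`, `H2`, `N2`, `HN2`,
#'   `C7`, `O7`/`S7`, `N8`, `HN8`, `C1A`, `C2A`, `C3A`, `C5A`, `C6A` and the
#'   ortho substituents (`CL2A`, `CM6A` or `H2A`, `H6A`).
#' @export
#' @examples
#' s <- make_fragment(fragment_spec(tau1 = 0, tau2 = 0, tau_aryl = 40))
#' ring_pucker(s, c("O5", "C1", "C2", "C3", "C4", "C5"))$label
make_fragment <- function(spec) {
  stopifnot(inherits(spec, "fragment_spec"))
  L <- 1.50                       # uniform ring edge
  r0 <- sqrt(8) / 3 * L           # ring radius of the ideal chair
  z0 <- r0 / (4 * sqrt(2))        # alternating displacement
  jj <- 0:5
  # alternating z displacements signed so that C4 lies above (and C1 below)
  # the Cremer-Pople mean plane, whose normal for this atom ordering points
  # along -z: the 4C1 chair by construction
  ring <- cbind(r0 * cos(pi * jj / 3), r0 * sin(pi * jj / 3),
                z0 * (-1)^(jj + 1))
  rownames(ring) <- c("O5", "C1", "C2", "C3", "C4", "C5")
  pos <- list()
  for (nm in rownames(ring)) pos[[nm]] <- ring[nm, ]

  # substituent directions at C2 (ring neighbours C1, C3)
  u <- pos$C1 - pos$C2; u <- u / sqrt(sum(u^2))
  v <- pos$C3 - pos$C2; v <- v / sqrt(sum(v^2))
  s_dir <- -(u + v); s_dir <- s_dir / sqrt(sum(s_dir^2))
  t_dir <- cross3(u, v); t_dir <- t_dir / sqrt(sum(t_dir^2))
  ca <- sqrt(3) / 3; sa <- sqrt(6) / 3   # cos/sin 54.7356 (half-tetrahedral)
  d1 <- ca * s_dir + sa * t_dir
  d2 <- ca * s_dir - sa * t_dir
  # the axial direction is the one parallel to the ring axis (z here)
  if (abs(d1[3]) >= abs(d2[3])) { ax <- d1; eq <- d2 } else { ax <- d2; eq <- d1 }
  pos$H2 <- pos$C2 + 1.09 * ax          # axial H-2 (gluco configuration)
  pos$N2 <- pos$C2 + 1.47 * eq          # equatorial nitrogen

  X <- if (spec$thio) "S7" else "O7"
  rX <- if (spec$thio) 1.68 else 1.22
  # NH antiperiplanar to H-2 (the arrangement required by the large J(NH,H2))
  pos$HN2 <- place_atom(pos$H2, pos$C2, pos$N2, 1.01, 118, 180)
  pos$C7 <- place_atom(pos$H2, pos$C2, pos$N2, 1.37, 124, 0)
  pos[[X]] <- place_atom(pos$C2, pos$N2, pos$C7, rX, 122, spec$tau1)
  pos$N8 <- place_atom(pos$C2, pos$N2, pos$C7, 1.37, 116, spec$tau1 + 180)
  pos$HN8 <- place_atom(pos[[X]], pos$C7, pos$N8, 1.01, 118,
                        spec$tau2 + 180)
  pos$C1A <- place_atom(pos[[X]], pos$C7, pos$N8, 1.41, 126, spec$tau2)
  pos$C2A <- place_atom(pos$C7, pos$N8, pos$C1A, 1.39, 120, spec$tau_aryl)
  pos$C6A <- place_atom(pos$C7, pos$N8, pos$C1A, 1.39, 120,
                        spec$tau_aryl + 180)
  pos$C3A <- place_atom(pos$N8, pos$C1A, pos$C2A, 1.39, 120, 180)
  pos$C5A <- place_atom(pos$N8, pos$C1A, pos$C6A, 1.39, 120, 180)
  if (spec$ortho_restricted) {
    pos$CL2A <- place_atom(pos$N8, pos$C1A, pos$C2A, 1.73, 120, 0)
    pos$CM6A <- place_atom(pos$N8, pos$C1A, pos$C6A, 1.50, 120, 0)
  } else {
    pos$H2A <- place_atom(pos$N8, pos$C1A, pos$C2A, 1.08, 120, 0)
    pos$H6A <- place_atom(pos$N8, pos$C1A, pos$C6A, 1.08, 120, 0)
  }

  labels <- names(pos)
  xyz <- do.call(rbind, pos)
  element <- sub("[0-9].*$", "", labels)
  element[labels == "CL2A"] <- "Cl"
  element[labels == "CM6A"] <- "C"
  element[labels %in% c("HN2", "HN8")] <- "H"
  s <- structure3d(element, xyz[, 1], xyz[, 2], xyz[, 3], label = labels,
                   title = sprintf("synthetic %s fragment tau1=%g tau2=%g tau_aryl=%g",
                                   if (spec$thio) "thiourea" else "urea",
                                   spec$tau1, spec$tau2, spec$tau_aryl))
  dmin <- min(stats::dist(xyz))
  if (dmin < 0.7)
    stop("clashing substituent request: minimum interatomic distance ",
         round(dmin, 3), " A")
  s
}

#' Torsions and descriptors measured back from a fragment
#'
#' Measures the three defining torsions of a built fragment and assigns the
#' corresponding Z/E and M/P descriptors, the round-trip companion of
#' [make_fragment()].
#'
#' @param s a structure from [make_fragment()].
#' @return List with `tau1`, `tau2`, `tau_aryl`, `ze1`, `ze2`, `helicity`
#'   and `label`.
#' @export
fragment_descriptors <- function(s) {
  X <- if ("S7" %in% s$atoms$label) "S7" else "O7"
  tau1 <- dihedral(s, "C2", "N2", "C7", X)
  tau2 <- dihedral(s, X, "C7", "N8", "C1A")
  tau_aryl <- dihedral(s, "C7", "N8", "C1A", "C2A")
  ze1 <- assign_ze(tau1)
  ze2 <- assign_ze(tau2)
  hel <- tryCatch(assign_helicity(tau_aryl), error = function(e) NA_character_)
  list(tau1 = tau1, tau2 = tau2, tau_aryl = tau_aryl,
       ze1 = ze1, ze2 = ze2, helicity = hel,
       label = paste0(ze1, ze2, if (!is.na(hel)) hel else ""))
}
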