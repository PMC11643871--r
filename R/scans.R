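# Periodic torsional-profile analysis: loading scan tables, locating
# stationary points (grid or periodic-spline), interconversion barriers,
# clockwise/counterclockwise consistency, and labeled minimum-to-minimum
# pathways.

#' Construct a periodic torsion profile
#'
#' Angles are wrapped into \[0, 360) and sorted; a profile must sample at
#' least 8 distinct angles of one 360-degree period.  Energies are stored
#' relative to the sampled minimum, in kcal/mol.
#'
#' @param angle dihedral angles in degrees (any branch; wrapped mod 360).
#' @param energy energies; see `unit`.
#' @param unit `"kcal/mol"` or `"hartree"` (converted by 627.5095).
#' @param direction scan direction metadata: `"none"`, `"clockwise"` or
#'   `"counterclockwise"`.
#' @return An object of class `torsion_profile`: list with `angle`, `energy`
#'   (kcal/mol, min 0) and `direction`.
#' @export
torsion_profile <- function(angle, energy, unit = c("kcal/mol", "hartree"),
                            direction = c("none", "clockwise",
                                          "counterclockwise")) {
  unit <- match.arg(unit)
  direction <- match.arg(direction)
  stopifnot(length(angle) == length(energy))
  if (length(angle) < 8)
    stop("a torsion profile needs at least 8 grid points")
  a <- angle %% 360
  if (anyDuplicated(round(a, 6)))
    stop("duplicate angles after wrapping into one period")
  o <- order(a)
  e <- if (unit == "hartree") energy * .hartree_kcal else energy
  e <- e - min(e)
  structure(list(angle = a[o], energy = e[o], direction = direction),
            class = "torsion_profile")
}

#' @export
print.torsion_profile <- function(x, ...) {
  cat("<torsion_profile> ", length(x$angle), " points, direction ",
      x$direction, "\n", sep = "")
  print(utils::head(data.frame(angle = x$angle, energy = x$energy), 8))
  if (length(x$angle) > 8) cat("...\n")
  invisible(x)
}

#' Load a torsion profile from a two-column CSV
#'
#' Column 1 is the dihedral in degrees, column 2 the energy.  The energy unit
#' is taken from the header when it names one (a column header containing
#' "hartree" triggers conversion), can be forced via `unit`, and under
#' `unit = "auto"` falls back to treating large negative absolute energies
#' (below -100) as hartree.  Energies are re-zeroed to the minimum; angles
#' spanning more than one period (e.g. 280 to 620 degrees) are wrapped.
#'
#' @param path CSV file path.
#' @param unit `"auto"`, `"kcal/mol"` or `"hartree"`.
#' @param direction scan direction metadata (see [torsion_profile()]).
#' @return A [torsion_profile()].
#' @export
load_profile <- function(path, unit = "auto",
                         direction = c("none", "clockwise",
                                       "counterclockwise")) {
  direction <- match.arg(direction)
  first <- readLines(path, n = 1)
  has_header <- !grepl("^[-0-9.eE+, \t]*$", first)
  df <- utils::read.csv(path, header = has_header,
                        stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected a two-column (angle, energy) CSV")
  ang <- as.numeric(df[[1]])
  en <- as.numeric(df[[2]])
  if (anyNA(ang) || anyNA(en)) stop("non-numeric entries in scan table")
  if (unit == "auto") {
    unit <- if (has_header && grepl("hartree", names(df)[2],
                                    ignore.case = TRUE)) "hartree"
            else if (all(en < -100)) "hartree"
            else "kcal/mol"
  }
  torsion_profile(ang, en, unit = unit, direction = direction)
}

#' Write a torsion profile to CSV
#'
#' @param p a [torsion_profile()].
#' @param path output CSV path.
#' @return The profile, invisibly.
#' @export
write_profile <- function(p, path) {
  utils::write.csv(data.frame(angle_deg = p$angle, energy_kcal = p$energy),
                   path, row.names = FALSE)
  invisible(p)
}

periodic_interpolant <- function(p) {
  stats::splinefun(c(p$angle, p$angle[1] + 360), c(p$energy, p$energy[1]),
                   method = "periodic")
}

# cyclic local extrema of a sampled series; plateau runs collapse to their
# arc midpoint. Returns list(minima=, maxima=) of data.frames(angle, energy).
grid_extrema <- function(angle, energy, tol = 1e-10) {
  n <- length(angle)
  # compress consecutive equal-energy runs (cyclically) into plateau runs
  runs <- list()
  idx <- 1
  while (idx <= n) {
    j <- idx
    while (j < n && abs(energy[j + 1] - energy[idx]) < tol) j <- j + 1
    runs[[length(runs) + 1]] <- idx:j
    idx <- j + 1
  }
  # merge wrap-around run
  if (length(runs) > 1 &&
      abs(energy[runs[[1]][1]] - energy[runs[[length(runs)]][1]]) < tol) {
    runs[[1]] <- c(runs[[length(runs)]], runs[[1]])
    runs[[length(runs)]] <- NULL
  }
  if (length(runs) < 2) stop("degenerate profile: no distinct extrema")
  minima <- data.frame(angle = numeric(0), energy = numeric(0))
  maxima <- data.frame(angle = numeric(0), energy = numeric(0))
  m <- length(runs)
  for (k in seq_len(m)) {
    prev <- runs[[if (k == 1) m else k - 1]]
    nxt <- runs[[if (k == m) 1 else k + 1]]
    e0 <- energy[runs[[k]][1]]
    ep <- energy[prev[1]]; en <- energy[nxt[1]]
    ang <- angle[runs[[k]]]
    # arc midpoint of the run (careful with wrap)
    if (length(ang) > 1 && (max(ang) - min(ang)) > 180) {
      ang2 <- ifelse(ang < 180, ang + 360, ang)
      mid <- mean(range(ang2)) %% 360
    } else mid <- mean(range(ang))
    if (e0 < ep && e0 < en)
      minima <- rbind(minima, data.frame(angle = mid, energy = e0))
    else if (e0 > ep && e0 > en)
      maxima <- rbind(maxima, data.frame(angle = mid, energy = e0))
  }
  if (nrow(minima) == 0 || nrow(maxima) == 0)
    stop("degenerate profile: no distinct extrema")
  list(minima = minima, maxima = maxima)
}

#' Locate stationary points of a periodic torsion profile
#'
#' `method = "grid"` reports cyclic local extrema of the sampled points (ties
#' across a plateau collapse to the arc midpoint), which reproduces a scan
#' table exactly.  `method = "spline"` refines positions on a periodic cubic
#' spline interpolant evaluated on a 0.01-degree grid and polished with
#' [stats::optimize()], recovering sub-grid extremum positions.  Minima and
#' maxima always alternate around the cycle and are equal in number.
#'
#' @param p a [torsion_profile()].
#' @param method `"spline"` (default) or `"grid"`.
#' @return An object of class `stationary_set`: list with data frames
#'   `minima` and `maxima` (columns `angle`, `energy`), and `method`.
#' @export
stationary_points <- function(p, method = c("spline", "grid")) {
  method <- match.arg(method)
  stopifnot(inherits(p, "torsion_profile"))
  if (diff(range(p$energy)) < 1e-12)
    stop("degenerate profile: energies are constant")
  if (method == "grid") {
    ex <- grid_extrema(p$angle, p$energy)
  } else {
    f <- periodic_interpolant(p)
    grid <- seq(0, 360 - 0.01, by = 0.01)
    e <- f(grid)
    ex <- grid_extrema(grid, e, tol = 0)
    polish <- function(df, maximum) {
      df$angle <- vapply(df$angle, function(a) {
        opt <- stats::optimize(f, interval = c(a - 0.02, a + 0.02),
                               maximum = maximum, tol = 1e-8)
        round(if (maximum) opt$maximum else opt$minimum, 6) %% 360
      }, numeric(1))
      df$energy <- f(df$angle)
      df
    }
    ex$minima <- polish(ex$minima, FALSE)
    ex$maxima <- polish(ex$maxima, TRUE)
  }
  ex$minima <- ex$minima[order(ex$minima$angle), , drop = FALSE]
  ex$maxima <- ex$maxima[order(ex$maxima$angle), , drop = FALSE]
  rownames(ex$minima) <- rownames(ex$maxima) <- NULL
  if (nrow(ex$minima) != nrow(ex$maxima))
    stop("internal error: extrema do not alternate")   # nocov
  structure(list(minima = ex$minima, maxima = ex$maxima, method = method),
            class = "stationary_set")
}

#' @export
print.stationary_set <- function(x, ...) {
  cat("<stationary_set> (", x$method, ") ", nrow(x$minima), " minima / ",
      nrow(x$maxima), " maxima\n", sep = "")
  cat("minima:\n"); print(round(x$minima, 4))
  cat("maxima:\n"); print(round(x$maxima, 4))
  invisible(x)
}

match_minimum <- function(sp, angle, tol) {
  d <- abs(((sp$minima$angle - angle + 180) %% 360) - 180)
  i <- which.min(d)
  if (d[i] > tol)
    stop("angle ", angle, " is not an identified minimum (nearest is ",
         round(sp$minima$angle[i], 2), ")")
  i
}

arc_max <- function(f_angle, f_energy, from, to, decreasing = FALSE) {
  # max energy over the directed arc from 'from' to 'to'
  if (decreasing) {
    rel_grid <- (from - f_angle) %% 360
    rel_to <- (from - to) %% 360
  } else {
    rel_grid <- (f_angle - from) %% 360
    rel_to <- (to - from) %% 360
  }
  if (rel_to == 0) rel_to <- 360
  sel <- rel_grid <= rel_to
  max(f_energy[sel])
}

#' Interconversion barrier between two minima
#'
#' The barrier is the highest energy along the directed arc from `from` to
#' `to`, minus the energy at `from`.  With `direction = "none"` the reported
#' barrier is the lower of the two directed values, i.e. the easiest path.
#' Angles increase counterclockwise: a `"counterclockwise"` path follows
#' increasing angle, a `"clockwise"` path decreasing angle.
#'
#' @param p a [torsion_profile()].
#' @param from,to angles (degrees) of two identified minima.
#' @param direction `"none"`, `"clockwise"` or `"counterclockwise"`.
#' @param method extremum method passed to [stationary_points()].
#' @param match_tol how far (degrees) `from`/`to` may sit from an identified
#'   minimum.
#' @return Barrier in kcal/mol.
#' @export
barrier <- function(p, from, to, direction = c("none", "clockwise",
                                               "counterclockwise"),
                    method = c("spline", "grid"), match_tol = 2) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  sp <- stationary_points(p, method = method)
  i <- match_minimum(sp, from, match_tol)
  j <- match_minimum(sp, to, match_tol)
  if (i == j) stop("'from' and 'to' refer to the same minimum")
  a_from <- sp$minima$angle[i]
  a_to <- sp$minima$angle[j]
  e_from <- sp$minima$energy[i]
  if (method == "grid") {
    ga <- p$angle; ge <- p$energy
  } else {
    f <- periodic_interpolant(p)
    ga <- seq(0, 360 - 0.01, by = 0.01)
    ge <- f(ga)
  }
  b_ccw <- arc_max(ga, ge, a_from, a_to, decreasing = FALSE) - e_from
  b_cw <- arc_max(ga, ge, a_from, a_to, decreasing = TRUE) - e_from
  switch(direction,
         none = min(b_ccw, b_cw),
         clockwise = b_cw,
         counterclockwise = b_ccw)
}

#' Consistency of clockwise and counterclockwise scans
#'
#' Compares two scans of the same torsion recorded in opposite directions.
#' After wrapping, the grids must coincide; the per-angle absolute energy
#' differences are reported together with a "coincidental" verdict when the
#' largest deviation stays below `tol` (hysteresis-free scan).
#'
#' @param p_cw,p_ccw two [torsion_profile()]s on the same wrapped grid.
#' @param tol verdict tolerance in kcal/mol.
#' @return List with `max_dev`, `deviations` (data frame `angle`, `dev`) and
#'   logical `coincidental`.
#' @export
direction_consistency <- function(p_cw, p_ccw, tol = 0.5) {
  if (length(p_cw$angle) != length(p_ccw$angle) ||
      max(abs(p_cw$angle - p_ccw$angle)) > 1e-6)
    stop("incompatible grids: the two scans sample different angles")
  dev <- abs(p_cw$energy - p_ccw$energy)
  list(max_dev = max(dev),
       deviations = data.frame(angle = p_cw$angle, dev = dev),
       coincidental = max(dev) < tol)
}

#' Labeled minimum-to-minimum pathway analysis
#'
#' Assigns a conformer label to every minimum of the profile and reports, for
#' each minimum, the neighbouring minimum it interconverts with across its
#' lowest adjacent saddle, together with that barrier.  This is the analysis
#' that turns a one-dimensional scan into statements of the kind "the ZZP
#' rotamer transforms into ZEP rather than ZZM".
#'
#' @param p a [torsion_profile()].
#' @param labeler function mapping an angle (degrees) to a conformer label.
#' @param method extremum method passed to [stationary_points()].
#' @return Data frame with one row per minimum: `from_label`, `from_angle`,
#'   `to_label`, `to_angle`, `saddle_angle`, `barrier` (kcal/mol).  Zero rows
#'   for a single-well profile.
#' @export
label_path <- function(p, labeler, method = c("spline", "grid")) {
  method <- match.arg(method)
  sp <- stationary_points(p, method = method)
  mins <- sp$minima
  maxs <- sp$maxima
  n <- nrow(mins)
  if (n < 2)
    return(data.frame(from_label = character(0), from_angle = numeric(0),
                      to_label = character(0), to_angle = numeric(0),
                      saddle_angle = numeric(0), barrier = numeric(0)))
  labels <- vapply(mins$angle, function(a) as.character(labeler(a)), "")
  out <- lapply(seq_len(n), function(i) {
    a <- mins$angle[i]
    # adjacent saddles: nearest maxima ccw and cw
    d_ccw <- (maxs$angle - a) %% 360
    d_cw <- (a - maxs$angle) %% 360
    s_ccw <- which.min(replace(d_ccw, d_ccw == 0, Inf))
    s_cw <- which.min(replace(d_cw, d_cw == 0, Inf))
    if (maxs$energy[s_ccw] <= maxs$energy[s_cw]) {
      saddle <- s_ccw; partner <- if (i == n) 1 else i + 1
    } else {
      saddle <- s_cw; partner <- if (i == 1) n else i - 1
    }
    data.frame(from_label = labels[i], from_angle = a,
               to_label = labels[partner], to_angle = mins$angle[partner],
               saddle_angle = maxs$angle[saddle],
               barrier = maxs$energy[saddle] - mins$energy[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
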