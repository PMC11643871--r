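cos2_profile <- function(step = 15) {
  ang <- seq(0, 360 - step, by = step)
  torsion_profile(ang, 1 - cos(2 * ang * pi / 180))
}

test_that("profiles load from CSV with unit handling and wrapping", {
  p <- withr::local_tempfile(fileext = ".csv")
  ang <- seq(0, 345, by = 15)
  write.csv(data.frame(angle_deg = ang,
                       energy_kcal = 1 - cos(ang * pi / 180)),
            p, row.names = FALSE)
  prof <- load_profile(p)
  expect_length(prof$angle, 24)
  expect_equal(min(prof$energy), 0)

  # hartree column auto-converted via the header name
  write.csv(data.frame(angle = ang,
                       energy_hartree = -1000 + (1 - cos(ang * pi / 180)) /
                         physical_constants()$hartree_kcal),
            p, row.names = FALSE)
  prof_h <- load_profile(p)
  expect_equal(max(prof_h$energy), 2, tolerance = 1e-6)

  # a 280 -> 620 grid wraps into one period
  ang2 <- seq(280, 620, by = 20)[-18]   # drop 620 == 280 duplicate
  write.csv(data.frame(a = ang2, e = 1 - cos(ang2 * pi / 180)),
            p, row.names = FALSE)
  prof_w <- load_profile(p)
  expect_true(all(prof_w$angle >= 0 & prof_w$angle < 360))
  expect_length(prof_w$angle, 17)

  write.csv(data.frame(a = c(ang, 0), e = c(ang, 0)), p, row.names = FALSE)
  expect_error(load_profile(p), "duplicate")
})

test_that("stationary points of 1 - cos(2 theta) sit at the analytic extrema", {
  prof <- cos2_profile()
  for (m in c("grid", "spline")) {
    sp <- stationary_points(prof, method = m)
    expect_equal(sp$minima$angle, c(0, 180), tolerance = 1e-4)
    expect_equal(sp$maxima$angle, c(90, 270), tolerance = 1e-4)
    expect_equal(nrow(sp$minima), nrow(sp$maxima))
  }
})

test_that("degenerate and sawtooth profiles are handled", {
  flat <- torsion_profile(seq(0, 315, by = 45), rep(1, 8))
  expect_error(stationary_points(flat), "degenerate")
  # monotone ramp glued periodically: exactly one minimum and one maximum
  saw <- torsion_profile(seq(0, 315, by = 45), 0:7)
  sp <- stationary_points(saw, method = "grid")
  expect_equal(nrow(sp$minima), 1)
  expect_equal(nrow(sp$maxima), 1)
  expect_equal(sp$minima$angle, 0)
  expect_equal(sp$maxima$angle, 315)
})

test_that("synthetic Fourier extrema are recovered within method tolerances", {
  set.seed(2)
  pots <- list(
    fourier_potential(n = 1, A = 5),
    fourier_potential(n = 2, A = 1.2, phi = 10),
    fourier_potential(n = c(1, 2, 3), A = c(1.5, 4, 0.6), phi = c(0, 15, 40)),
    two_well_potential(13.5, 1.5))
  for (pot in pots) {
    mk <- make_potential(pot, step = 15)
    truth <- mk$truth
    for (m in c("grid", "spline")) {
      tol <- if (m == "grid") 7.5 else 1
      sp <- stationary_points(mk$profile, method = m)
      expect_equal(nrow(sp$minima), nrow(truth$minima))
      expect_equal(nrow(sp$maxima), nrow(truth$maxima))
      for (k in c("minima", "maxima")) {
        for (a in truth[[k]]$angle) {
          dev <- min(abs(((sp[[k]]$angle - a + 180) %% 360) - 180))
          expect_lt(dev, tol)
        }
      }
    }
  }
})

test_that("barriers match closed forms and the path-difference identity", {
  # V = (B/2)(1 - cos theta): barrier from 0 across 180 equals B
  B <- 7
  prof <- torsion_profile(seq(0, 345, by = 15),
                          (B / 2) * (1 - cos(seq(0, 345, by = 15) * pi / 180)))
  # single-well profile: 0 is the only minimum, 180 the only maximum,
  # so measure the directed arc to the maximum via the two-well instead
  tw <- make_potential(two_well_potential(10, 2), step = 15)
  b_fwd <- barrier(tw$profile, 0, 180)
  b_rev <- barrier(tw$profile, 180, 0)
  expect_equal(b_fwd - b_rev,
               eval_potential(two_well_potential(10, 2), 180) -
                 eval_potential(two_well_potential(10, 2), 0),
               tolerance = 1e-3)
  expect_equal(b_fwd, 10, tolerance = 0.05)
  # directed barriers: clockwise and counterclockwise arcs agree here by
  # symmetry of the two-well potential
  expect_equal(barrier(tw$profile, 0, 180, direction = "clockwise"),
               barrier(tw$profile, 0, 180, direction = "counterclockwise"),
               tolerance = 0.05)
  expect_error(barrier(tw$profile, 0, 90), "not an identified minimum")
  expect_equal(nrow(stationary_points(prof)$minima), 1)
})

test_that("barriers are invariant to energy offset and origin rotation", {
  tw <- make_potential(two_well_potential(12, 1), step = 15)
  b0 <- barrier(tw$profile, 0, 180)
  shifted <- torsion_profile(tw$profile$angle, tw$profile$energy + 5)
  expect_equal(barrier(shifted, 0, 180), b0, tolerance = 1e-9)
  rotated <- torsion_profile((tw$profile$angle + 40) %% 360,
                             tw$profile$energy)
  expect_equal(barrier(rotated, 40, 220), b0, tolerance = 1e-9)
})

test_that("direction consistency compares wrapped grids", {
  ang <- seq(0, 345, by = 15)
  e <- 1 - cos(2 * ang * pi / 180)
  p1 <- torsion_profile(ang, e, direction = "clockwise")
  p2 <- torsion_profile(ang, e, direction = "counterclockwise")
  res <- direction_consistency(p1, p2)
  expect_equal(res$max_dev, 0)
  expect_true(res$coincidental)

  # a uniform 0.3 kcal/mol offset disappears on re-zeroing only if constant;
  # inject it after construction to emulate scan hysteresis
  p3 <- p2
  p3$energy <- p3$energy + 0.3
  res3 <- direction_consistency(p1, p3)
  expect_equal(res3$max_dev, 0.3)
  expect_true(res3$coincidental)

  # hysteresis at a single angle is flagged there
  p4 <- p2
  i <- 7
  p4$energy[i] <- p4$energy[i] + 1.1
  res4 <- direction_consistency(p1, p4)
  expect_false(res4$coincidental)
  expect_equal(res4$deviations$angle[which.max(res4$deviations$dev)], ang[i])

  p5 <- torsion_profile(seq(0, 350, by = 10), 1 - cos(2 * seq(0, 350, 10) * pi / 180))
  expect_error(direction_consistency(p1, p5), "incompatible")
})

test_that("label_path reports minimum-to-minimum transitions over low saddles", {
  # two-well landscape labeled like the rotamer pathway: the global minimum
  # interconverts with the secondary minimum, not with its mirror image
  mk <- make_potential(two_well_potential(13.5, 1.5), step = 15)
  labeler <- function(a) if (abs(((a + 180) %% 360) - 180) < 90) "ZZP" else "ZEP"
  path <- label_path(mk$profile, labeler)
  expect_equal(nrow(path), 2)
  from_zzp <- path[path$from_label == "ZZP", ]
  expect_equal(from_zzp$to_label, "ZEP")
  expect_equal(from_zzp$barrier, 13.5, tolerance = 0.05)

  # single well: no transitions
  single <- make_potential(fourier_potential(1, 4), step = 15)
  expect_equal(nrow(label_path(single$profile, function(a) "ZZ")), 0)

  # symmetric double well: both directed barriers equal
  sym <- make_potential(fourier_potential(2, 3), step = 15)
  path_sym <- label_path(sym$profile, function(a) sprintf("m%.0f", a))
  expect_equal(nrow(path_sym), 2)
  expect_equal(diff(path_sym$barrier), 0, tolerance = 1e-6)
})
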