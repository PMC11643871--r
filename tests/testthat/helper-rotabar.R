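# Shared test helpers: random rigid motions, random formulas, simple peak
# counting independent of the package's own detector.

random_rigid_motion <- function() {
  # uniform-ish random rotation from a QR decomposition + random translation
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t_vec <- stats::rnorm(3, sd = 5)
  list(R = R, t = t_vec)
}

apply_rigid <- function(s, motion) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(motion$R)
  xyz <- sweep(xyz, 2, motion$t, "+")
  structure3d(s$atoms$element, xyz[, 1], xyz[, 2], xyz[, 3],
              label = s$atoms$label, title = s$title)
}

random_formula <- function() {
  els <- sample(c("C", "H", "N", "O", "S", "Cl", "F", "Na"),
                sample(2:5, 1))
  counts <- sample(1:30, length(els), replace = TRUE)
  names(counts) <- els
  molecular_formula(counts)
}

# count strict local maxima of an intensity vector (independent of the
# package's prominence-based peak finder)
count_modes <- function(y) {
  n <- length(y)
  sum(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n])
}

# temperature at which the Eyring rate reaches the coalescence rate
true_coalescence_T <- function(dG, delta_nu) {
  stats::uniroot(function(T) eyring_rate(dG, T) - rate_at_coalescence(delta_nu),
                 c(100, 600), tol = 1e-6)$root
}
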