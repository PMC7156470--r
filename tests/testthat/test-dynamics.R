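test_that("screened pair potential reproduces hand-computed values", {
  # two +2 ions at the disulfide bond length, unscreened
  expect_equal(screened_pair_potential(2, 2, 2.08, 0), 4 * 14.3996 / 2.08,
               tolerance = 1e-12)
  expect_equal(screened_pair_potential(2, 2, 2.08, 0), 27.692, tolerance = 1e-4)
  # at r = 1/kappa the potential is the unscreened value / e
  expect_equal(screened_pair_potential(1, 1, 2, 0.5),
               screened_pair_potential(1, 1, 2, 0) * exp(-1))
  expect_equal(screened_pair_potential(0, 3, 1.5, 0.2), 0)
  expect_error(screened_pair_potential(1, 1, 0, 0))
})

test_that("collision potential is a finite wall inside the contact radius", {
  expect_equal(collision_potential(2.0, r_e = 2.0), 0)      # zero at r_e
  expect_equal(collision_potential(3.5, r_e = 2.0), 0)      # zero beyond
  # continuity at the boundary
  expect_lt(collision_potential(2.0 - 1e-8, r_e = 2.0), 1e-10)
  # direct substitution at r -> 0
  D <- 27.2; a <- 2; re <- 2.0
  expect_equal(collision_potential(0, D, a, re), D * (1 - exp(a * re))^2)
  # monotone decreasing on (0, r_e)
  r <- seq(0.1, 1.99, length.out = 50)
  expect_true(all(diff(collision_potential(r, D, a, re)) < 0))
})

test_that("total force is minus the gradient of the total potential", {
  cell <- generate_supercell(edge_length = 10, target_atom_count = 10,
                             sulfur_fraction = 0.2, seed = 3, free_radius = 5)
  set.seed(4)
  cell$atoms$charge <- sample(0:3, 10, replace = TRUE)
  # keep the motif carbons neutral: their bonded S sits exactly at the
  # contact radius, where the wall's curvature kink spoils a finite
  # difference (the analytic force itself is well defined there)
  cell$atoms$charge[c(1, 4)] <- 0
  params <- pair_potential_params()
  config <- dynamics_config()
  for (kappa in c(0, 0.6)) {
    FF <- total_force(cell, kappa, params, config)
    eps <- 1e-5
    for (i in c(1, 4, 8)) {
      for (d in c("x", "y", "z")) {
        cp <- cell; cm <- cell
        cp$atoms[i, d] <- cp$atoms[i, d] + eps
        cm$atoms[i, d] <- cm$atoms[i, d] - eps
        fd <- -(plasmaMD:::total_potential(cp, kappa, params, config) -
                plasmaMD:::total_potential(cm, kappa, params, config)) / (2 * eps)
        ref <- FF[i, match(d, c("x", "y", "z"))]
        expect_lt(abs(fd - ref), 1e-6 * max(1, abs(ref)))
      }
    }
  }
})

test_that("forces obey Newton's third law and screening never strengthens them", {
  cell <- two_sulfur_cell(2.08)
  cell$atoms$charge <- c(2, 2)
  F0 <- total_force(cell, 0)
  expect_equal(F0[1, ], -F0[2, ], tolerance = 1e-12)
  # |screened| <= |unscreened| for the same geometry
  for (kappa in c(0.2, 1, 3)) {
    Fk <- total_force(cell, kappa)
    expect_lte(sqrt(sum(Fk[1, ]^2)), sqrt(sum(F0[1, ]^2)))
  }
  # overlapping atoms are refused by name
  bad <- cell
  bad$atoms[2, c("x", "y", "z")] <- bad$atoms[1, c("x", "y", "z")]
  expect_error(total_force(bad, 0), "overlapping")
})

test_that("strong screening reduces the periodic sum to the nearest image", {
  # two ions in a periodic box under heavy screening: the periodic force
  # equals the isolated-pair force because farther images are cut off
  cell <- generate_supercell(edge_length = 14, target_atom_count = 4,
                             sulfur_fraction = 0.05, seed = 1)
  cell$atoms$charge <- c(0, 3, 3, 0)
  kappa <- 2.5
  Fper <- total_force(cell, kappa)
  iso <- cell
  iso$periodic <- FALSE
  Fiso <- total_force(iso, kappa)
  expect_equal(Fper[2, ], Fiso[2, ], tolerance = 1e-9)
})

test_that("compiled force kernel agrees with the R reference forces", {
  cell <- generate_supercell(edge_length = 14, target_atom_count = 40,
                             sulfur_fraction = 0.05, seed = 8, free_radius = 7)
  set.seed(9)
  cell$atoms$charge <- sample(0:2, 40, replace = TRUE)
  kappa <- 0.8
  # a zero-length integration step exposes the kernel forces via the
  # velocity update of a single tiny step
  dtt <- 1e-6
  tr <- integrate_ions(cell, cell$atoms$charge, kappa = kappa,
                       config = dynamics_config(dt = dtt, t_end = dtt,
                                                rcut_max = 50))
  vel <- as.matrix(tr$final$atoms[, c("vx", "vy", "vz")])
  acc_ref <- total_force(cell, kappa, config = dynamics_config(rcut_max = 50)) /
    103.6427 / cell$atoms$mass
  mob <- cell$atoms$mobile
  expect_equal(unname(vel[mob, ]), unname(acc_ref[mob, ] * dtt),
               tolerance = 1e-4)
  expect_equal(unname(vel[!mob, ]),
               matrix(0, sum(!mob), 3))       # frozen atoms never move
})

test_that("two-body Coulomb explosion matches the closed-form energy", {
  cell <- two_sulfur_cell(2.08)
  params <- pair_potential_params(collision = FALSE)
  tr <- integrate_ions(cell, c(1, 1), kappa = 0, params = params,
                       config = dynamics_config(dt = 0.01, t_end = 3000,
                                                out_stride = 50))
  n <- length(tr$times)
  E_closed <- 14.3996 / 2.08                 # 6.923 eV
  # asymptotic kinetic energy: all potential energy converted
  expect_equal(tr$kinetic[n] + tr$potential[n], E_closed, tolerance = 1e-3)
  expect_gt(tr$kinetic[n] / E_closed, 0.97)
  # energy conservation along the whole trajectory at dt = 0.01
  drift <- max(abs(tr$kinetic + tr$potential - E_closed)) / E_closed
  expect_lt(drift, 1e-3)
  # screening strictly weakens the explosion
  trs <- integrate_ions(cell, c(1, 1), kappa = 0.5, params = params,
                        config = dynamics_config(dt = 0.01, t_end = 3000,
                                                 out_stride = 50))
  expect_lt(trs$kinetic[n], tr$kinetic[n])
})

test_that("RK4 converges at fourth order in the step size", {
  cell <- two_sulfur_cell(1.2)               # strong forces, visible error
  params <- pair_potential_params(collision = FALSE)
  ss_end <- vapply(c(0.8, 0.4, 0.0125), function(dd) {
    tr <- integrate_ions(cell, c(3, 3), kappa = 0, params = params,
                         config = dynamics_config(dt = dd, t_end = 100,
                                                  out_stride = 100))
    tr$ss[length(tr$ss)]
  }, numeric(1))
  err <- abs(ss_end[1:2] - ss_end[3])        # against a 32x finer reference
  # halving dt shrinks the endpoint error ~16x (4th order; allow 10-40x)
  expect_gt(err[1] / err[2], 10)
  expect_lt(err[1] / err[2], 40)
})

test_that("two-body trajectory matches an adaptive reference integration", {
  skip_if_not_installed("deSolve")
  # reduced one-dimensional problem: mu r'' = ke q1 q2 / r^2
  mu <- 32.06 / 2
  ke <- 14.3996
  deriv <- function(t, y, parms)
    list(c(y[2], ke * 4 / y[1]^2 / mu / 103.6427))
  times <- seq(0, 100, by = 1)
  ref <- deSolve::lsoda(c(r = 2.08, v = 0), times, deriv, NULL,
                        rtol = 1e-12, atol = 1e-12)
  cell <- two_sulfur_cell(2.08)
  tr <- integrate_ions(cell, c(2, 2), kappa = 0,
                       params = pair_potential_params(collision = FALSE),
                       config = dynamics_config(dt = 0.01, t_end = 100))
  expect_lt(max(abs(tr$ss - ref[, "r"])), 1e-4)
})

test_that("zero charges leave every atom stationary", {
  cell <- generate_supercell(seed = 31)
  tr <- integrate_ions(cell, rep(0, nrow(cell$atoms)), kappa = 0,
                       config = dynamics_config(t_end = 10))
  expect_equal(tr$ss, rep(2.08, length(tr$times)), tolerance = 1e-12)
  expect_equal(max(abs(as.matrix(tr$final$atoms[, c("vx", "vy", "vz")]))), 0)
})

test_that("unstable steps abort with a helpful error", {
  cell <- two_sulfur_cell(0.8)
  expect_error(
    integrate_ions(cell, c(10, 10), kappa = 0,
                   config = dynamics_config(dt = 3, t_end = 30)),
    "unstable")
})

test_that("trajectory export writes frames and summary", {
  cell <- two_sulfur_cell(2.08)
  tr <- integrate_ions(cell, c(1, 1), kappa = 0,
                       config = dynamics_config(dt = 0.05, t_end = 5,
                                                store_positions = TRUE))
  xyz <- withr::local_tempfile(fileext = ".xyz")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, xyz, csv)
  expect_equal(length(readLines(xyz)), (2 + 2) * length(tr$times))
  df <- read.csv(csv)
  expect_equal(names(df), c("time", "ss_distance", "kinetic", "potential"))
  tr2 <- integrate_ions(cell, c(1, 1), kappa = 0,
                        config = dynamics_config(dt = 0.05, t_end = 5))
  expect_error(write_trajectory(tr2, xyz), "store_positions")
})
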