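rt <- default_rate_table()

test_that("screening parameter matches an independent SI-unit derivation", {
  expect_equal(screening_parameter(0, 0), 0)
  expect_equal(screening_parameter(0.004, 10),
               2 * screening_parameter(0.001, 10))  # sqrt scaling
  # SI oracle: lambda_D = sqrt(eps0 kB Te / (n e^2))
  eps0 <- 8.8541878128e-12; ee <- 1.602176634e-19
  n_si <- 0.01 * 1e30                      # A^-3 -> m^-3
  lam_si <- sqrt(eps0 * 10 * ee / (n_si * ee^2)) * 1e10   # m -> A
  # the package Coulomb constant carries 6 significant digits
  expect_equal(1 / screening_parameter(0.01, 10), lam_si, tolerance = 5e-6)
  expect_error(screening_parameter(0.01, 0), "T_e")
})

test_that("electron fate follows the spherical Coulomb barrier", {
  pl <- new_plasma_state(cell_volume = 14^3, sample_radius = 1000)
  # no net charge: everything escapes
  expect_equal(electron_fate(0.5, pl), "escaped")
  pl$escaped_charge <- 100
  # barrier = 14.3996 * 100 / 1000 = 1.43996 eV
  expect_equal(electron_fate(1.43995, pl), "trapped")
  expect_equal(electron_fate(1.44, pl), "escaped")
  expect_equal(electron_fate(0, pl), "trapped")
})

test_that("rate equations conserve atoms and charge and converge in dt", {
  comp <- c(C = 46, H = 154, N = 12, O = 86, S = 2)
  pp <- pulse_pair(fluence_cases("A2")["med"], delay = 20)
  h <- run_rate_equations(comp, pp, rt, t_end = 40, dt = 0.02,
                          cell_volume = 14^3)
  # per-element occupation conserved
  for (sym in names(comp)) {
    tot <- rowSums(h$pops[[sym]])
    expect_lt(max(abs(tot - comp[[sym]])) / comp[[sym]], 1e-9)
  }
  # charge balance: total ionic charge = trapped + escaped (per supercell)
  n <- length(h$times)
  ion_charge <- sum(vapply(names(comp), function(sym)
    h$mean_charge[n, sym] * comp[[sym]], numeric(1)))
  esc_per_cell <- h$escaped_charge[n] / ((4 / 3) * pi * 1000^3 / 14^3)
  expect_equal(ion_charge, h$n_trapped[n] + esc_per_cell, tolerance = 1e-9)
  # kappa finite, T_e non-negative
  expect_true(all(is.finite(h$kappa)) && all(h$T_e >= 0))
  # halving dt changes final mean charges by far less than 1e-3 relative
  h2 <- run_rate_equations(comp, pp, rt, t_end = 40, dt = 0.01,
                           cell_volume = 14^3)
  expect_lt(max(abs(h2$mean_charge[n, ] - h$mean_charge[n, ])) /
              max(h$mean_charge[n, ]), 1e-3)
})

test_that("photoionization-only limit matches the exponential closed form", {
  # single element, Auger disabled, trapping off (no plasma, no secondaries):
  # neutral fraction after the pulse = exp(-sigma * F_delivered)
  rt2 <- rt
  rt2$elements$C$auger_rate <- 0
  pp <- pulse_pair(2e4, delay = 10, pump_center = 20)
  t_end <- 60
  h <- run_rate_equations(c(C = 10), pp, rt2, t_end = t_end, dt = 0.005,
                          cell_volume = 1000, trapping = FALSE)
  Fdel <- integrate(function(t) pulse_flux(pp, t), 0, t_end,
                    rel.tol = 1e-12)$value
  neutral <- h$pops$C[length(h$times), 1] / 10
  expect_equal(neutral, exp(-rt$elements$C$photo_cross_section[1] * Fdel),
               tolerance = 1e-6)
  # no plasma formed
  expect_equal(max(h$n_e), 0)
})

test_that("advance_rate_equations leaves a driverless state unchanged", {
  pops <- new_charge_populations(c(O = 5, H = 3))
  pl <- new_plasma_state(14^3)
  out <- advance_rate_equations(pops, pl, rt, flux = 0, dt = 0.1)
  expect_equal(out$pops$elements$O$P, pops$elements$O$P)
  expect_equal(out$plasma$n_e, 0)
  expect_equal(out$plasma$time, 0.1)
  # with flux, occupations shift upward but stay conserved
  out2 <- advance_rate_equations(pops, pl, rt, flux = 1e3, dt = 0.1)
  expect_equal(sum(out2$pops$elements$O$P), 5, tolerance = 1e-12)
  expect_gt(out2$pops$elements$O$P[2], 0)
})

test_that("sampled charge staircases are monotone with matching statistics", {
  comp <- c(C = 46, H = 154, N = 12, O = 86, S = 2)
  pp <- pulse_pair(fluence_cases("A2")["max"], delay = 20)
  h <- run_rate_equations(comp, pp, rt, t_end = 40, cell_volume = 14^3)
  cell <- generate_supercell(seed = 5)
  q <- sample_ion_charges(h, cell, seed = 9)
  expect_identical(q$charges, sample_ion_charges(h, cell, seed = 9)$charges)
  # staircases never decrease, never exceed Z
  expect_true(all(apply(q$charges, 1, function(x) all(diff(x) >= 0))))
  Zmax <- c(H = 1, C = 6, N = 7, O = 8, S = 16)[cell$atoms$element]
  expect_true(all(q$charges[, ncol(q$charges)] <= Zmax))
  # frozen neutral populations give all-zero charges
  h0 <- run_rate_equations(comp, pulse_pair(0, 20), rt, t_end = 10,
                           cell_volume = 14^3)
  q0 <- sample_ion_charges(h0, cell, seed = 1)
  expect_true(all(q0$charges == 0))
  # ensemble-mean staircase converges to the population mean charge:
  # a large class of identical atoms is equivalent to many seeds of one atom
  fake <- structure(list(atoms = data.frame(element = rep("O", 4000),
                                            stringsAsFactors = FALSE)),
                    class = "sim_cell")
  qf <- sample_ion_charges(h, fake, seed = 21)
  mu <- h$mean_charge[length(h$times), "O"]
  pO <- h$pops$O[length(h$times), ] / comp[["O"]]
  sdO <- sqrt(sum((seq_along(pO) - 1)^2 * pO) - mu^2)
  expect_lt(abs(mean(qf$charges[, ncol(qf$charges)]) - mu),
            3 * sdO / sqrt(4000))
  # distribution match at the final time
  emp <- tabulate(qf$charges[, ncol(qf$charges)] + 1, nbins = length(pO)) / 4000
  expect_lt(max(abs(emp - pO)), 0.03)
  # mean-charge mode
  qm <- sample_ion_charges(h, cell, mode = "mean")
  expect_equal(unname(qm$charges[which(cell$atoms$element == "O")[1], ]),
               unname(h$mean_charge[, "O"]))
})

test_that("mean sulfur charge is the largest among elements after the pulse", {
  comp <- c(C = 46, H = 154, N = 12, O = 86, S = 2)
  pp <- pulse_pair(fluence_cases("A2")["med"], delay = 0)
  h <- run_rate_equations(comp, pp, rt, t_end = 45, cell_volume = 14^3)
  mc <- h$mean_charge[length(h$times), ]
  expect_equal(names(which.max(mc)), "S")
})

test_that("plasma history export and printing work", {
  h <- run_rate_equations(c(O = 10), pulse_pair(1e3, 10), rt, t_end = 20,
                          cell_volume = 500)
  df <- as.data.frame(h)
  expect_true(all(c("time", "O", "n_e", "T_e", "kappa") %in% names(df)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_plasma_csv(h, path)
  expect_equal(nrow(read.csv(path)), length(h$times))
  expect_output(print(h), "plasma_history")
})
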