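test_that("geometry_pair computes the Derjaguin effective radius", {
  expect_equal(geometry_pair("sphere_sphere", 20, 20)$effective_radius, 10)
  expect_equal(geometry_pair("sphere_sphere", 10, 40)$effective_radius, 8)
  expect_equal(geometry_pair("sphere_plate", 25)$effective_radius, 25)
  expect_error(geometry_pair("sphere_sphere", 10), "radius2")
  expect_error(geometry_pair("sphere_plate", -1), "radius1")
})

test_that("profile totals are the exact sum of components", {
  set.seed(31)
  for (i in 1:10) {
    a <- random_chemistry(); b <- random_chemistry()
    prof <- energy_profile(geometry_pair("sphere_sphere", runif(1, 4, 50),
                                         runif(1, 4, 50)),
                           a, b, phys_medium())
    expect_identical(prof$total, prof$lw + prof$el + prof$ab)
  }
})

test_that("identity medium with zero potential gives an all-zero profile", {
  w <- water_chemistry()
  prof <- energy_profile(geometry_pair("sphere_sphere", 10, 10), w, w,
                         phys_medium())
  expect_true(all(prof$total == 0))
  expect_true(all(prof$lw == 0))
  expect_true(all(prof$el == 0))
  expect_true(all(prof$ab == 0))
})

test_that("AB component e-folds over one decay length", {
  # grid step 0.01 nm puts both d0 and d0 + lambda exactly on the grid
  params <- xdlvo_parameters(d0 = 0.157, lambda_ab = 0.6, d_max = 6.157,
                             n_grid = 601)
  prof <- energy_profile(geometry_pair("sphere_plate", 20), generic_cell(),
                         generic_cell(), phys_medium(), params)
  i0 <- 1L
  i1 <- which.min(abs(prof$distance - (0.157 + 0.6)))
  expect_equal(prof$distance[i1], 0.757, tolerance = 1e-10)
  expect_equal(prof$ab[i1], prof$ab[i0] * exp(-1), tolerance = 1e-9)
})

test_that("LW component follows the 1/d law", {
  params <- xdlvo_parameters(d0 = 0.5, d_max = 8.5, n_grid = 801)
  cell <- generic_cell()
  prof <- energy_profile(geometry_pair("sphere_sphere", 15, 15), cell, cell,
                         phys_medium(), params)
  i1 <- which.min(abs(prof$distance - 2))
  i2 <- which.min(abs(prof$distance - 4))
  expect_equal(prof$lw[i2], prof$lw[i1] / 2, tolerance = 1e-9)
  # independent closed form: U(d) = 2*pi*R_eff*d0^2*G_lw/d in SI
  g_lw <- contact_lw(cell, cell, phys_medium()) * 1e-3
  u2 <- 2 * pi * 7.5e-9 * (0.5e-9)^2 * g_lw / 2e-9 * 6.02214076e23 / 1000
  expect_equal(prof$lw[i1], u2, tolerance = 1e-9)
})

test_that("EL component vanishes for uncharged pairs and repels like charges", {
  neutral <- surface_chemistry("n", 30, 1, 40, psi0 = 0)
  prof <- energy_profile(geometry_pair("sphere_sphere", 10, 10), neutral,
                         neutral, phys_medium())
  expect_true(all(prof$el == 0))
  charged <- surface_chemistry("c", 30, 1, 40, psi0 = -40)
  prof2 <- energy_profile(geometry_pair("sphere_sphere", 10, 10), charged,
                          charged, phys_medium())
  expect_true(all(prof2$el > 0))     # like charges repel at every separation
  expect_true(all(diff(prof2$el) < 0))  # screened decay is monotone
})

test_that("profiles vanish at the grid edge for fixture-sized particles", {
  panel <- as.data.frame(generate_np_panel(synthetic_spec(seed = 5,
                                                          n_nps = 8)))
  cell <- generic_cell()
  for (i in seq_len(nrow(panel))) {
    np <- surface_chemistry(panel$coating[i], panel$gamma_lw[i],
                            panel$gamma_plus[i], panel$gamma_minus[i])
    r <- panel$diameter_nm[i] / 2
    for (pair in list(geometry_pair("sphere_sphere", r, r),
                      geometry_pair("sphere_plate", r))) {
      prof <- energy_profile(pair, np, cell, phys_medium())
      expect_lt(abs(prof$total[length(prof$total)]), 1)
    }
  }
})

test_that("sphere-plate is the large-radius limit of sphere-sphere", {
  cell <- generic_cell()
  np <- surface_chemistry("np", 35, 0.5, 30, psi0 = -10)
  plate <- energy_profile(geometry_pair("sphere_plate", 12), np, cell,
                          phys_medium())
  huge <- energy_profile(geometry_pair("sphere_sphere", 12, 12e4), np, cell,
                         phys_medium())
  rel <- abs(np_vesicle_energy(huge) - np_vesicle_energy(plate)) /
    abs(np_vesicle_energy(plate))
  expect_lt(rel, 0.01)
})

test_that("all per-component energies scale linearly in effective radius", {
  cell <- generic_cell()
  np <- surface_chemistry("np", 28, 2, 55, psi0 = -25)
  set.seed(32)
  for (i in 1:5) {
    r <- runif(1, 5, 40); f <- runif(1, 1.5, 4)
    p1 <- energy_profile(geometry_pair("sphere_plate", r), np, cell,
                         phys_medium())
    p2 <- energy_profile(geometry_pair("sphere_plate", r * f), np, cell,
                         phys_medium())
    expect_equal(p2$lw, p1$lw * f, tolerance = 1e-12)
    expect_equal(p2$el, p1$el * f, tolerance = 1e-12)
    expect_equal(p2$ab, p1$ab * f, tolerance = 1e-12)
  }
})

test_that("np_vesicle_energy is the grid maximum (exhaustive-scan oracle)", {
  d <- seq(0.157, 25, length.out = 500)
  # constructed profile with one interior maximum
  tot <- -50 / d + 400 * exp(-d / 1.2)
  prof <- structure(list(distance = d, total = tot,
                         pair = geometry_pair("sphere_plate", 10)),
                    class = "interaction_profile")
  mx <- -Inf
  for (v in tot) if (v > mx) mx <- v   # brute-force scan
  expect_identical(np_vesicle_energy(prof), mx)
  # strictly decreasing repulsive profile: contact value wins
  prof2 <- structure(list(distance = d, total = 300 * exp(-d)),
                     class = "interaction_profile")
  expect_identical(np_vesicle_energy(prof2), prof2$total[1L])
  # all-zero profile
  prof3 <- structure(list(distance = d, total = numeric(length(d))),
                     class = "interaction_profile")
  expect_identical(np_vesicle_energy(prof3), 0)
  expect_error(np_vesicle_energy(structure(list(distance = numeric(0),
                                                total = numeric(0)),
                                           class = "interaction_profile")),
               "empty")
})

test_that("barrier_height matches a continuous-optimum oracle and flags", {
  d <- seq(0.157, 25, length.out = 4000)
  f <- function(x) -80 / x + 900 * exp(-x / 0.9)
  prof <- structure(list(distance = d, total = f(d)),
                    class = "interaction_profile")
  # bracket the single interior peak (f is not unimodal over the whole grid:
  # the 1/d tail creeps back toward zero at long range)
  opt <- optimize(f, c(0.157, 3), maximum = TRUE)
  b <- barrier_height(prof)
  expect_equal(as.numeric(b), opt$objective, tolerance = 1e-4)
  expect_equal(attr(b, "distance"), opt$maximum, tolerance = 1e-2)
  expect_false(attr(b, "no_barrier"))
  # purely attractive: floored at zero with the flag
  prof2 <- structure(list(distance = d, total = -100 / d),
                     class = "interaction_profile")
  b2 <- barrier_height(prof2)
  expect_identical(as.numeric(b2), 0)
  expect_true(attr(b2, "no_barrier"))
  # barrier dominates every grid value
  set.seed(33)
  for (i in sample(length(d), 25))
    expect_gte(as.numeric(b), prof$total[i])
})

test_that("barrier height is stable under grid refinement", {
  cell <- generic_cell()
  for (ng in c(2000L)) {
    p1 <- energy_profile(geometry_pair("sphere_plate", 30), cell, cell,
                         phys_medium(), xdlvo_parameters(n_grid = ng))
    p2 <- energy_profile(geometry_pair("sphere_plate", 30), cell, cell,
                         phys_medium(), xdlvo_parameters(n_grid = 2L * ng))
    rel <- abs(as.numeric(barrier_height(p2)) -
                 as.numeric(barrier_height(p1))) /
      as.numeric(barrier_height(p1))
    expect_lt(rel, 0.001)
  }
})

test_that("interaction_summary combines the two legs exactly", {
  cell <- generic_cell()
  np <- surface_chemistry("np", 35, 0.5, 30)
  s <- interaction_summary(np, np_radius = 10, cell = cell)
  expect_identical(s$dg_change, s$dg_barrier_v_m - s$dg_np_v)
  expect_equal(s$vesicle_radius, 10)   # default: vesicle wraps the NP
  expect_true(s$dg_np_v > 0 && s$dg_barrier_v_m > 0)
  # three identical phases: a summary of zeros
  w <- water_chemistry()
  s0 <- interaction_summary(w, np_radius = 10, cell = w)
  expect_identical(s0$dg_np_v, 0)
  expect_identical(s0$dg_barrier_v_m, 0)
  expect_identical(s0$dg_change, 0)
  expect_true(s0$no_barrier)
})

test_that("NP-vesicle energies grow monotonically with particle size", {
  # same monotone pattern as the packaged transferrin series (rows 59-63)
  cell <- generic_cell()
  np <- surface_chemistry("coated", 33, 1.2, 45)
  sizes <- c(7, 15, 25, 37, 50)
  en <- vapply(sizes, function(r)
    interaction_summary(np, np_radius = r, cell = cell)$dg_np_v, numeric(1))
  expect_true(all(diff(en) > 0))
  bar <- vapply(sizes, function(r)
    interaction_summary(np, np_radius = r, cell = cell)$dg_barrier_v_m,
    numeric(1))
  expect_true(all(diff(bar) > 0))
})
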