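# Synthetic screen generator: libraries, layouts, Cq simulation.

test_that("library generation respects class counts and seeds", {
  lib0 <- generate_library(5280, seed = 1)
  expect_equal(nrow(lib0), 5280)
  expect_true(all(lib0$class == "inactive"))
  expect_true(all(is.infinite(lib0$kd)))

  lib <- generate_library(110, binder_kds = c(0.26, 5000),
                          frac_interferer = 3 / 110, seed = 1)
  expect_equal(sum(lib$class == "binder"), 2)
  expect_equal(sum(lib$class == "interferer"), 3)
  expect_setequal(lib$kd[lib$class == "binder"], c(0.26, 5000))
  expect_true(all(lib$shift[lib$class == "interferer"] != 0))
  # reproducible for a fixed seed
  expect_identical(lib, generate_library(110, binder_kds = c(0.26, 5000),
                                         frac_interferer = 3 / 110,
                                         seed = 1))
  expect_error(generate_library(100, frac_binder = 0.6,
                                frac_interferer = 0.6), "fractions")
})

test_that("spread actives land in distinct pools", {
  lib <- generate_library(550, frac_binder = 0.01, frac_interferer = 0.01,
                          seed = 2)
  pm <- pool_map(lib, 11)
  active_pools <- pm$pool_id[lib$class != "inactive"]
  expect_false(anyDuplicated(active_pools) > 0)
})

test_that("plate layout produces the expected well counts", {
  d384 <- screen_design(n_compounds = 5280, pool_size = 11)
  lib <- generate_library(5280, seed = 3)
  wells <- layout_plates(lib, d384)
  expect_equal(sum(wells$role == "test"), 480)       # 5280 / 11
  expect_equal(length(unique(wells$plate_id)), 2)
  # every plate carries its control complement
  for (p in unique(wells$plate_id)) {
    pl <- wells[wells$plate_id == p, ]
    expect_equal(sum(pl$role == "negative_control"), 12)
    expect_equal(sum(pl$role == "inhibited_control"), 8)
    expect_equal(sum(pl$role == "positive_control"), 12)  # 6 concs x 2
  }
  # positive-control series: six 3-fold points in duplicate
  pos <- wells[wells$role == "positive_control" & wells$plate_id == "S01", ]
  expect_equal(sort(unique(pos$i_tot_nM)), sort(100 / 3^(0:5)))
  expect_true(all(table(pos$i_tot_nM) == 2))

  # individual format: one well per compound
  d1298 <- screen_design(n_compounds = 1298, pool_size = 1)
  w2 <- layout_plates(generate_library(1298, seed = 3), d1298)
  expect_equal(sum(w2$role == "test"), 1298)
  # 96-well plate fits 80 individual compounds plus controls
  d96 <- screen_design(n_compounds = 80, pool_size = 1, plate_format = 96)
  w3 <- layout_plates(generate_library(80, seed = 3), d96)
  expect_equal(length(unique(w3$plate_id)), 1)
  expect_equal(sum(w3$role == "test"), 80)
  # sizing error when a plate cap is imposed
  dcap <- screen_design(n_compounds = 5280, pool_size = 11, max_plates = 1)
  expect_error(layout_plates(lib, dcap), "max_plates")
})

test_that("noise-free Cq readouts match the forward model", {
  design <- screen_design(n_compounds = 33, pool_size = 11, noise_sd = 0,
                          seed = 4)
  lib <- generate_library(33, seed = 4)
  lib$class[12] <- "binder"; lib$kd[12] <- 5000          # one 5 uM binder
  lib$class[23] <- "interferer"; lib$shift[23] <- 1.5
  wells <- layout_plates(lib, design)
  screen <- simulate_cq(wells, lib, design)
  d <- delta_cq_table(screen)
  dt <- d[d$role == "test", ]
  # all-inactive pool: tiny residual shift only
  expect_equal(dt$delta_cq[1], 0, tolerance = 0.02)
  # pool with the 5 uM binder at 9 uM: above the 0.80 threshold
  expect_equal(dt$delta_cq[2], 1.36, tolerance = 0.01)
  expect_gt(dt$delta_cq[2], 0.80)
  # interferer pool: elevated by the shift in screen ...
  expect_equal(dt$delta_cq[3], 1.5, tolerance = 0.02)
  # ... and in counter-screen mode alike
  counter <- simulate_cq(wells, lib, design, counter = TRUE)
  dc <- delta_cq_table(counter)
  dct <- dc[dc$role == "test", ]
  expect_equal(dct$delta_cq[3], 1.5, tolerance = 0.02)
  # weak binders show no counter-screen shift; classes separate perfectly
  expect_lt(abs(dct$delta_cq[2]), 0.1)
  expect_lt(abs(dct$delta_cq[1]), 0.02)
})

test_that("strong binders out-compete the counter-screen ligand", {
  # documented limitation: at 9 uM a sub-nM binder displaces probe even
  # against 83 nM reference ligand, so the counter-screen cannot clear it
  design <- screen_design(n_compounds = 11, pool_size = 11, noise_sd = 0,
                          seed = 5)
  lib <- generate_library(11, seed = 5)
  lib$class[6] <- "binder"; lib$kd[6] <- 0.26
  wells <- layout_plates(lib, design)
  counter <- simulate_cq(wells, lib, design, counter = TRUE)
  dcq <- delta_cq_table(counter)
  expect_gt(dcq$delta_cq[dcq$role == "test"], 1)
})

test_that("exact multi-competitor pools agree with the approximation", {
  # one active per pool: strongest-competitor approximation is near-exact
  design <- screen_design(n_compounds = 11, pool_size = 11, noise_sd = 0,
                          seed = 6)
  lib <- generate_library(11, seed = 6)
  lib$class[6] <- "binder"; lib$kd[6] <- 2000
  wells <- layout_plates(lib, design)
  a <- simulate_cq(wells, lib, design, exact_pool = FALSE)
  b <- simulate_cq(wells, lib, design, exact_pool = TRUE)
  i <- which(wells$role == "test")
  expect_equal(a$cq[i], b$cq[i], tolerance = 1e-9)
  # two binders in one pool: exact model shows more competition
  lib$class[2] <- "binder"; lib$kd[2] <- 2000
  a2 <- simulate_cq(wells, lib, design, exact_pool = FALSE)
  b2 <- simulate_cq(wells, lib, design, exact_pool = TRUE)
  expect_gt(b2$cq[i], a2$cq[i])
})

test_that("empirical negative-control noise matches the configured SD", {
  design <- screen_design(n_compounds = 264, pool_size = 11,
                          noise_sd = 0.14, seed = 7, n_neg = 24)
  lib <- generate_library(264, seed = 7)
  screen <- simulate_cq(layout_plates(lib, design), lib, design, seed = 7)
  neg <- screen$cq[screen$role == "negative_control"]
  expect_equal(length(neg), 24)
  expect_lt(abs(sd(neg) - 0.14) / 0.14, 0.25)
})

test_that("detectability boundary sits at the closed-form inversion", {
  # noise-free hit boundary at 9 uM, threshold 0.80
  limit <- kd_detection_limit(0.80, 9000)
  dcq_of <- function(kd)
    delta_cq_forward(binding_system(0.01, 0.2, 9000, 1.32, kd))
  # brute-force boundary from the forward model
  brute <- uniroot(function(kd) dcq_of(kd) - 0.80,
                   c(1000, 50000), tol = 1e-4)$root
  expect_equal(brute, limit, tolerance = 0.01)
  expect_gt(dcq_of(limit * 0.95), 0.80)
  expect_lt(dcq_of(limit * 1.05), 0.80)
})

test_that("simulation is reproducible and validates compound ids", {
  design <- screen_design(n_compounds = 22, pool_size = 11, seed = 8)
  lib <- generate_library(22, seed = 8)
  wells <- layout_plates(lib, design)
  s1 <- simulate_cq(wells, lib, design, seed = 8)
  s2 <- simulate_cq(wells, lib, design, seed = 8)
  expect_identical(s1, s2)
  wells$content[wells$role == "test"][1] <- "C99999"
  expect_error(simulate_cq(wells, lib, design, seed = 8), "C99999")
})
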