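# Screening pipeline: delta-Cq, QC, hit calling, counter-screen filter,
# deconvolution, summary.

test_that("delta-Cq is computed against the plate's noninhibited mean", {
  w <- make_wells(neg_cq = c(9.8, 10.0), test_cq = c(10.7, 9.9))
  d <- delta_cq_table(w)
  expect_equal(d$delta_cq[d$role == "test"], c(0.8, 0.0))
  # negative-control delta-Cq averages to 0 by construction
  expect_equal(mean(d$delta_cq[d$role == "negative_control"]), 0)
  # censored Cq propagates, plates are independent
  w2 <- rbind(w, make_wells(neg_cq = c(12, 12.2), test_cq = NA_real_,
                            plate = "S02"))
  d2 <- delta_cq_table(w2)
  expect_true(is.na(d2$delta_cq[d2$plate_id == "S02" & d2$role == "test"]))
  expect_equal(attr(d2, "neg_mean_cq")[["S02"]], 12.1)
  # no negative controls -> pipeline error
  expect_error(delta_cq_table(w[w$role != "negative_control", ]),
               "negative-control")
})

test_that("QC reproduces the published pooled-screen statistics", {
  w <- make_wells(neg_cq = make_control_cq(24, 9.89, 0.14),
                  pos_cq = make_control_cq(24, 22.92, 0.11))
  qc <- qc_metrics(w)
  expect_equal(round(qc$assay_window, 2), 13.03)
  expect_equal(round(qc$z_prime, 2), 0.94)
  expect_equal(qc$n_neg, 24)
  # individual-format column: window 12.63, formula gives Z' 0.91
  w2 <- make_wells(neg_cq = make_control_cq(24, 10.22, 0.18),
                   pos_cq = make_control_cq(24, 22.85, 0.18))
  qc2 <- qc_metrics(w2)
  expect_equal(round(qc2$assay_window, 2), 12.63)
  expect_equal(round(qc2$z_prime, 2), 0.91)
  # noiseless limit
  expect_equal(z_prime_factor(10, 0, 23, 0), 1)
  expect_error(qc_metrics(w[w$role == "negative_control", ]), "QC needs")
})

test_that("thresholds from control SDs follow k * sd", {
  expect_equal(threshold_from_sd(0.09, 8), 0.72)
  expect_equal(threshold_from_sd(0.18, 3), 0.54)
  expect_error(threshold_from_sd(0.09, 0), "k")
  expect_error(threshold_from_sd(0, 3), "neg_sd")
})

test_that("hit calling is inclusive, deterministic and order-independent", {
  calls <- call_hits(c(A1 = 0.85, A2 = 0.30), threshold = 0.80)
  expect_equal(calls$status, c("initial_hit", "inactive"))
  expect_equal(call_hits(c(A1 = 0.80), 0.80)$status, "initial_hit")
  expect_equal(nrow(call_hits(setNames(numeric(0), character(0)), 0.8)), 0)
  # permuting input wells does not change the hit set
  set.seed(51)
  dcq <- setNames(runif(50, 0, 1.6), sprintf("W%02d", 1:50))
  h1 <- call_hits(dcq, 0.8)
  h2 <- call_hits(dcq[sample(50)], 0.8)
  expect_setequal(h1$subject[h1$status == "initial_hit"],
                  h2$subject[h2$status == "initial_hit"])
  expect_warning(call_hits(c(A1 = NA_real_), 0.8), "censored")
})

test_that("counter-screen filter reclassifies interferers only", {
  hits <- call_hits(c(A1 = 1.0, A2 = 1.2, A3 = 0.3), threshold = 0.8)
  out <- counter_screen_filter(hits, c(A1 = 1.2, A2 = 0.05, A3 = 2.0),
                               significance = 0.5)
  expect_equal(out$status, c("interferer", "initial_hit", "inactive"))
  expect_equal(out$counter_delta_cq, c(1.2, 0.05, 2.0))
  # missing counter data: retained with a warning and a flag
  expect_warning(out2 <- counter_screen_filter(hits, c(A1 = 1.2, A3 = 0.1),
                                               significance = 0.5),
                 "A2")
  expect_equal(out2$status[2], "initial_hit")
  expect_true(out2$counter_unresolved[2])
})

test_that("deconvolution plans list each pool member once at retest conc", {
  pm <- data.frame(pool_id = rep(c("P0001", "P0002"), each = 11),
                   compound_id = sprintf("C%05d", 1:22))
  hits <- call_hits(c(A1 = 1.0, A2 = 0.2), threshold = 0.8)
  hits$pool_id <- c("P0001", "P0002")
  plan <- deconvolution_plan(hits, pm)
  expect_equal(nrow(plan), 11)
  expect_setequal(plan$compound_id, sprintf("C%05d", 1:11))
  expect_true(all(plan$i_tot_nM == 10000))
  # two disjoint hit pools -> 22 unique entries
  hits2 <- hits; hits2$status <- "initial_hit"
  expect_equal(nrow(deconvolution_plan(hits2, pm)), 22)
  # no hits -> empty plan
  hits3 <- hits; hits3$status <- "inactive"
  expect_equal(nrow(deconvolution_plan(hits3, pm)), 0)
  # unknown pool is named in the error
  hits$pool_id[1] <- "P9999"
  expect_error(deconvolution_plan(hits, pm), "P9999")
})

test_that("confirmation can yield several compounds from one pool", {
  dcq <- c(C1 = 1.1, C2 = 0.9, C3 = 0.1, C4 = 0.05)
  pm <- data.frame(pool_id = "P0001", compound_id = names(dcq))
  calls <- confirm_hits(dcq, threshold = 0.8, pool_map = pm)
  expect_equal(sum(calls$status == "confirmed_hit"), 2)
  expect_setequal(calls$subject[calls$status == "confirmed_hit"],
                  c("C1", "C2"))
  expect_equal(unname(attr(calls, "pool_status")["P0001"]), "confirmed_hit")
  # all below threshold: the pool is not confirmed
  calls2 <- confirm_hits(c(C1 = 0.2, C2 = 0.3), 0.8, pool_map = pm[1:2, ])
  expect_true(all(calls2$status == "not_confirmed"))
  expect_equal(unname(attr(calls2, "pool_status")["P0001"]), "not_confirmed")
})

test_that("summary rates match the published screen outcome", {
  # 24 initial hits of which 20 interferers, library of 5,280
  status <- c(rep("interferer", 20), rep("initial_hit", 4),
              rep("inactive", 456))
  calls <- data.frame(subject = sprintf("W%03d", seq_along(status)),
                      status = status)
  s <- screen_summary(calls, library_size = 5280)
  expect_equal(s$n_initial_hits, 24)
  expect_equal(s$rate_initial, 0.45)    # < 0.5 % pre-deconvolution
  expect_equal(s$n_survivors, 4)
  expect_equal(s$rate_survivors, 0.076) # < 0.1 % post-counter-screen
  # no hits at all
  s0 <- screen_summary(data.frame(subject = "W1", status = "inactive"), 100)
  expect_equal(s0$rate_initial, 0)
})

test_that("well-record validation enforces role-content invariants", {
  w <- make_wells(neg_cq = c(10, 10.1), test_cq = 11)
  expect_silent(validate_wells(w, require_cq = TRUE))
  bad <- w; bad$content[1] <- "C00001"
  expect_error(validate_wells(bad), "negative_control")
  bad2 <- w; bad2$well[1] <- "Q99"
  expect_error(validate_wells(bad2), "well label")
  bad3 <- w; bad3$role[1] <- "blank"
  expect_error(validate_wells(bad3), "role")
  bad4 <- w; bad4$content[bad4$role == "test"] <- ""
  expect_error(validate_wells(bad4), "test wells")
})

test_that("pipeline outputs are invariant to well order", {
  design <- screen_design(n_compounds = 110, seed = 61, noise_sd = 0.1)
  lib <- generate_library(110, binder_kds = c(1000, 4000),
                          frac_interferer = 2 / 110, seed = 61)
  wells <- layout_plates(lib, design)
  screen <- simulate_cq(wells, lib, design, seed = 61)
  perm <- screen[sample(nrow(screen)), ]
  q1 <- qc_metrics(screen); q2 <- qc_metrics(perm)
  expect_equal(q1$z_prime, q2$z_prime)
  h1 <- call_hits(delta_cq_table(screen), 0.8)
  h2 <- call_hits(delta_cq_table(perm), 0.8)
  expect_setequal(h1$subject[h1$status == "initial_hit"],
                  h2$subject[h2$status == "initial_hit"])
})
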