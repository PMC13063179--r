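# Independent oracles and fixture builders.  These deliberately do NOT call
# package internals: the two-species quadratic, the closed-form delta-Cq
# and its inversion are written out directly so the numerical solver is
# checked against something it does not share code with.

# two-species complex concentration, textbook quadratic root
oracle_quad_bound <- function(t_tot, p_tot, kd) {
  s <- t_tot + p_tot + kd
  (s - sqrt(s^2 - 4 * t_tot * p_tot)) / 2
}

# closed-form delta-Cq in the negligible-target-depletion regime
oracle_dcq <- function(kd_compound, i_tot, p_tot = 0.2, kd_probe = 1.32) {
  log2(1 + (i_tot / kd_compound) / (1 + p_tot / kd_probe))
}

# closed-form single-well inversion (the published equation)
oracle_kd <- function(delta_cq, i_tot, p_tot = 0.2, kd_probe = 1.32) {
  (2^(-delta_cq) / (1 - 2^(-delta_cq))) * i_tot / (1 + p_tot / kd_probe)
}

# n Cq values with exactly the requested sample mean and SD
make_control_cq <- function(n, mean, sd) {
  z <- seq_len(n)
  z <- (z - base::mean(z)) / stats::sd(z)
  mean + sd * z
}

# minimal well-record table: negative controls + inhibited controls + tests
make_wells <- function(neg_cq, test_cq = numeric(0), pos_cq = numeric(0),
                       plate = "S01", test_conc = 9000,
                       pool_ids = NULL, contents = NULL) {
  n_n <- length(neg_cq); n_t <- length(test_cq); n_p <- length(pos_cq)
  labels <- dianascreen::well_labels(384)
  data.frame(
    plate_id = plate,
    well = labels[seq_len(n_n + n_t + n_p)],
    role = c(rep("negative_control", n_n), rep("test", n_t),
             rep("inhibited_control", n_p)),
    content = c(rep(NA_character_, n_n),
                if (n_t) (contents %||% sprintf("C%05d", seq_len(n_t))),
                rep("WL12", n_p)),
    pool_id = c(rep(NA_character_, n_n),
                if (n_t) (pool_ids %||% rep(NA_character_, n_t)),
                rep(NA_character_, n_p)),
    i_tot_nM = c(rep(0, n_n), rep(test_conc, n_t), rep(2500, n_p)),
    cq = c(neg_cq, test_cq, pos_cq),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
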