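# Independent oracles used across the suite. These deliberately re-derive
# the quantities with different code paths (plain formula re-evaluation,
# bisection instead of closed forms / Brent) so agreement is evidence, not
# tautology.

# Straight re-evaluation of the amplification-factor formula.
eta_oracle <- function(i0, istd, epsilon) {
  epsilon * (i0 - istd) / i0
}

# Plain bisection for the 1:1 free-ligand mass balance.
bisect_free_ligand <- function(p_total, l_total, kd, iters = 200) {
  if (l_total == 0) return(0)
  f <- function(lf) lf + p_total * lf / (kd + lf) - l_total
  lo <- 0; hi <- l_total
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Nested plain bisection for the competitive two-site equilibrium:
# inner loop solves the probe balance for a trial free ligand, outer loop
# the ligand balance.
bisect_two_site <- function(p_total, l_total, kd1, kd2, q_total, kd_q,
                            probe_site = 2L, iters = 120) {
  bound_l <- function(lf, qf) {
    d1 <- 1 + lf / kd1 + if (probe_site == 1L) qf / kd_q else 0
    d2 <- 1 + lf / kd2 + if (probe_site == 2L) qf / kd_q else 0
    c(p_total * (lf / kd1) / d1, p_total * (lf / kd2) / d2)
  }
  bound_q <- function(lf, qf) {
    kd_l <- if (probe_site == 1L) kd1 else kd2
    p_total * (qf / kd_q) / (1 + lf / kd_l + qf / kd_q)
  }
  qf_for <- function(lf) {
    if (q_total == 0) return(0)
    lo <- 0; hi <- q_total
    for (i in seq_len(iters)) {
      mid <- (lo + hi) / 2
      if (mid + bound_q(lf, mid) > q_total) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  lo <- 0; hi <- l_total
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (mid + sum(bound_l(mid, qf_for(mid))) > l_total) hi <- mid
    else lo <- mid
  }
  lf <- (lo + hi) / 2
  qf <- qf_for(lf)
  list(l_free = lf, q_free = qf, bound_l = bound_l(lf, qf),
       bound_q = bound_q(lf, qf))
}

# Noiseless saturation series straight from the model (no generator).
make_series <- function(std_max, k_sat, times = default_schedule(),
                        epsilon = 40, i0 = 1000,
                        proton_id = "p1", shift = 7.99,
                        ligand_id = "lig") {
  eta <- std_max * (1 - exp(-k_sat * times))
  saturation_series(ligand_id, proton_id, shift, times,
                    i0 = rep(i0, length(times)),
                    istd = i0 * (1 - eta / epsilon), epsilon = epsilon)
}

# Minimal converged buildup_fit stand-in for ratio/epitope tests.
fake_fit <- function(proton_id, std0, shift = 1, ligand_id = "lig",
                     converged = TRUE) {
  structure(
    list(ligand_id = ligand_id, proton_id = proton_id,
         chemical_shift = shift, std_max = std0, k_sat = 1, std0 = std0,
         se_std_max = NA_real_, se_k_sat = NA_real_, se_std0 = NA_real_,
         rss = 0, converged = converged, n_points = 8L,
         warnings = character(0)),
    class = "buildup_fit")
}
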