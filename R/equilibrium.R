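# Binding equilibria: binding degree from dialysis/ultrafiltration
# concentrations, 1:1 and competitive two-site mass-action solvers, and
# free-energy <-> dissociation-constant conversion.

# Gas constant in kcal mol^-1 K^-1 (standard state 1 M).
R_KCAL <- 1.9872e-3

#' Protein-binding degree from total and free drug concentrations
#'
#' Computes the percentage of drug bound to protein from the total drug
#' concentration in the protein-containing compartment (`d_total`) and the
#' free drug concentration measured after equilibrium dialysis or
#' ultrafiltration (`d_free`):
#' \deqn{100 (D_t - D_f) / D_t.}
#' The quantity is the \emph{bound} percentage ("binding degree"); the free
#' fraction is its complement. Both inputs must share the same concentration
#' unit; the result is unit-free (scale invariant).
#'
#' @param d_total total drug concentration(s), > 0.
#' @param d_free free drug concentration(s), in `[0, d_total]`.
#' @return Numeric vector of binding degrees in percent.
#' @examples
#' binding_degree(100, 20)   # 80
#' binding_degree(50, 0)     # 100 (fully bound)
#' @export
binding_degree <- function(d_total, d_free) {
  if (!is.numeric(d_total) || !is.numeric(d_free))
    abort_invalid("d_total and d_free must be numeric")
  if (length(d_free) != length(d_total))
    abort_invalid("d_total and d_free must have equal length")
  if (any(!is.finite(d_total)) || any(!is.finite(d_free)))
    abort_invalid("concentrations must be finite")
  if (any(d_total <= 0))
    abort_invalid("d_total must be > 0")
  if (any(d_free < 0))
    abort_invalid("d_free must be >= 0")
  if (any(d_free > d_total))
    abort_invalid(
      "d_free exceeds d_total: analytical error in the measurement, not clipped")
  100 * (d_total - d_free) / d_total
}

#' Summarize binding degrees per separation method
#'
#' Aggregates replicate dialysis/ultrafiltration measurements into a
#' mean +/- sd binding degree per method, the usual reporting shape for
#' plasma protein binding studies.
#'
#' @param measurements data frame with columns `method`, `D_t`, `D_f`
#'   (as returned by [generate_dialysis_dataset()] or
#'   [read_dialysis_table()]).
#' @return data frame with columns `method`, `n`, `mean_percent`,
#'   `sd_percent`.
#' @export
summarize_binding_degree <- function(measurements) {
  req <- c("method", "D_t", "D_f")
  if (!is.data.frame(measurements) || !all(req %in% names(measurements)))
    abort_invalid("measurements must contain columns method, D_t, D_f")
  deg <- binding_degree(measurements$D_t, measurements$D_f)
  methods <- sort(unique(as.character(measurements$method)))
  out <- lapply(methods, function(m) {
    d <- deg[measurements$method == m]
    data.frame(method = m, n = length(d), mean_percent = mean(d),
               sd_percent = if (length(d) > 1L) sd(d) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Free ligand concentration at 1:1 binding equilibrium
#'
#' Solves the mass-action equilibrium P + L <-> PL for the free ligand
#' concentration, given total protein `p_total`, total ligand `l_total` and
#' dissociation constant `kd` (all in the same concentration unit). Uses the
#' numerically stable closed form of the positive quadratic root.
#'
#' @param p_total total protein (binding-site) concentration, >= 0.
#' @param l_total total ligand concentration, >= 0.
#' @param kd dissociation constant, > 0.
#' @return Free ligand concentration (same unit as inputs). Vectorized over
#'   its arguments.
#' @examples
#' solve_free_ligand_1to1(p_total = 20, l_total = 800, kd = 13)
#' @export
solve_free_ligand_1to1 <- function(p_total, l_total, kd) {
  if (any(p_total < 0) || any(l_total < 0))
    abort_invalid("p_total and l_total must be >= 0")
  if (any(kd <= 0))
    abort_invalid("kd must be > 0")
  b <- p_total - l_total + kd
  disc <- sqrt(b^2 + 4 * kd * l_total)
  # L_f = (-b + disc)/2, rewritten to avoid cancellation when b > 0
  2 * kd * l_total / (b + disc)
}

#' Construct a binding system for equilibrium computations
#'
#' Bundles the concentrations and dissociation constants describing a
#' ligand (and optionally a site-selective competitor probe) binding to a
#' two-site protein such as HSA (Sudlow sites I and II), under an
#' independent-sites model.
#'
#' @param p_total total protein concentration (uM); each site is present at
#'   this concentration.
#' @param l_total total ligand concentration (uM).
#' @param kd_site named numeric vector of the ligand's per-site dissociation
#'   constants (uM); names are site identifiers (default
#'   `c(site_I = ..., site_II = ...)`). A single unnamed value is treated as
#'   a one-site (1:1) system.
#' @param q_total total probe concentration (uM); 0 means no probe.
#' @param kd_probe probe dissociation constant at its site (uM).
#' @param probe_site site identifier the probe binds (must match a name of
#'   `kd_site` when `q_total > 0`).
#' @param temperature temperature in kelvin.
#' @return An object of class `binding_system`.
#' @export
binding_system <- function(p_total, l_total, kd_site,
                           q_total = 0, kd_probe = NULL,
                           probe_site = NULL, temperature = 298) {
  if (!is_scalar_number(p_total) || p_total < 0)
    abort_invalid("p_total must be a nonnegative number")
  if (!is_scalar_number(l_total) || l_total < 0)
    abort_invalid("l_total must be a nonnegative number")
  if (!is.numeric(kd_site) || length(kd_site) < 1L || length(kd_site) > 2L ||
      any(!is.finite(kd_site)) || any(kd_site <= 0))
    abort_invalid("kd_site must be 1 or 2 finite positive values")
  if (length(kd_site) == 1L && is.null(names(kd_site)))
    names(kd_site) <- "site_I"
  if (length(kd_site) == 2L && is.null(names(kd_site)))
    names(kd_site) <- c("site_I", "site_II")
  if (anyDuplicated(names(kd_site)))
    abort_invalid("kd_site names must be unique site identifiers")
  if (!is_scalar_number(q_total) || q_total < 0)
    abort_invalid("probe concentration q_total must be >= 0")
  if (q_total > 0) {
    if (!is_scalar_number(kd_probe) || kd_probe <= 0)
      abort_invalid("kd_probe must be a positive number when a probe is present")
    if (is.null(probe_site) || !probe_site %in% names(kd_site))
      abort_invalid("probe_site must name exactly one site of kd_site")
  }
  if (!is_scalar_number(temperature) || temperature <= 0)
    abort_invalid("temperature must be > 0 K")
  structure(
    list(p_total = p_total, l_total = l_total, kd_site = kd_site,
         q_total = q_total, kd_probe = kd_probe, probe_site = probe_site,
         temperature = temperature),
    class = "binding_system")
}

#' @export
print.binding_system <- function(x, ...) {
  cat("Binding system (independent sites)\n")
  cat(sprintf("  protein: %g uM per site; ligand: %g uM\n",
              x$p_total, x$l_total))
  cat(sprintf("  ligand Kd: %s\n",
              paste(sprintf("%s = %g uM", names(x$kd_site), x$kd_site),
                    collapse = ", ")))
  if (x$q_total > 0)
    cat(sprintf("  probe: %g uM at %s (Kd = %g uM)\n",
                x$q_total, x$probe_site, x$kd_probe))
  cat(sprintf("  temperature: %g K\n", x$temperature))
  invisible(x)
}

# Bound ligand at each site for given free ligand/probe concentrations.
bound_ligand_at_sites <- function(system, l_free, q_free) {
  kd <- system$kd_site
  denom <- 1 + l_free / kd
  if (system$q_total > 0 || q_free > 0) {
    i <- match(system$probe_site, names(kd))
    if (!is.na(i)) denom[i] <- denom[i] + q_free / system$kd_probe
  }
  system$p_total * (l_free / kd) / denom
}

bound_probe <- function(system, l_free, q_free) {
  if (is.null(system$probe_site) || system$q_total == 0) return(0)
  kd_l <- system$kd_site[[system$probe_site]]
  system$p_total * (q_free / system$kd_probe) /
    (1 + l_free / kd_l + q_free / system$kd_probe)
}

#' Solve the competitive two-site binding equilibrium
#'
#' Solves the coupled mass-action equilibrium of a ligand binding two
#' independent protein sites while a probe competes at one of them.
#' Free concentrations are found by nested one-dimensional root finding on
#' the ligand and probe mass balances (each balance is strictly monotone in
#' its free concentration, so the roots are unique).
#'
#' @param system a [binding_system()].
#' @param tol relative tolerance on the mass balances (default `1e-12`).
#' @return A list with components `l_free`, `q_free`, `bound_l` (named per
#'   site), `bound_q`, and `mass_balance_rel_error`. Fails with an explicit
#'   error if the requested tolerance cannot be met.
#' @export
solve_competitive_two_site <- function(system, tol = 1e-12) {
  stopifnot(inherits(system, "binding_system"))
  lt <- system$l_total
  qt <- system$q_total

  # Roots are found on the log-concentration scale: free concentrations can
  # be many orders of magnitude below the totals (tight binding), and a
  # linear-scale bracket cannot resolve them to relative precision.
  log_root <- function(balance, total) {
    # balance(x) is strictly increasing with balance(total) >= 0
    f <- function(u) balance(exp(u))
    lo <- log(total) - 745   # exp() underflows just below this span
    if (f(lo) >= 0) return(0)
    if (f(log(total)) <= 0) return(total)  # nothing bound (up to rounding)
    exp(uniroot(f, lower = lo, upper = log(total), tol = tol)$root)
  }

  q_free_given_l <- function(l_free) {
    if (qt == 0) return(0)
    log_root(function(qf) qf + bound_probe(system, l_free, qf) - qt, qt)
  }

  if (lt == 0) {
    l_free <- 0
    q_free <- q_free_given_l(0)
  } else {
    l_free <- log_root(function(lf) {
      qf <- q_free_given_l(lf)
      lf + sum(bound_ligand_at_sites(system, lf, qf)) - lt
    }, lt)
    q_free <- q_free_given_l(l_free)
  }

  bl <- bound_ligand_at_sites(system, l_free, q_free)
  bq <- bound_probe(system, l_free, q_free)
  rel_err <- max(
    if (lt > 0) abs(l_free + sum(bl) - lt) / lt else 0,
    if (qt > 0) abs(q_free + bq - qt) / qt else 0)
  if (!is.finite(rel_err) || rel_err > 1e-9)
    stop_stdbind("stdbind_solver_error",
                 sprintf("equilibrium solver did not reach tolerance (rel. error %.3g)",
                         rel_err))
  list(l_free = l_free, q_free = q_free, bound_l = bl, bound_q = bq,
       mass_balance_rel_error = rel_err)
}

#' Model-predicted bound fraction of ligand
#'
#' Percentage of total ligand bound to protein at equilibrium under the
#' system's mass-action model; the model counterpart of the experimental
#' [binding_degree()].
#'
#' @param system a [binding_system()] with `l_total > 0`.
#' @return Bound percentage (0-100).
#' @export
predicted_bound_fraction <- function(system) {
  stopifnot(inherits(system, "binding_system"))
  if (system$l_total <= 0)
    abort_invalid("l_total must be > 0 to define a bound fraction")
  eq <- solve_competitive_two_site(system)
  100 * (system$l_total - eq$l_free) / system$l_total
}

#' Convert binding free energy to a dissociation constant (and back)
#'
#' `kd_from_deltaG()` maps a binding free energy (kcal/mol, negative =
#' favorable) to the dissociation constant Kd = exp(dG / (R T)) in molar
#' units at the 1 M standard state; `deltaG_from_kd()` is the exact inverse.
#' R = 1.9872e-3 kcal/(mol K).
#'
#' @param deltaG binding free energy in kcal/mol.
#' @param kd dissociation constant in M, > 0.
#' @param temperature temperature in kelvin.
#' @return Kd in molar units, or deltaG in kcal/mol.
#' @examples
#' kd_from_deltaG(-6.67, 298)   # ~1.3e-5 M (micromolar)
#' @export
kd_from_deltaG <- function(deltaG, temperature = 298) {
  if (any(temperature <= 0)) abort_invalid("temperature must be > 0 K")
  exp(deltaG / (R_KCAL * temperature))
}

#' @rdname kd_from_deltaG
#' @export
deltaG_from_kd <- function(kd, temperature = 298) {
  if (any(temperature <= 0)) abort_invalid("temperature must be > 0 K")
  if (any(kd <= 0)) abort_invalid("kd must be > 0")
  R_KCAL * temperature * log(kd)
}
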