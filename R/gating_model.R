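#' Boltzmann steady-state gating curve
#'
#' Sigmoid voltage dependence \eqn{y = A / (1 + \exp((V_{1/2} - V)/k))}. With
#' `k > 0` the curve increases with voltage (activation); steady-state
#' availability (inactivation) curves use the decreasing form
#' \eqn{A / (1 + \exp((V - V_{1/2})/k))}.
#'
#' @param v Membrane potential(s), mV.
#' @param vhalf Half-maximal voltage, mV.
#' @param k Slope factor, mV (positive).
#' @param A Amplitude (default 1, i.e. a normalized curve).
#' @param orientation `"activation"` (increasing) or `"inactivation"`
#'   (decreasing with voltage).
#' @return Numeric vector of curve values.
#' @export
boltzmann <- function(v, vhalf, k, A = 1,
                      orientation = c("activation", "inactivation")) {
  orientation <- match.arg(orientation)
  s <- if (orientation == "activation") (vhalf - v) / k else (v - vhalf) / k
  A / (1 + exp(s))
}

#' Sodium-channel gating model for the synthetic generators
#'
#' Bundles the steady-state and kinetic parameters needed to simulate
#' voltage-clamp protocols: Boltzmann activation and availability curves,
#' voltage-dependent biexponential inactivation decay, double-pulse recovery
#' from inactivation, and entry into slow inactivation. Defaults are the
#' wild-type parameter set used throughout the package (see
#' [gating_model_preset()] for the mutant-line sets).
#'
#' @param vhalf_act,k_act Activation midpoint and slope, mV.
#' @param vhalf_inact,k_inact Steady-state inactivation midpoint and slope, mV.
#' @param gmax Maximal specific conductance, nS/pF.
#' @param e_rev Reversal potential, mV.
#' @param tau_fast,tau_slow Inactivation-decay time constants, ms; either a
#'   scalar or a function of command voltage (mV).
#' @param A_frac_fast Fraction of the decay carried by the fast component,
#'   in \[0, 1\].
#' @param recovery_tau_fast,recovery_tau_slow Recovery-from-inactivation time
#'   constants, ms.
#' @param recovery_A_fast Fast fraction of the recovery curve (slow fraction is
#'   its complement; full recovery at long intervals).
#' @param slowentry_tau_fast,slowentry_tau_slow Time constants of entry into
#'   slow inactivation, ms.
#' @param slowentry_steady Residual availability after complete entry, in
#'   \[0, 1).
#' @param slowentry_A_fast Fast fraction of the decaying entry curve.
#' @return An object of class `gating_model`.
#' @examples
#' m <- gating_model()
#' boltzmann(-31, m$vhalf_act, m$k_act)  # 0.5 at the midpoint
#' @export
gating_model <- function(vhalf_act = -31.0, k_act = 6.0,
                         vhalf_inact = -71.5, k_inact = 9.9,
                         gmax = 0.39, e_rev = 40,
                         tau_fast = function(v) 0.8 + 2.2 * exp(-(v + 60) / 30),
                         tau_slow = function(v) 8 + 22 * exp(-(v + 60) / 30),
                         A_frac_fast = 0.85,
                         recovery_tau_fast = 74.8, recovery_tau_slow = 700.3,
                         recovery_A_fast = 0.6,
                         slowentry_tau_fast = 100, slowentry_tau_slow = 1000,
                         slowentry_steady = 0.35, slowentry_A_fast = 0.6) {
  assert_number(k_act, "k_act", lower = 1e-9)
  assert_number(k_inact, "k_inact", lower = 1e-9)
  assert_number(gmax, "gmax", lower = 1e-12)
  assert_number(A_frac_fast, "A_frac_fast", lower = 0, upper = 1)
  assert_number(recovery_tau_fast, "recovery_tau_fast", lower = 1e-9)
  assert_number(recovery_tau_slow, "recovery_tau_slow", lower = 1e-9)
  assert_number(recovery_A_fast, "recovery_A_fast", lower = 0, upper = 1)
  assert_number(slowentry_tau_fast, "slowentry_tau_fast", lower = 1e-9)
  assert_number(slowentry_tau_slow, "slowentry_tau_slow", lower = 1e-9)
  assert_number(slowentry_steady, "slowentry_steady", lower = 0, upper = 1)
  assert_number(slowentry_A_fast, "slowentry_A_fast", lower = 0, upper = 1)
  tau_fast <- as_tau_fun(tau_fast, "tau_fast")
  tau_slow <- as_tau_fun(tau_slow, "tau_slow")
  structure(list(
    vhalf_act = vhalf_act, k_act = k_act,
    vhalf_inact = vhalf_inact, k_inact = k_inact,
    gmax = gmax, e_rev = e_rev,
    tau_fast = tau_fast, tau_slow = tau_slow, A_frac_fast = A_frac_fast,
    recovery_tau_fast = recovery_tau_fast,
    recovery_tau_slow = recovery_tau_slow,
    recovery_A_fast = recovery_A_fast,
    slowentry_tau_fast = slowentry_tau_fast,
    slowentry_tau_slow = slowentry_tau_slow,
    slowentry_steady = slowentry_steady,
    slowentry_A_fast = slowentry_A_fast
  ), class = "gating_model")
}

as_tau_fun <- function(x, name) {
  if (is.function(x)) return(x)
  assert_number(x, name, lower = 1e-9)
  force(x)
  function(v) rep(x, length(v))
}

#' Group-level gating parameter presets
#'
#' Parameter sets for the three cell-line groups analyzed by the pipeline:
#' wild-type control and the two SCN5A-p.R1913C carrier lines (clinically
#' asymptomatic and symptomatic). Steady-state and recovery constants are the
#' group means; maximal conductance is set so each group's simulated peak
#' current density at -20 mV matches its group mean.
#'
#' @param group One of `"wt"`, `"asymptomatic"`, `"symptomatic"`.
#' @return A [gating_model()].
#' @export
gating_model_preset <- function(group = c("wt", "asymptomatic", "symptomatic")) {
  group <- match.arg(group)
  switch(group,
    wt = gating_model(),
    asymptomatic = gating_model(
      vhalf_act = -33.5, k_act = 5.4, vhalf_inact = -73.1, k_inact = 10.5,
      gmax = 0.469,
      recovery_tau_fast = 47.4, recovery_tau_slow = 509.2),
    symptomatic = gating_model(
      vhalf_act = -31.9, k_act = 5.1, vhalf_inact = -74.1, k_inact = 10.3,
      gmax = 0.479,
      recovery_tau_fast = 63.3, recovery_tau_slow = 579.9)
  )
}

#' @export
print.gating_model <- function(x, ...) {
  cat("Gating model\n")
  cat(sprintf("  activation:   V1/2 = %.1f mV, k = %.1f mV\n", x$vhalf_act, x$k_act))
  cat(sprintf("  inactivation: V1/2 = %.1f mV, k = %.1f mV\n", x$vhalf_inact, x$k_inact))
  cat(sprintf("  gmax = %.3f nS/pF, Erev = %.1f mV, A_fast = %.2f\n",
              x$gmax, x$e_rev, x$A_frac_fast))
  cat(sprintf("  recovery: tau_f = %.1f ms, tau_s = %.1f ms (A_f = %.2f)\n",
              x$recovery_tau_fast, x$recovery_tau_slow, x$recovery_A_fast))
  cat(sprintf("  slow-inactivation entry: tau_f = %.0f ms, tau_s = %.0f ms, steady = %.2f\n",
              x$slowentry_tau_fast, x$slowentry_tau_slow, x$slowentry_steady))
  invisible(x)
}
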