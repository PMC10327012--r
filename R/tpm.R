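# Tsodyks-Pawelzik-Markram short-term synaptic plasticity: event-driven
# closed-form updates between spikes, a deSolve dense-ODE reference route,
# and conductance-to-current coupling.

#' Tsodyks-Pawelzik-Markram synapse parameters
#'
#' Five constants per directed type pair: peak unitary conductance `g` (nS),
#' conductance decay time `tau_d` (ms), resource recovery time `tau_r` (ms),
#' facilitation time `tau_f` (ms) and utilization ratio `U` in (0, 1\].
#'
#' @param g_nS Peak unitary conductance (nS, > 0).
#' @param tau_d_ms Decay time constant (ms, > 0).
#' @param tau_r_ms Recovery time constant (ms, > 0).
#' @param tau_f_ms Facilitation time constant (ms, > 0).
#' @param U Utilization ratio in (0, 1\].
#' @return A `tpm_params` object with fields `g`, `tau_d`, `tau_r`, `tau_f`,
#'   `U`.
#' @examples
#' tpm_params(1, 5, 400, 50, 0.35)
#' @export
tpm_params <- function(g_nS, tau_d_ms, tau_r_ms, tau_f_ms, U) {
  if (g_nS <= 0 || tau_d_ms <= 0 || tau_r_ms <= 0 || tau_f_ms <= 0) {
    stop("g and all time constants must be positive", call. = FALSE)
  }
  if (U <= 0 || U > 1) {
    stop("U must lie in (0, 1]", call. = FALSE)
  }
  structure(list(g = g_nS, tau_d = tau_d_ms, tau_r = tau_r_ms,
                 tau_f = tau_f_ms, U = U),
            class = "tpm_params")
}

#' Coerce to TPM parameters
#'
#' Accepts a `tpm_params` object, a named list, or a one-row data frame in
#' the knowledge-base dialect (`g_nS`, `tau_d_ms`, ...).
#'
#' @param x Object to coerce.
#' @return A `tpm_params` object.
#' @export
as_tpm_params <- function(x) {
  if (inherits(x, "tpm_params")) {
    return(x)
  }
  x <- as.list(x)
  nm <- c("g_nS", "tau_d_ms", "tau_r_ms", "tau_f_ms", "U")
  if (!all(nm %in% names(x))) {
    nm <- c("g", "tau_d", "tau_r", "tau_f", "U")
  }
  do.call(tpm_params, setNames(lapply(x[nm], as.numeric),
                               c("g_nS", "tau_d_ms", "tau_r_ms", "tau_f_ms",
                                 "U")))
}

#' @export
print.tpm_params <- function(x, ...) {
  cat(sprintf("<tpm_params> g=%g nS tau_d=%g tau_r=%g tau_f=%g ms U=%g\n",
              x$g, x$tau_d, x$tau_r, x$tau_f, x$U))
  invisible(x)
}

#' Synapse state
#'
#' `R` is the available resource fraction (relaxes to 1 with `tau_r`), `u`
#' the running utilization (relaxes to 0 with `tau_f`; the baseline `U` is
#' re-added at each presynaptic spike) and `g_t` the instantaneous
#' conductance (decays with `tau_d`).
#'
#' @param R Resource fraction in \[0, 1\] (default 1, rested).
#' @param u Utilization in \[0, 1\] (default 0).
#' @param g_t Conductance (nS, >= 0; default 0).
#' @return A `tpm_state` list.
#' @export
tpm_state <- function(R = 1, u = 0, g_t = 0) {
  if (R < 0 || R > 1 || u < 0 || u > 1 || g_t < 0) {
    stop("state out of bounds: need 0 <= R,u <= 1 and g_t >= 0",
         call. = FALSE)
  }
  list(R = R, u = u, g_t = g_t)
}

#' Closed-form relaxation between presynaptic spikes
#'
#' Over an inter-event interval the three state variables relax
#' independently and exponentially: `R' = 1 - (1 - R) exp(-dt/tau_r)`,
#' `u' = u exp(-dt/tau_f)`, `g' = g_t exp(-dt/tau_d)`. Exact for any elapsed
#' time; composing two half-intervals equals one full interval.
#'
#' @param state A [tpm_state()].
#' @param params A [tpm_params()] (or coercible).
#' @param elapsed_ms Elapsed time (ms, >= 0).
#' @return The relaxed `tpm_state`.
#' @export
tpm_decay <- function(state, params, elapsed_ms) {
  if (elapsed_ms < 0) stop("elapsed_ms must be >= 0", call. = FALSE)
  p <- as_tpm_params(params)
  list(
    R = 1 - (1 - state$R) * exp(-elapsed_ms / p$tau_r),
    u = state$u * exp(-elapsed_ms / p$tau_f),
    g_t = state$g_t * exp(-elapsed_ms / p$tau_d)
  )
}

#' Presynaptic spike update
#'
#' Facilitation-before-release: utilization first jumps toward 1,
#' `u+ = u + U (1 - u)`; the released resource fraction is `R u+`; the
#' resource pool is depleted by that amount; and the conductance jumps by
#' `g * released`.
#'
#' @inheritParams tpm_decay
#' @return List with the updated `state` and the `released` fraction.
#' @examples
#' tpm_on_spike(tpm_state(), tpm_params(1, 5, 400, 50, 0.35))$released  # 0.35
#' @export
tpm_on_spike <- function(state, params) {
  p <- as_tpm_params(params)
  u2 <- state$u + p$U * (1 - state$u)
  released <- state$R * u2
  list(
    state = list(R = state$R - released, u = u2,
                 g_t = state$g_t + p$g * released),
    released = released
  )
}

#' Conductance-based synaptic current
#'
#' `I = g_t (reversal - v)`: with conductance in nS and potentials in mV the
#' current is in pA. Positive (depolarizing) below the reversal potential,
#' zero at it, negative above.
#'
#' @param g_t_nS Instantaneous conductance (nS).
#' @param v_mV Postsynaptic membrane potential (mV).
#' @param reversal_mV Synaptic reversal potential (mV; 0 for excitatory,
#'   about -70 for inhibitory synapses).
#' @return Current (pA); vectorized.
#' @export
synaptic_current <- function(g_t_nS, v_mV, reversal_mV) {
  g_t_nS * (reversal_mV - v_mV)
}

#' Per-spike conductance amplitudes along a spike train
#'
#' Drives the synapse event-by-event with the closed-form relaxation between
#' spikes and the spike update at each spike, returning the per-spike state
#' and the conductance jump (`g * released`) -- depressing trains give
#' decreasing jumps, facilitating trains increasing ones.
#'
#' @param params A [tpm_params()] (or coercible).
#' @param spike_times_ms Strictly increasing spike times (ms).
#' @return Tibble with one row per spike: `time_ms`, `R_before`, `u_after`,
#'   `released`, `amplitude_nS` (conductance jump), `g_after_nS`.
#' @examples
#' psc_amplitude_train(tpm_params(1, 5, 400, 50, 0.35), c(0, 50, 100))
#' @export
psc_amplitude_train <- function(params, spike_times_ms) {
  p <- as_tpm_params(params)
  if (length(spike_times_ms) == 0) {
    return(tibble::tibble(time_ms = double(), R_before = double(),
                          u_after = double(), released = double(),
                          amplitude_nS = double(), g_after_nS = double()))
  }
  if (any(diff(spike_times_ms) <= 0)) {
    stop("spike times must be strictly increasing", call. = FALSE)
  }
  n <- length(spike_times_ms)
  state <- tpm_state()
  last_t <- spike_times_ms[1]
  out <- vector("list", n)
  for (i in seq_len(n)) {
    state <- tpm_decay(state, p, spike_times_ms[i] - last_t)
    R_before <- state$R
    upd <- tpm_on_spike(state, p)
    state <- upd$state
    last_t <- spike_times_ms[i]
    out[[i]] <- tibble::tibble(
      time_ms = spike_times_ms[i], R_before = R_before, u_after = state$u,
      released = upd$released, amplitude_nS = p$g * upd$released,
      g_after_nS = state$g_t
    )
  }
  dplyr::bind_rows(out)
}

#' Dense-ODE reference integration of the TPM synapse
#'
#' Independent route for checking the event-driven closed form: integrates
#' `dR/dt = (1 - R)/tau_r`, `du/dt = -u/tau_f`, `dg/dt = -g/tau_d` with
#' `deSolve::ode()` (lsoda, tight tolerances), applying the spike update as
#' a discrete event at each spike time and logging the released fraction
#' inside the event function.
#'
#' @inheritParams psc_amplitude_train
#' @param t_end_ms End of integration (default: last spike + 5 decay times).
#' @param rtol,atol Integrator tolerances (default 1e-10).
#' @return List with `released` (per-spike released fractions) and `trace`
#'   (tibble `time_ms`, `R`, `u`, `g_t` on a dense grid).
#' @export
tpm_ode_trace <- function(params, spike_times_ms, t_end_ms = NULL,
                          rtol = 1e-10, atol = 1e-12) {
  p <- as_tpm_params(params)
  if (length(spike_times_ms) > 0 && any(diff(spike_times_ms) <= 0)) {
    stop("spike times must be strictly increasing", call. = FALSE)
  }
  if (length(spike_times_ms) > 0 && spike_times_ms[1] <= 0) {
    stop("spike times must be positive (integration starts at 0)",
         call. = FALSE)
  }
  t_end_ms <- t_end_ms %||%
    (if (length(spike_times_ms) > 0) max(spike_times_ms) + 5 * p$tau_d else 1)
  deriv <- function(t, y, parms) {
    list(c((1 - y[1]) / p$tau_r, -y[2] / p$tau_f, -y[3] / p$tau_d))
  }
  eventfun <- function(t, y, parms) {
    u2 <- y[2] + p$U * (1 - y[2])
    rel <- y[1] * u2
    c(y[1] - rel, u2, y[3] + p$g * rel)
  }
  # the state reported at an event time is pre-event; sampling just after
  # each spike recovers the per-spike released fraction as the drop in R
  # across the event (the decay over eps is O(eps/tau_r), negligible)
  eps <- 1e-7
  post_times <- spike_times_ms + eps
  times <- sort(unique(c(seq(0, t_end_ms, length.out = 512), spike_times_ms,
                         post_times)))
  sol <- deSolve::ode(
    y = c(R = 1, u = 0, g_t = 0), times = times, func = deriv, parms = NULL,
    method = "lsoda", rtol = rtol, atol = atol,
    events = if (length(spike_times_ms) > 0) {
      list(func = eventfun, time = spike_times_ms)
    } else {
      NULL
    }
  )
  t_sol <- sol[, "time"]
  released <- if (length(spike_times_ms) > 0) {
    i_pre <- match(spike_times_ms, t_sol)
    i_post <- match(post_times, t_sol)
    sol[i_pre, "R"] - sol[i_post, "R"]
  } else {
    numeric(0)
  }
  list(
    released = released,
    trace = tibble::tibble(time_ms = t_sol, R = sol[, "R"],
                           u = sol[, "u"], g_t = sol[, "g_t"])
  )
}

#' Steady-state per-spike release for a periodic train
#'
#' Analytic fixed point of the two-variable spike-to-spike recurrence under
#' a periodic presynaptic train with interval `T`: with
#' `Ef = exp(-T/tau_f)` and `Er = exp(-T/tau_r)`, the post-spike utilization
#' converges to `u* = U / (1 - (1 - U) Ef)` and the pre-spike resource to
#' `R* = (1 - Er) / (1 - (1 - u*) Er)`, giving steady released fraction
#' `R* u*`.
#'
#' @param params A [tpm_params()] (or coercible).
#' @param interval_ms Spike interval (ms, > 0).
#' @return List with `u_star`, `R_star`, `released_star`,
#'   `amplitude_star_nS`.
#' @export
tpm_periodic_fixed_point <- function(params, interval_ms) {
  if (interval_ms <= 0) stop("interval_ms must be positive", call. = FALSE)
  p <- as_tpm_params(params)
  Ef <- exp(-interval_ms / p$tau_f)
  Er <- exp(-interval_ms / p$tau_r)
  u_star <- p$U / (1 - (1 - p$U) * Ef)
  R_star <- (1 - Er) / (1 - (1 - u_star) * Er)
  list(u_star = u_star, R_star = R_star, released_star = R_star * u_star,
       amplitude_star_nS = p$g * R_star * u_star)
}
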