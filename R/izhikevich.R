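# Single-compartment nine-parameter Izhikevich dynamics: hybrid quadratic
# integrate-and-reset model, step-current protocols, F-I curves, rheobase.

#' Nine-parameter Izhikevich neuron model
#'
#' The hybrid two-variable model
#' `C dv/dt = k (v - Vr)(v - Vt) - u + I` and
#' `du/dt = a (b (v - Vr) - u)`, with the discontinuous reset
#' `v >= Vpeak  =>  v <- Vmin, u <- u + d`. Units: `C` pF, `k` nS/mV, all
#' potentials mV, `a` 1/ms, `b` nS, `d` pA; currents in pA, time in ms.
#'
#' @param C Membrane capacitance (pF, > 0).
#' @param k Quadratic scaling (nS/mV, > 0).
#' @param Vr Resting potential (mV).
#' @param Vt Threshold potential (mV), `Vr < Vt`.
#' @param Vpeak Spike cutoff potential (mV), `> Vt`.
#' @param Vmin Post-spike reset potential (mV), `< Vpeak`.
#' @param a Recovery rate (1/ms, > 0).
#' @param b Recovery sensitivity (nS; may be negative).
#' @param d Post-spike recovery increment (pA).
#' @return An `izhikevich_params` object.
#' @examples
#' izhikevich_params(C = 100, k = 0.7, Vr = -60, Vt = -40, Vpeak = 35,
#'                   Vmin = -50, a = 0.03, b = -2, d = 100)
#' @export
izhikevich_params <- function(C, k, Vr, Vt, Vpeak, Vmin, a, b, d) {
  p <- list(C = C, k = k, Vr = Vr, Vt = Vt, Vpeak = Vpeak, Vmin = Vmin,
            a = a, b = b, d = d)
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                  logical(1)))) {
    stop("all Izhikevich parameters must be finite scalars", call. = FALSE)
  }
  if (!(Vr < Vt && Vt < Vpeak && Vmin < Vpeak)) {
    stop("potentials must satisfy Vr < Vt < Vpeak and Vmin < Vpeak",
         call. = FALSE)
  }
  if (C <= 0 || k <= 0 || a <= 0) {
    stop("C, k and a must be positive", call. = FALSE)
  }
  structure(p, class = "izhikevich_params")
}

#' Coerce to Izhikevich parameters
#'
#' Accepts an `izhikevich_params` object, a named list, or a one-row data
#' frame in the knowledge-base dialect (`C_pF`, `k_nS_per_mV`, `Vr_mV`, ...).
#'
#' @param x Object to coerce.
#' @return An `izhikevich_params` object.
#' @export
as_izhikevich_params <- function(x) {
  if (inherits(x, "izhikevich_params")) {
    return(x)
  }
  x <- as.list(x)
  dialect <- c(C = "C_pF", k = "k_nS_per_mV", Vr = "Vr_mV", Vt = "Vt_mV",
               Vpeak = "Vpeak_mV", Vmin = "Vmin_mV", a = "a_per_ms",
               b = "b_nS", d = "d_pA")
  if (all(dialect %in% names(x))) {
    x <- setNames(x[dialect], names(dialect))
  }
  do.call(izhikevich_params, lapply(x[names(dialect)], as.numeric))
}

#' @export
print.izhikevich_params <- function(x, ...) {
  cat(sprintf(
    "<izhikevich_params> C=%g pF k=%g nS/mV Vr=%g Vt=%g Vpeak=%g Vmin=%g mV a=%g /ms b=%g nS d=%g pA\n",
    x$C, x$k, x$Vr, x$Vt, x$Vpeak, x$Vmin, x$a, x$b, x$d))
  invisible(x)
}

#' Square current-step stimulation protocol
#'
#' A constant current `amplitude_pA` applied from `onset_ms` for
#' `duration_ms`, padded before and after by zero current. The default
#' mirrors the standard characterization protocol: a 1 s pulse with 100 ms
#' padding on each side.
#'
#' @param amplitude_pA Step amplitude (pA).
#' @param onset_ms Stimulus onset (ms, default 100).
#' @param duration_ms Stimulus duration (ms, default 1000).
#' @param tail_ms Zero-current padding after offset (ms, default 100).
#' @return A `step_protocol` object with fields `amplitude_pA`, `onset_ms`,
#'   `duration_ms`, `total_ms`.
#' @export
step_protocol <- function(amplitude_pA, onset_ms = 100, duration_ms = 1000,
                          tail_ms = 100) {
  if (onset_ms < 0 || duration_ms <= 0 || tail_ms < 0) {
    stop("onset_ms and tail_ms must be >= 0 and duration_ms > 0",
         call. = FALSE)
  }
  structure(list(amplitude_pA = amplitude_pA, onset_ms = onset_ms,
                 duration_ms = duration_ms,
                 total_ms = onset_ms + duration_ms + tail_ms),
            class = "step_protocol")
}

#' One forward-Euler update of the Izhikevich model
#'
#' Advances `(v, u)` by `dt` under injected current `I`, then applies the
#' reset rule. Exposed mainly for stepping small circuits by hand; network
#' simulation uses the same update vectorized over populations.
#'
#' @param state Named list or vector with `v` (mV) and `u` (pA).
#' @param params An [izhikevich_params()] (or coercible).
#' @param I Injected current (pA).
#' @param dt Time step (ms, > 0).
#' @return List with `v`, `u` and logical `spike`.
#' @export
step_state <- function(state, params, I, dt = 0.1) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  p <- as_izhikevich_params(params)
  v <- state$v
  u <- state$u
  if (!is.finite(v) || !is.finite(u)) {
    stop("non-finite neuron state", call. = FALSE)
  }
  v2 <- v + dt * (p$k * (v - p$Vr) * (v - p$Vt) - u + I) / p$C
  u2 <- u + dt * p$a * (p$b * (v - p$Vr) - u)
  spike <- v2 >= p$Vpeak
  if (spike) {
    v2 <- p$Vmin
    u2 <- u2 + p$d
  }
  list(v = v2, u = u2, spike = spike)
}

#' Simulate a neuron under a current-step protocol
#'
#' Forward-Euler integration (default `dt = 0.1` ms) from rest
#' `(Vr, 0)`. A spike is recorded at the step where `v` reaches `Vpeak`; the
#' recorded voltage at that step is `Vpeak` followed by the reset, so every
#' recorded sample satisfies `v <= Vpeak`.
#'
#' @param params An [izhikevich_params()] (or coercible).
#' @param protocol A [step_protocol()].
#' @param dt Time step (ms, default 0.1).
#' @return An `izhikevich_sim` object: list with `trace` (tibble `time_ms`,
#'   `v_mV`, `u_pA`), `spike_times_ms`, `params`, `protocol`, `dt`.
#' @examples
#' p <- izhikevich_params(100, 0.7, -60, -40, 35, -50, 0.03, -2, 100)
#' sim <- simulate_izhikevich(p, step_protocol(250))
#' length(sim$spike_times_ms)
#' @export
simulate_izhikevich <- function(params, protocol, dt = 0.1) {
  p <- as_izhikevich_params(params)
  stopifnot(inherits(protocol, "step_protocol"))
  n <- as.integer(round(protocol$total_ms / dt))
  t_ms <- seq_len(n) * dt
  I <- ifelse(t_ms > protocol$onset_ms &
                t_ms <= protocol$onset_ms + protocol$duration_ms,
              protocol$amplitude_pA, 0)
  v_out <- numeric(n)
  u_out <- numeric(n)
  spikes <- numeric(0)
  v <- p$Vr
  u <- 0
  C <- p$C; k <- p$k; Vr <- p$Vr; Vt <- p$Vt; Vpeak <- p$Vpeak
  Vmin <- p$Vmin; a <- p$a; b <- p$b; d <- p$d
  for (i in seq_len(n)) {
    v2 <- v + dt * (k * (v - Vr) * (v - Vt) - u + I[i]) / C
    u <- u + dt * a * (b * (v - Vr) - u)
    if (v2 >= Vpeak) {
      spikes <- c(spikes, t_ms[i])
      v_out[i] <- Vpeak
      v <- Vmin
      u <- u + d
    } else {
      v_out[i] <- v2
      v <- v2
    }
    u_out[i] <- u
    if (!is.finite(v)) {
      stop(sprintf("non-finite membrane potential at t = %g ms", t_ms[i]),
           call. = FALSE)
    }
  }
  structure(
    list(trace = tibble::tibble(time_ms = t_ms, v_mV = v_out, u_pA = u_out),
         spike_times_ms = spikes, params = p, protocol = protocol, dt = dt),
    class = "izhikevich_sim"
  )
}

#' @export
print.izhikevich_sim <- function(x, ...) {
  cat(sprintf("<izhikevich_sim> %g ms at dt=%g ms, %d spikes (%.1f Hz over stimulus)\n",
              x$protocol$total_ms, x$dt, length(x$spike_times_ms),
              1000 * length(x$spike_times_ms) / x$protocol$duration_ms))
  invisible(x)
}

#' @method tidy izhikevich_sim
#' @export
tidy.izhikevich_sim <- function(x, ...) x$trace

#' @method glance izhikevich_sim
#' @export
glance.izhikevich_sim <- function(x, ...) {
  tibble::tibble(
    n_spikes = length(x$spike_times_ms),
    rate_Hz = 1000 * length(x$spike_times_ms) / x$protocol$duration_ms,
    amplitude_pA = x$protocol$amplitude_pA,
    duration_ms = x$protocol$duration_ms,
    dt_ms = x$dt
  )
}

#' @method autoplot izhikevich_sim
#' @export
autoplot.izhikevich_sim <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$time_ms, y = .data$v_mV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = "membrane potential (mV)") +
    ggplot2::theme_minimal()
}

#' Frequency-current (F-I) curve
#'
#' Firing rate (spike count divided by stimulus duration) as a function of
#' step amplitude, swept from 0 to `I_max_pA` in `I_step_pA` increments
#' (default 10 pA).
#'
#' @inheritParams simulate_izhikevich
#' @param I_max_pA Largest step amplitude (pA).
#' @param I_step_pA Amplitude increment (pA, default 10).
#' @param duration_ms Stimulus duration (ms, default 1000).
#' @return Tibble with `amplitude_pA`, `n_spikes`, `rate_Hz` (class
#'   `f_i_curve`).
#' @export
f_i_curve <- function(params, I_max_pA, I_step_pA = 10, duration_ms = 1000,
                      dt = 0.1) {
  if (I_step_pA <= 0) stop("I_step_pA must be positive", call. = FALSE)
  p <- as_izhikevich_params(params)
  amps <- seq(0, I_max_pA, by = I_step_pA)
  rows <- purrr::map(amps, function(amp) {
    sim <- simulate_izhikevich(
      p, step_protocol(amp, duration_ms = duration_ms), dt = dt)
    tibble::tibble(amplitude_pA = amp,
                   n_spikes = length(sim$spike_times_ms),
                   rate_Hz = 1000 * length(sim$spike_times_ms) / duration_ms)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("f_i_curve", class(out))
  out
}

#' @method autoplot f_i_curve
#' @export
autoplot.f_i_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$amplitude_pA, y = .data$rate_Hz)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "injected current (pA)", y = "firing rate (Hz)") +
    ggplot2::theme_minimal()
}

#' Rheobase by bisection
#'
#' Minimal step amplitude that elicits at least one spike under the standard
#' protocol, found by bisection between 0 and `I_hi_pA` to tolerance
#' `tol_pA`. Errors if the model is silent at `I_hi_pA`.
#'
#' @inheritParams simulate_izhikevich
#' @param I_hi_pA Upper bracket (pA); spiking must occur here.
#' @param tol_pA Bisection tolerance (pA, default 1).
#' @param duration_ms Stimulus duration (ms, default 1000).
#' @return Rheobase estimate (pA).
#' @export
rheobase <- function(params, I_hi_pA = 1000, tol_pA = 1, duration_ms = 1000,
                     dt = 0.1) {
  p <- as_izhikevich_params(params)
  spikes_at <- function(amp) {
    length(simulate_izhikevich(
      p, step_protocol(amp, duration_ms = duration_ms), dt = dt
    )$spike_times_ms) > 0
  }
  if (!spikes_at(I_hi_pA)) {
    stop("no spiking at I_hi_pA; raise the upper bracket", call. = FALSE)
  }
  lo <- 0
  hi <- I_hi_pA
  while (hi - lo > tol_pA) {
    mid <- (lo + hi) / 2
    if (spikes_at(mid)) hi <- mid else lo <- mid
  }
  hi
}
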