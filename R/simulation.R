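# Time-stepped co-simulation of all populations and synapse groups:
# vectorized hybrid neuron updates, event-driven TPM state per presynaptic
# neuron, delayed conductance delivery through a ring buffer, and recording
# of spikes, selected traces and per-group absolute synaptic current (the
# LFP-proxy ingredient).

#' Background drive
#'
#' Independent injected current per neuron: a constant mean plus white noise
#' redrawn each step, `I = mean + sd * N(0, 1)`. Either argument may be a
#' named vector keyed by neuron type (a `.default` entry covers the rest) to
#' differentiate populations. Note the noise is discrete per-step noise: its
#' integrated effect depends on the step size, so refinement comparisons
#' should use `sd_pA = 0`.
#'
#' @param mean_pA Mean current (pA); scalar or named by type.
#' @param sd_pA Noise standard deviation (pA); scalar or named by type.
#' @return A `background_drive` object.
#' @export
background_drive <- function(mean_pA = 100, sd_pA = 30) {
  structure(list(mean_pA = mean_pA, sd_pA = sd_pA),
            class = "background_drive")
}

drive_value <- function(x, type_name) {
  if (is.null(names(x))) {
    return(unname(x[1]))
  }
  if (type_name %in% names(x)) {
    return(unname(x[[type_name]]))
  }
  if (".default" %in% names(x)) {
    return(unname(x[[".default"]]))
  }
  stop(sprintf("no drive entry for population \"%s\" (add a \".default\")",
               type_name), call. = FALSE)
}

#' Run a network simulation
#'
#' Advances every population by forward Euler (the same hybrid update as
#' [simulate_izhikevich()]), with conductance-based synapses: per-edge TPM
#' state is updated event-driven at presynaptic spikes, the released
#' conductance arrives at the postsynaptic neuron after the edge's delay,
#' and per-group conductances decay exponentially with the pair's `tau_d`.
#' Given equal `(network, duration, dt, seed)` the result is bit-identical.
#'
#' @param network A `network_spec` from [build_network()].
#' @param duration_ms Simulated time (ms, default 1000).
#' @param dt_ms Time step (ms, default 0.1).
#' @param drive A [background_drive()].
#' @param seed RNG seed for the noise drive (default 1).
#' @param trace_every_ms Trace sampling interval (ms, default 1 = 1 kHz).
#' @param trace_neurons How many neurons per population to record (default
#'   1, the population's first neuron).
#' @return A `simulation_result`: list with `spikes` (tibble `time_ms`,
#'   `neuron`, `population`), `traces` (tibble `time_ms`, `population`,
#'   `neuron`, `v_mV`), `syn_abs` (matrix of summed absolute synaptic
#'   current per step x group, in pA), `group_post` (postsynaptic population
#'   of each group), `populations`, `duration_ms`, `dt_ms`, `seed`.
#' @examples
#' net <- build_network(make_toy_circuit(), scale = 0.05, seed = 1)
#' res <- run_simulation(net, duration_ms = 200, seed = 1)
#' population_rates(res)
#' @export
run_simulation <- function(network, duration_ms = 1000, dt_ms = 0.1,
                           drive = background_drive(), seed = 1,
                           trace_every_ms = 1, trace_neurons = 1) {
  stopifnot(inherits(network, "network_spec"))
  if (dt_ms <= 0) stop("dt_ms must be positive", call. = FALSE)
  pops <- network$populations
  P <- nrow(pops)
  n_steps <- as.integer(round(duration_ms / dt_ms))
  if (P == 0 || n_steps == 0) {
    return(structure(
      list(spikes = tibble::tibble(time_ms = double(), neuron = integer(),
                                   population = character()),
           traces = tibble::tibble(time_ms = double(), population = character(),
                                   neuron = integer(), v_mV = double()),
           syn_abs = matrix(0, 0, 0), group_post = character(),
           populations = pops, duration_ms = duration_ms, dt_ms = dt_ms,
           seed = seed, drive = drive),
      class = "simulation_result"))
  }

  izh <- network$izhikevich
  par <- lapply(pops$type_name, function(nm) {
    row <- izh[izh$name == nm, ]
    if (nrow(row) != 1) {
      stop("no Izhikevich parameters for population ", nm, call. = FALSE)
    }
    as_izhikevich_params(row)
  })
  v <- lapply(seq_len(P), function(p) rep(par[[p]]$Vr, pops$size[p]))
  u <- lapply(seq_len(P), function(p) rep(0, pops$size[p]))
  mean_d <- vapply(pops$type_name, function(nm)
    drive_value(drive$mean_pA, nm), numeric(1))
  sd_d <- vapply(pops$type_name, function(nm)
    drive_value(drive$sd_pA, nm), numeric(1))

  groups <- network$groups
  if (is.null(groups) || nrow(groups) == 0) {
    groups <- tibble::tibble(
      pre = character(), post = character(), probability = double(),
      contacts = double(), g_nS = double(), tau_d_ms = double(),
      tau_r_ms = double(), tau_f_ms = double(), U = double(),
      reversal_mV = double(), n_edges = integer(), edges = list()
    )
  }
  G <- nrow(groups)
  pre_pop <- match(groups$pre, pops$type_name)
  post_pop <- match(groups$post, pops$type_name)
  decay_fac <- exp(-dt_ms / groups$tau_d_ms)
  gcond <- lapply(seq_len(G), function(g) rep(0, pops$size[post_pop[g]]))
  # per-group outgoing adjacency, indexed by presynaptic local neuron and
  # split by discrete delay steps
  out_by_pre <- vector("list", G)
  tpm_R <- vector("list", G)
  tpm_u <- vector("list", G)
  tpm_last <- vector("list", G)
  groups_of_pop <- split(seq_len(G), factor(pre_pop, levels = seq_len(P)))
  max_ds <- 1L
  for (g in seq_len(G)) {
    e <- groups$edges[[g]]
    n_pre <- pops$size[pre_pop[g]]
    ds <- pmax(1L, as.integer(round(e$delay_ms / dt_ms)))
    if (nrow(e) > 0) max_ds <- max(max_ds, max(ds))
    w <- groups$g_nS[g] * groups$contacts[g]
    by_pre <- vector("list", n_pre)
    if (nrow(e) > 0) {
      idx_split <- split(seq_len(nrow(e)), e$pre_index)
      for (nm in names(idx_split)) {
        rows <- idx_split[[nm]]
        by_delay <- split(rows, ds[rows])
        by_pre[[as.integer(nm)]] <- lapply(by_delay, function(r) {
          list(post = e$post_index[r], amt_scale = rep(w, length(r)))
        })
      }
    }
    out_by_pre[[g]] <- by_pre
    tpm_R[[g]] <- rep(1, n_pre)
    tpm_u[[g]] <- rep(0, n_pre)
    tpm_last[[g]] <- rep(-Inf, n_pre)
  }
  L <- max_ds  # ring-buffer length; ds in 1..L never collides within a step
  ring <- vector("list", L)
  for (s in seq_len(L)) ring[[s]] <- list()

  trace_stride <- max(1L, as.integer(round(trace_every_ms / dt_ms)))
  n_trace <- pmin(trace_neurons, pops$size)
  trace_acc <- list()
  spike_t <- list()
  spike_id <- list()
  syn_abs <- matrix(0, n_steps, G)
  first_idx <- pops$first_index

  set.seed(substream_seed(seed, "background-drive"))
  for (step in seq_len(n_steps)) {
    t_now <- step * dt_ms
    slot <- (step - 1L) %% L + 1L
    arrivals <- ring[[slot]]
    ring[[slot]] <- list()
    for (g in seq_len(G)) gcond[[g]] <- gcond[[g]] * decay_fac[g]
    if (length(arrivals) > 0) {
      for (a in arrivals) {
        gc <- gcond[[a[[1]]]]
        gc[a[[2]]] <- gc[a[[2]]] + a[[3]]
        gcond[[a[[1]]]] <- gc
      }
    }
    Isyn <- lapply(pops$size, numeric)
    for (g in seq_len(G)) {
      Ig <- gcond[[g]] * (groups$reversal_mV[g] - v[[post_pop[g]]])
      Isyn[[post_pop[g]]] <- Isyn[[post_pop[g]]] + Ig
      syn_abs[step, g] <- sum(abs(Ig))
    }
    for (p in seq_len(P)) {
      pp <- par[[p]]
      I <- Isyn[[p]] + mean_d[p]
      if (sd_d[p] > 0) I <- I + sd_d[p] * rnorm(pops$size[p])
      vv <- v[[p]]
      uu <- u[[p]]
      v2 <- vv + dt_ms * (pp$k * (vv - pp$Vr) * (vv - pp$Vt) - uu + I) / pp$C
      u2 <- uu + dt_ms * pp$a * (pp$b * (vv - pp$Vr) - uu)
      if (any(!is.finite(v2))) {
        stop(sprintf("non-finite dynamics in population %s at t = %g ms",
                     pops$type_name[p], t_now), call. = FALSE)
      }
      sp <- which(v2 >= pp$Vpeak)
      if (length(sp) > 0) {
        v2[sp] <- pp$Vmin
        u2[sp] <- u2[sp] + pp$d
        k <- length(spike_t) + 1L
        spike_t[[k]] <- rep(t_now, length(sp))
        spike_id[[k]] <- first_idx[p] + sp - 1L
        for (g in groups_of_pop[[p]]) {
          el <- t_now - tpm_last[[g]][sp]
          tr <- groups$tau_r_ms[g]
          tf <- groups$tau_f_ms[g]
          Ug <- groups$U[g]
          Rd <- 1 - (1 - tpm_R[[g]][sp]) * exp(-el / tr)
          ud <- tpm_u[[g]][sp] * exp(-el / tf)
          u_plus <- ud + Ug * (1 - ud)
          rel <- Rd * u_plus
          tpm_R[[g]][sp] <- Rd - rel
          tpm_u[[g]][sp] <- u_plus
          tpm_last[[g]][sp] <- t_now
          ob <- out_by_pre[[g]]
          for (ii in seq_along(sp)) {
            targets <- ob[[sp[ii]]]
            if (is.null(targets)) next
            for (nm in names(targets)) {
              ds <- as.integer(nm)
              tslot <- (step + ds - 1L) %% L + 1L
              tg <- targets[[nm]]
              ring[[tslot]][[length(ring[[tslot]]) + 1L]] <-
                list(g, tg$post, tg$amt_scale * rel[ii])
            }
          }
        }
      }
      v[[p]] <- v2
      u[[p]] <- u2
    }
    if (step %% trace_stride == 0L) {
      k <- length(trace_acc) + 1L
      trace_acc[[k]] <- list(t_now, lapply(seq_len(P), function(p)
        v[[p]][seq_len(n_trace[p])]))
    }
  }

  spikes <- tibble::tibble(
    time_ms = unlist(spike_t) %||% double(),
    neuron = as.integer(unlist(spike_id) %||% integer())
  )
  spikes$population <- pops$type_name[
    findInterval(spikes$neuron, pops$first_index)]
  spikes <- spikes[order(spikes$time_ms, spikes$neuron), ]

  traces <- dplyr::bind_rows(purrr::map(trace_acc, function(rec) {
    tibble::tibble(
      time_ms = rec[[1]],
      population = rep(pops$type_name, n_trace),
      neuron = as.integer(unlist(purrr::map(seq_len(P), function(p)
        first_idx[p] + seq_len(n_trace[p]) - 1L))),
      v_mV = unlist(rec[[2]])
    )
  }))

  structure(
    list(spikes = spikes, traces = traces, syn_abs = syn_abs,
         group_post = pops$type_name[post_pop], populations = pops,
         duration_ms = duration_ms, dt_ms = dt_ms, seed = seed,
         drive = drive),
    class = "simulation_result"
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %g ms at dt=%g ms, %d neurons in %d populations, %d spikes\n",
              x$duration_ms, x$dt_ms, sum(x$populations$size),
              nrow(x$populations), nrow(x$spikes)))
  invisible(x)
}

#' @method tidy simulation_result
#' @export
tidy.simulation_result <- function(x, ...) x$spikes

#' @method glance simulation_result
#' @export
glance.simulation_result <- function(x, ...) {
  tibble::tibble(
    n_populations = nrow(x$populations),
    n_neurons = sum(x$populations$size),
    n_spikes = nrow(x$spikes),
    mean_rate_Hz = if (sum(x$populations$size) > 0) {
      nrow(x$spikes) / sum(x$populations$size) / (x$duration_ms / 1000)
    } else {
      NA_real_
    },
    duration_ms = x$duration_ms,
    dt_ms = x$dt_ms,
    seed = x$seed
  )
}

#' Per-population mean firing rates
#'
#' Spike count divided by population size and duration.
#'
#' @param result A `simulation_result`.
#' @return Tibble with `population`, `n_neurons`, `n_spikes`, `rate_Hz`.
#' @export
population_rates <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  pops <- result$populations
  counts <- table(factor(result$spikes$population, levels = pops$type_name))
  tibble::tibble(
    population = pops$type_name,
    n_neurons = pops$size,
    n_spikes = as.integer(counts),
    rate_Hz = as.integer(counts) / pops$size / (result$duration_ms / 1000)
  )
}

#' Local-field-potential proxy
#'
#' Sum of absolute synaptic currents onto the reference populations (by
#' default all excitatory ones) -- a standard computable stand-in for the
#' extracellular field. Optionally block-averaged down to `downsample_Hz`.
#'
#' @param result A `simulation_result`.
#' @param populations Postsynaptic populations to include (default: the
#'   excitatory ones; must be non-empty).
#' @param downsample_Hz Output sampling rate (default 1000 Hz; `NULL` keeps
#'   the integration step).
#' @return Tibble with `time_ms`, `lfp_pA`, plus a `sample_rate_Hz`
#'   attribute.
#' @export
lfp_proxy <- function(result, populations = NULL, downsample_Hz = 1000) {
  stopifnot(inherits(result, "simulation_result"))
  pops <- result$populations
  if (is.null(populations)) {
    populations <- pops$type_name[pops$polarity == "excitatory"]
  }
  if (length(populations) == 0) {
    stop("the reference population subset is empty", call. = FALSE)
  }
  unknown <- setdiff(populations, pops$type_name)
  if (length(unknown) > 0) {
    stop("unknown population(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  keep <- result$group_post %in% populations
  n_steps <- nrow(result$syn_abs)
  sig <- if (any(keep)) rowSums(result$syn_abs[, keep, drop = FALSE]) else
    rep(0, n_steps)
  fs <- 1000 / result$dt_ms
  t_ms <- seq_len(n_steps) * result$dt_ms
  if (!is.null(downsample_Hz) && downsample_Hz < fs) {
    stride <- as.integer(round(fs / downsample_Hz))
    n_out <- n_steps %/% stride
    idx <- seq_len(n_out * stride)
    sig <- colMeans(matrix(sig[idx], nrow = stride))
    t_ms <- t_ms[seq_len(n_out) * stride]
    fs <- fs / stride
  }
  out <- tibble::tibble(time_ms = t_ms, lfp_pA = sig)
  attr(out, "sample_rate_Hz") <- fs
  out
}

#' Raster plot of a simulation
#'
#' @param object A `simulation_result`.
#' @param ... Unused.
#' @return A ggplot raster (time vs neuron index, colored by population).
#' @method autoplot simulation_result
#' @export
autoplot.simulation_result <- function(object, ...) {
  ggplot2::ggplot(object$spikes,
                  ggplot2::aes(x = .data$time_ms, y = .data$neuron,
                               colour = .data$population)) +
    ggplot2::geom_point(shape = ".", show.legend = TRUE) +
    ggplot2::labs(x = "time (ms)", y = "neuron index") +
    ggplot2::theme_minimal()
}
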