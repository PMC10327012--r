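# Potential connectivity from axonal-dendritic overlap: bouton counts from
# inter-bouton distances, per-parcel hit probabilities, and closed-form
# connection probability / contacts per connected pair, with a Monte-Carlo
# reference route.

#' Expected bouton count along an axon
#'
#' Number of presynaptic boutons an axon places inside a parcel, estimated as
#' axonal length divided by the mean inter-bouton distance. For the rat
#' mossy-fiber circuit, a granule cell's 3,236 um of axon in CA3 with the
#' 67.4 um inter-bouton distance of en-passant/filopodial boutons yields 48
#' contacted interneurons.
#'
#' @param axonal_length_um Axonal length within the parcel (um, >= 0).
#' @param interbouton_um Mean inter-bouton distance (um, > 0).
#' @return Expected bouton count (real, >= 0); vectorized.
#' @examples
#' round(bouton_count(3236, 67.4))  # 48
#' @export
bouton_count <- function(axonal_length_um, interbouton_um) {
  if (any(!is.finite(interbouton_um)) || any(interbouton_um <= 0)) {
    stop("interbouton_um must be positive", call. = FALSE)
  }
  if (any(axonal_length_um < 0)) {
    stop("axonal_length_um must be non-negative", call. = FALSE)
  }
  axonal_length_um / interbouton_um
}

#' Partition total axonal length across a target region's layers
#'
#' Splits a neuron's total axonal length first by the fraction entering the
#' target region, then across that region's layers by the reported per-layer
#' fractions (which must sum to 1).
#'
#' @param total_length_um Total axonal length (um).
#' @param region_fraction Fraction of total length inside the target region,
#'   in \[0, 1\].
#' @param layer_fractions Named numeric vector of per-layer fractions summing
#'   to 1 (e.g. `c(SR = 0.64, SP = 0.15, SO = 0.21)`).
#' @return Tibble with columns `layer` and `length_um`; lengths sum to
#'   `total_length_um * region_fraction`.
#' @examples
#' partition_axonal_length(100000, 0.275, c(SR = 0.64, SP = 0.15, SO = 0.21))
#' @export
partition_axonal_length <- function(total_length_um, region_fraction,
                                    layer_fractions) {
  if (region_fraction < 0 || region_fraction > 1) {
    stop("region_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (any(layer_fractions < 0) || any(layer_fractions > 1)) {
    stop("layer fractions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(layer_fractions) - 1) > 1e-9) {
    stop("layer fractions must sum to 1", call. = FALSE)
  }
  tibble::tibble(
    layer = names(layer_fractions),
    length_um = total_length_um * region_fraction * unname(layer_fractions)
  )
}

#' Average inter-bouton distance across reports
#'
#' Arithmetic mean of independently reported inter-bouton distances;
#' displayed at 0.1 um resolution (the Schaffer-collateral reports 3.7, 4.4
#' and 4.29 um average to 4.13, displayed as 4.1).
#'
#' @param values_um Positive inter-bouton distances (um).
#' @return Mean distance (um); round to one decimal for display.
#' @examples
#' round(mean_interbouton_distance(c(3.7, 4.4, 4.29)), 1)  # 4.1
#' @export
mean_interbouton_distance <- function(values_um) {
  if (length(values_um) == 0) {
    stop("at least one inter-bouton distance is required", call. = FALSE)
  }
  if (any(!is.finite(values_um)) || any(values_um <= 0)) {
    stop("inter-bouton distances must be positive", call. = FALSE)
  }
  mean(values_um)
}

#' Probability that one bouton reaches one target neuron's dendrite
#'
#' Models the dendrite of a single postsynaptic neuron inside a parcel as a
#' cylinder of interaction radius `r` around its dendritic length `Ld`; a
#' bouton placed uniformly at random in the parcel volume `V` falls within
#' reach with probability `min(1, Ld * pi * r^2 / V)`.
#'
#' @param dendritic_length_um Dendritic length of one postsynaptic neuron in
#'   the parcel (um).
#' @param volume_um3 Parcel convex-hull volume (um^3, > 0).
#' @param radius_um Interaction radius (um, > 0; default 1, the order of
#'   bouton plus spine reach).
#' @return Hit probability in \[0, 1\]; vectorized.
#' @examples
#' pair_hit_probability(1000, 1e9)  # ~3.14e-6
#' @export
pair_hit_probability <- function(dendritic_length_um, volume_um3,
                                 radius_um = 1) {
  if (any(volume_um3 <= 0) || any(radius_um <= 0)) {
    stop("volume_um3 and radius_um must be positive", call. = FALSE)
  }
  if (any(dendritic_length_um < 0)) {
    stop("dendritic_length_um must be non-negative", call. = FALSE)
  }
  pmin(1, dendritic_length_um * pi * radius_um^2 / volume_um3)
}

check_parcels <- function(parcels) {
  parcels <- tibble::as_tibble(parcels)
  required <- c("parcel_id", "volume_um3", "axonal_length_um",
                "dendritic_length_um", "interbouton_um")
  missing <- setdiff(required, names(parcels))
  if (length(missing) > 0) {
    stop("parcels table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"radius_um" %in% names(parcels)) parcels$radius_um <- 1
  if (nrow(parcels) == 0) {
    stop("at least one parcel is required", call. = FALSE)
  }
  parcels
}

#' Closed-form connection estimate from parcel geometries
#'
#' For each parcel the presynaptic axon drops `Nb = La / ibd` boutons, each
#' independently hitting the target's dendrite with probability `q` from
#' [pair_hit_probability()]. Across parcels the expected number of synapses
#' is `lambda = sum(Nb * q)`, the probability that the pair is connected at
#' all is `p = 1 - prod((1 - q)^Nb)`, and the contacts per connected pair is
#' the conditional expectation `lambda / p` (undefined, returned as `NA`,
#' when `p = 0`). Always `p <= lambda` and `contacts >= 1` whenever `p > 0`.
#'
#' @param parcels Data frame with columns `parcel_id`, `volume_um3`,
#'   `axonal_length_um`, `dendritic_length_um`, `interbouton_um` and
#'   optionally `radius_um` (default 1).
#' @return One-row tibble with `expected_synapses`, `probability`,
#'   `contacts`.
#' @seealso [simulate_connection()] for the Monte-Carlo reference route.
#' @examples
#' estimate_connection(data.frame(
#'   parcel_id = "CA3:SL", volume_um3 = 1e8, axonal_length_um = 3236,
#'   dendritic_length_um = 2000, interbouton_um = 67.4
#' ))
#' @export
estimate_connection <- function(parcels) {
  parcels <- check_parcels(parcels)
  nb <- bouton_count(parcels$axonal_length_um, parcels$interbouton_um)
  q <- pair_hit_probability(parcels$dendritic_length_um, parcels$volume_um3,
                            parcels$radius_um)
  lambda <- sum(nb * q)
  p <- 1 - prod((1 - q)^nb)
  tibble::tibble(
    expected_synapses = lambda,
    probability = p,
    contacts = if (p > 0) lambda / p else NA_real_
  )
}

#' Monte-Carlo connection estimate by explicit bouton placement
#'
#' Reference route for [estimate_connection()]: in each replicate,
#' `floor(Nb)` boutons per parcel each hit the target independently with
#' probability `q`; the empirical connection probability is the fraction of
#' replicates with at least one hit, and contacts is the mean hit count
#' among connected replicates. Bouton counts are floored here (a simulation
#' needs whole boutons), so compare against the closed form on
#' integer-valued `Nb`.
#'
#' @inheritParams estimate_connection
#' @param n_rep Number of replicates (default 1e5).
#' @param seed Optional RNG seed (caller's RNG state is preserved).
#' @return One-row tibble with `probability`, `contacts`, their standard
#'   errors, and `n_rep`.
#' @export
simulate_connection <- function(parcels, n_rep = 1e5, seed = NULL) {
  parcels <- check_parcels(parcels)
  nb <- floor(bouton_count(parcels$axonal_length_um, parcels$interbouton_um))
  q <- pair_hit_probability(parcels$dendritic_length_um, parcels$volume_um3,
                            parcels$radius_um)
  with_preserved_seed(seed, {
    hits <- rep(0, n_rep)
    for (k in seq_len(nrow(parcels))) {
      if (nb[k] >= 1 && q[k] > 0) {
        hits <- hits + rbinom(n_rep, size = nb[k], prob = q[k])
      }
    }
    connected <- hits > 0
    p_hat <- mean(connected)
    c_hat <- if (any(connected)) mean(hits[connected]) else NA_real_
    tibble::tibble(
      probability = p_hat,
      probability_se = sqrt(p_hat * (1 - p_hat) / n_rep),
      contacts = c_hat,
      contacts_se = if (sum(connected) > 1) {
        sd(hits[connected]) / sqrt(sum(connected))
      } else {
        NA_real_
      },
      n_rep = n_rep
    )
  })
}

#' Multiscale connectivity summary of a knowledge base
#'
#' Aggregates the directed connection table at one of three levels:
#' `"subregion"` (edge weight = number of connected type pairs between the
#' two subregions), `"type"` (one edge per connection row; weight =
#' probability) or `"pair"` (identical edges, but named for per-pair use).
#' Only rows with positive probability count as connections.
#'
#' @param kb A [knowledge_base()].
#' @param level `"subregion"`, `"type"` or `"pair"`.
#' @return Tibble with columns `pre`, `post`, `weight` and, at subregion
#'   level, `n_pairs`.
#' @export
aggregate_connectivity <- function(kb, level = c("subregion", "type", "pair")) {
  stopifnot(inherits(kb, "knowledge_base"))
  level <- match.arg(level)
  cn <- dplyr::filter(kb$connections, .data$probability > 0)
  if (level == "subregion") {
    nt <- kb$neuron_types
    cn$pre_sub <- nt$subregion[match(cn$pre, nt$name)]
    cn$post_sub <- nt$subregion[match(cn$post, nt$name)]
    out <- dplyr::summarise(
      dplyr::group_by(cn, pre = .data$pre_sub, post = .data$post_sub),
      n_pairs = dplyr::n(), .groups = "drop"
    )
    out$weight <- as.numeric(out$n_pairs)
    return(out[, c("pre", "post", "weight", "n_pairs")])
  }
  tibble::tibble(pre = cn$pre, post = cn$post, weight = cn$probability)
}

#' Synaptic transfer function
#'
#' Product of the unitary synaptic conductance and the single-exponential
#' decay time constant, `g * tau_d` -- proportional to the total charge a
#' unitary event transfers, and the standard scalar summary of connection
#' strength between two types.
#'
#' @param g_nS Peak unitary conductance (nS, > 0).
#' @param tau_d_ms Decay time constant (ms, > 0).
#' @return Transfer function (nS ms); vectorized.
#' @examples
#' transfer_function(0.5, 4)  # 2
#' @export
transfer_function <- function(g_nS, tau_d_ms) {
  if (any(g_nS <= 0) || any(tau_d_ms <= 0)) {
    stop("g_nS and tau_d_ms must be positive", call. = FALSE)
  }
  g_nS * tau_d_ms
}

#' Read a parcel-geometry table
#'
#' Columns: `parcel_id` (subregion:layer label), `volume_um3`,
#' `axonal_length_um`, `dendritic_length_um`, `interbouton_um`, and optional
#' `radius_um` and `target`.
#'
#' @param path CSV file path.
#' @return Tibble of parcel geometries.
#' @export
read_parcels <- function(path) {
  tibble::as_tibble(readr::read_csv(path, col_types = readr::cols(
    parcel_id = "c", .default = readr::col_guess()
  ), progress = FALSE))
}
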