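# Synthetic-input generators: toy and randomized knowledge bases for tests,
# the CA3-like eight-type demo circuit, and the printed-parameter
# mossy-fiber / Schaffer-collateral connectivity scenarios. All parameter
# magnitudes are package-defined physiologically plausible fixtures (resting
# potentials in the -45 to -75 mV range, fast-spiking interneurons vs
# regular-spiking principal cells); none are measured values.

fixture_rs_row <- function() {
  # regular-spiking principal cell
  tibble::tibble(C_pF = 100, k_nS_per_mV = 0.7, Vr_mV = -60, Vt_mV = -40,
                 Vpeak_mV = 35, Vmin_mV = -50, a_per_ms = 0.03, b_nS = -2,
                 d_pA = 100, is_default = FALSE)
}

fixture_fs_row <- function(a = 0.15, d = 10) {
  # fast-spiking interneuron
  tibble::tibble(C_pF = 20, k_nS_per_mV = 1, Vr_mV = -55, Vt_mV = -40,
                 Vpeak_mV = 25, Vmin_mV = -45, a_per_ms = a, b_nS = 0.5,
                 d_pA = d, is_default = FALSE)
}

fixture_syn_row <- function(pre_polarity, jitter = 0) {
  if (pre_polarity == "excitatory") {
    tibble::tibble(g_nS = 0.6 * (1 + jitter), tau_d_ms = 4, tau_r_ms = 400,
                   tau_f_ms = 30, U = 0.4, is_default = FALSE)
  } else {
    tibble::tibble(g_nS = 1.2 * (1 + jitter), tau_d_ms = 8, tau_r_ms = 500,
                   tau_f_ms = 20, U = 0.25, is_default = FALSE)
  }
}

#' Toy four-type circuit
#'
#' A deterministic two-subregion fixture: two excitatory and two inhibitory
#' types spanning DG and CA3, with a complete census, neuron models, all 12
#' non-self directed connection rows and matching synapse rows. Passes every
#' knowledge-base validator by construction.
#'
#' @param seed Seed controlling the small deterministic jitter applied to
#'   probabilities and conductances (default 1).
#' @return A validated [knowledge_base()].
#' @examples
#' glance(make_toy_circuit())
#' @export
make_toy_circuit <- function(seed = 1) {
  nt <- tibble::tibble(
    name = c("DG Granule", "DG Basket", "CA3 Pyramidal", "CA3 Basket"),
    subregion = c("DG", "DG", "CA3", "CA3"),
    polarity = c("excitatory", "inhibitory", "excitatory", "inhibitory"),
    rank = c(1, 2, 1, 2),
    laminar_code = c("2231p", "2232", "22233p", "22032")
  )
  census <- tibble::tibble(name = nt$name, species = "mouse",
                           count = c(500, 100, 300, 80))
  izh <- dplyr::bind_cols(
    tibble::tibble(name = nt$name),
    dplyr::bind_rows(fixture_rs_row(), fixture_fs_row(0.15, 10),
                     fixture_rs_row(), fixture_fs_row(0.2, 20))
  )
  pairs <- tidyr::expand_grid(pre = nt$name, post = nt$name)
  pairs <- pairs[pairs$pre != pairs$post, ]
  jit <- with_preserved_seed(seed, runif(nrow(pairs), -0.2, 0.2))
  pol <- nt$polarity[match(pairs$pre, nt$name)]
  cn <- tibble::tibble(
    pre = pairs$pre, post = pairs$post,
    probability = round(ifelse(pol == "excitatory", 0.02, 0.06) *
                          (1 + jit), 5),
    contacts = round(ifelse(pol == "excitatory", 2, 4) * (1 + jit / 2), 2),
    is_default = FALSE
  )
  sy <- dplyr::bind_cols(
    pairs,
    dplyr::bind_rows(purrr::map2(pol, jit, function(p, j)
      fixture_syn_row(p, j / 2)))
  )
  knowledge_base(nt, census, izh, cn, sy)
}

#' CA3-like eight-type demo circuit
#'
#' One excitatory Pyramidal population plus the seven main inhibitory
#' interneuron types of the CA3 circuit -- Axo-Axonic, Basket, Basket CCK+,
#' Bistratified, Ivy, Mossy Fiber-Associated ORDEN, and QuadD-LM cells.
#' Census counts are chosen so that `scale = 0.005` instantiates 500
#' Pyramidal cells and 50 of each interneuron type (850 neurons). Neuron
#' models, probabilities and synapse constants are plausible fixtures
#' (regular-spiking principal cell, fast-spiking interneurons, depressing
#' excitatory and inhibitory synapses), not measured values.
#'
#' @param seed Seed for the deterministic jitter on interneuron parameters
#'   (default 1).
#' @return A validated [knowledge_base()] with a complete 64-row connection
#'   table (unconnected pairs carry probability 0).
#' @examples
#' kb <- make_ca3_demo()
#' kb$neuron_types$name
#' @seealso [ca3_demo_drive()] for the matching background drive.
#' @export
make_ca3_demo <- function(seed = 1) {
  ins <- c("CA3 Axo-Axonic", "CA3 Basket", "CA3 Basket CCK+",
           "CA3 Bistratified", "CA3 Ivy", "CA3 MFA ORDEN", "CA3 QuadD-LM")
  nt <- tibble::tibble(
    name = c("CA3 Pyramidal", ins),
    subregion = "CA3",
    polarity = c("excitatory", rep("inhibitory", 7)),
    rank = c(1, 2, 1, 2, 2, 2, 2, 2),
    laminar_code = c("22233p", "00030", "02232", "22232", "02220", "02330",
                     "00332", "32200")
  )
  census <- tibble::tibble(name = nt$name, species = "mouse",
                           count = c(100000, rep(10000, 7)))
  jit <- with_preserved_seed(seed, runif(7, -0.25, 0.25))
  izh <- dplyr::bind_cols(
    tibble::tibble(name = nt$name),
    dplyr::bind_rows(c(list(fixture_rs_row()),
                       purrr::map(seq_len(7), function(i)
                         fixture_fs_row(a = 0.1 + 0.05 * (1 + jit[i]),
                                        d = 10 + 10 * (1 + jit[i])))))
  )
  # measured-style sparse motif: Pyramidal cells excite every interneuron
  # type and themselves; every interneuron type inhibits Pyramidal cells;
  # a few interneuron-interneuron motifs; all other pairs are explicit
  # zero-probability rows so the table is complete.
  nonzero <- dplyr::bind_rows(
    tibble::tibble(pre = "CA3 Pyramidal", post = "CA3 Pyramidal",
                   probability = 0.01, contacts = 2),
    tibble::tibble(pre = "CA3 Pyramidal", post = ins, probability = 0.02,
                   contacts = 2),
    tibble::tibble(pre = ins, post = "CA3 Pyramidal", probability = 0.08,
                   contacts = 3),
    tibble::tibble(
      pre = c("CA3 Basket", "CA3 Basket", "CA3 Basket CCK+",
              "CA3 Bistratified", "CA3 Ivy"),
      post = c("CA3 Basket", "CA3 Basket CCK+", "CA3 Basket",
               "CA3 Basket", "CA3 Ivy"),
      probability = 0.03, contacts = 3)
  )
  grid <- tidyr::expand_grid(pre = nt$name, post = nt$name)
  zero <- dplyr::anti_join(grid, nonzero, by = c("pre", "post"))
  zero$probability <- 0
  zero$contacts <- NA_real_
  cn <- dplyr::arrange(dplyr::bind_rows(nonzero, zero), .data$pre, .data$post)
  cn$is_default <- FALSE
  live <- nonzero[, c("pre", "post")]
  pol <- nt$polarity[match(live$pre, nt$name)]
  sy <- dplyr::bind_cols(
    live, dplyr::bind_rows(purrr::map(pol, fixture_syn_row))
  )
  knowledge_base(nt, census, izh, cn, sy)
}

#' Knowledge base with a known fraction of connection rows removed
#'
#' Starts from [make_toy_circuit()] and keeps a deterministic random subset
#' of the connection rows, for exercising
#' [fill_missing_probabilities()]: at `completeness = 1` the fill step is a
#' no-op; at `completeness = 0` every post-fill row is a flagged default.
#'
#' @param completeness Fraction of connection rows retained, in \[0, 1\].
#' @param seed Seed for the subset draw (default 1).
#' @return A validated [knowledge_base()].
#' @export
make_incomplete_kb <- function(completeness = 0.5, seed = 1) {
  if (completeness < 0 || completeness > 1) {
    stop("completeness must lie in [0, 1]", call. = FALSE)
  }
  kb <- make_toy_circuit(seed)
  n <- nrow(kb$connections)
  keep_n <- round_half_up(completeness * n)
  keep <- with_preserved_seed(seed, sort(sample.int(n, keep_n)))
  kb$connections <- kb$connections[keep, ]
  validate_knowledge_base(kb)
}

#' Mossy-fiber worked-example parcel table
#'
#' The rat dentate-gyrus-to-CA3 mossy-fiber scenario with its printed
#' anatomical constants: 3,236 um of granule-cell axon inside CA3, all of it
#' in stratum lucidum (SL) -- the SP rows carry zero axonal length --
#' and inter-bouton distances of 162 um (CA3c Pyramidal targets), 284 um
#' (Pyramidal targets in the rest of CA3) and 67.4 um (en-passant/filopodial
#' boutons onto interneurons, i.e. one granule cell can contact 48
#' interneurons). Parcel hull volumes and per-target dendritic lengths are
#' synthetic placeholders (`volume_is_placeholder = TRUE`); the inter-bouton
#' distances and axonal length are the printed constants.
#'
#' @return Tibble of parcel geometries with a `target` column.
#' @examples
#' sc <- make_mossy_fiber_scenario()
#' round(bouton_count(3236, sc$interbouton_um[sc$target == "CA3 interneuron" &
#'                                            sc$axonal_length_um > 0]))
#' @export
make_mossy_fiber_scenario <- function() {
  tibble::tibble(
    target = rep(c("CA3 interneuron", "CA3c Pyramidal", "CA3 Pyramidal"),
                 each = 2),
    parcel_id = rep(c("CA3:SL", "CA3:SP"), 3),
    volume_um3 = 1.0e8,
    axonal_length_um = rep(c(3236, 0), 3),
    dendritic_length_um = rep(c(1200, 2600, 2600), each = 2),
    interbouton_um = rep(c(67.4, 162, 284), each = 2),
    radius_um = 1,
    volume_is_placeholder = TRUE
  )
}

#' Schaffer-collateral worked-example inputs
#'
#' The printed axonal-partition and inter-bouton constants for the CA3/CA3c
#' Pyramidal projections to CA1: CA3 Pyramidal cells send 27.5% of their
#' total axonal length to CA1 (64% to stratum radiatum, 15% to stratum
#' pyramidale, 21% to stratum oriens) and CA3c Pyramidal cells 64.1% (94% /
#' 3% / 3%); the generic Schaffer inter-bouton distances are 4.47 um (SR)
#' and 5.8 um (SO); the CA3c-specific SR value is 5.5 um; and the three
#' independent CA3 SR reports 3.7, 4.4 and 4.29 um average to 4.1 um.
#'
#' @return List with elements `sr_interbouton_reports_um`, `ca3` and `ca3c`
#'   (each with `region_fraction`, `layer_fractions`, `interbouton_um`).
#' @examples
#' sc <- make_schaffer_scenario()
#' round(mean_interbouton_distance(sc$sr_interbouton_reports_um), 1)  # 4.1
#' @export
make_schaffer_scenario <- function() {
  list(
    sr_interbouton_reports_um = c(3.7, 4.4, 4.29),
    ca3 = list(region_fraction = 0.275,
               layer_fractions = c(SR = 0.64, SP = 0.15, SO = 0.21),
               interbouton_um = c(SR = 4.47, SO = 5.8)),
    ca3c = list(region_fraction = 0.641,
                layer_fractions = c(SR = 0.94, SP = 0.03, SO = 0.03),
                interbouton_um = c(SR = 5.5, SO = 5.8))
  )
}

#' Randomized knowledge base for property tests
#'
#' Generates `n_types` synthetic types with random subregions, polarities,
#' ranks and laminar codes, plausible jittered neuron models and synapse
#' constants, and a `completeness` fraction of the possible directed
#' connection rows. Deterministic per seed, and valid for every seed.
#'
#' @param n_types Number of types (default 6).
#' @param completeness Fraction of directed pairs given a connection row
#'   (default 1).
#' @param seed RNG seed.
#' @return A validated [knowledge_base()].
#' @export
make_random_kb <- function(n_types = 6, completeness = 1, seed = 1) {
  with_preserved_seed(seed, {
    nm <- paste0("T", seq_len(n_types), " ",
                 sample(c("Pyramidal", "Granule", "Basket", "Ivy", "Axo-Axonic",
                          "Bistratified"), n_types, replace = TRUE))
    nt <- tibble::tibble(
      name = nm,
      subregion = sample(SUBREGIONS, n_types, replace = TRUE),
      polarity = sample(POLARITIES, n_types, replace = TRUE),
      rank = as.numeric(sample(1:5, n_types, replace = TRUE)),
      laminar_code = vapply(seq_len(n_types), function(i) {
        paste0(paste(sample(0:3, sample(3:6, 1), replace = TRUE),
                     collapse = ""),
               if (runif(1) < 0.3) "p" else "")
      }, character(1))
    )
    census <- tibble::tibble(name = nm, species = sample(SPECIES_LEVELS, 1),
                             count = as.numeric(sample(50:5000, n_types, replace = TRUE)))
    izh <- dplyr::bind_cols(
      tibble::tibble(name = nm),
      dplyr::bind_rows(purrr::map(nt$polarity, function(p) {
        base <- if (p == "excitatory") fixture_rs_row() else fixture_fs_row()
        base$C_pF <- base$C_pF * runif(1, 0.8, 1.2)
        base$d_pA <- base$d_pA * runif(1, 0.5, 1.5)
        base
      }))
    )
    pairs <- tidyr::expand_grid(pre = nm, post = nm)
    keep <- sort(sample.int(nrow(pairs),
                            round_half_up(completeness * nrow(pairs))))
    pairs <- pairs[keep, ]
    pol <- nt$polarity[match(pairs$pre, nt$name)]
    cn <- tibble::tibble(
      pre = pairs$pre, post = pairs$post,
      probability = round(runif(nrow(pairs), 0, 0.3), 5),
      contacts = round(runif(nrow(pairs), 1, 8), 2),
      is_default = FALSE
    )
    sy <- if (nrow(pairs) > 0) {
      dplyr::bind_cols(
        pairs[, c("pre", "post")],
        dplyr::bind_rows(purrr::map(pol, function(p)
          fixture_syn_row(p, runif(1, -0.3, 0.3))))
      )
    } else {
      NULL
    }
    knowledge_base(nt, census, izh, cn, sy)
  })
}

#' Background drive matched to the CA3-like demo circuit
#'
#' Package-chosen resting-state drive for [make_ca3_demo()]: a stronger mean
#' current to the regular-spiking Pyramidal population (whose capacitance is
#' five times the interneurons\') and a weaker one to the fast-spiking
#' interneurons, keeping every population moderately active rather than
#' saturated.
#'
#' @return A [background_drive()] with named per-type means.
#' @export
ca3_demo_drive <- function() {
  background_drive(mean_pA = c("CA3 Pyramidal" = 150, .default = 70),
                   sd_pA = 30)
}
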