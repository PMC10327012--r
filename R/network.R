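# Network instantiation: populations from census counts (with scaling),
# Bernoulli wiring per directed type pair, per-edge synapse parameters and
# delays, and lossless text export/import.

#' Instantiate populations from census counts
#'
#' One population per retained type with size
#' `max(1, round_half_up(scale * count))` (a scaled type never vanishes) and
#' contiguous, gapless 1-based global index ranges in type order.
#'
#' @param kb A [knowledge_base()] whose census covers every type.
#' @param scale Population scaling factor in (0, 1\].
#' @return Tibble with `type_name`, `subregion`, `polarity`, `size`,
#'   `first_index` (global index of the population's first neuron).
#' @examples
#' build_populations(make_toy_circuit(), scale = 0.1)
#' @export
build_populations <- function(kb, scale = 1) {
  stopifnot(inherits(kb, "knowledge_base"))
  if (scale <= 0 || scale > 1) {
    stop("scale must lie in (0, 1]", call. = FALSE)
  }
  nt <- kb$neuron_types
  counts <- kb$census$count[match(nt$name, kb$census$name)]
  if (anyNA(counts)) {
    stop("census is missing counts for: ",
         paste(nt$name[is.na(counts)], collapse = ", "), call. = FALSE)
  }
  size <- pmax(1, round_half_up(scale * counts))
  tibble::tibble(
    type_name = nt$name, subregion = nt$subregion, polarity = nt$polarity,
    size = as.integer(size),
    first_index = as.integer(cumsum(c(1, size))[seq_along(size)])
  )
}

#' Bernoulli wiring between two populations
#'
#' Each ordered pair `(i, j)` -- excluding self-pairs when the populations
#' are the same (`recurrent = TRUE`) -- is included independently with the
#' given probability. Implemented by drawing the edge count from
#' `Binomial(M, p)` and then choosing that many distinct pairs uniformly,
#' which yields exactly the independent-Bernoulli edge-set distribution.
#'
#' @param n_pre,n_post Population sizes.
#' @param probability Connection probability in \[0, 1\].
#' @param recurrent Populations are the same (self-edges `i -> i` excluded).
#' @param seed Optional RNG seed for a reproducible draw (caller's RNG state
#'   is preserved).
#' @return Tibble with local 1-based `pre_index`, `post_index`.
#' @examples
#' nrow(wire_bernoulli(10, 10, 1))  # 100
#' @export
wire_bernoulli <- function(n_pre, n_post, probability, recurrent = FALSE,
                           seed = NULL) {
  if (probability < 0 || probability > 1) {
    stop("probability must lie in [0, 1]", call. = FALSE)
  }
  if (recurrent && n_pre != n_post) {
    stop("recurrent wiring requires n_pre == n_post", call. = FALSE)
  }
  M <- if (recurrent) as.numeric(n_pre) * (n_post - 1) else
    as.numeric(n_pre) * n_post
  if (M == 0 || probability == 0) {
    return(tibble::tibble(pre_index = integer(), post_index = integer()))
  }
  with_preserved_seed(seed, {
    n_edges <- rbinom(1, size = M, prob = probability)
    idx <- if (n_edges > 0) sort(sample.int(M, n_edges)) else integer(0)
    if (recurrent) {
      # column-major over the n x (n-1) off-diagonal grid: column j lists
      # all presynaptic rows except j itself
      j <- (idx - 1) %/% (n_pre - 1) + 1
      r <- (idx - 1) %% (n_pre - 1) + 1
      i <- r + (r >= j)
    } else {
      i <- (idx - 1) %% n_pre + 1
      j <- (idx - 1) %/% n_pre + 1
    }
    tibble::tibble(pre_index = as.integer(i), post_index = as.integer(j))
  })
}

#' Attach synapse parameters and conduction delays to an edge list
#'
#' Every edge of a directed type pair carries the pair's TPM parameters, a
#' weight scale equal to the pair's contacts per connected pair (scaling the
#' conductance instead of creating multi-edges), and a delay drawn uniformly
#' from `delay_range_ms` (a degenerate range gives a constant delay).
#'
#' @param edges Edge list from [wire_bernoulli()].
#' @param tpm A [tpm_params()] (or coercible) for the pair.
#' @param contacts Expected contacts per connected pair (>= 1, default 1).
#' @param delay_range_ms Length-2 delay bounds in ms (default `c(1, 2)`).
#' @param reversal_mV Synaptic reversal potential (mV).
#' @param seed Optional RNG seed for the delay draw.
#' @return A `synapse_group` list: `edges` (with `delay_ms`), `tpm`,
#'   `contacts`, `reversal_mV`.
#' @export
assign_synapses <- function(edges, tpm, contacts = 1,
                            delay_range_ms = c(1, 2), reversal_mV = 0,
                            seed = NULL) {
  if (length(delay_range_ms) != 2 || delay_range_ms[1] > delay_range_ms[2] ||
      delay_range_ms[1] <= 0) {
    stop("delay_range_ms must be positive and nondecreasing", call. = FALSE)
  }
  tpm <- as_tpm_params(tpm)
  edges <- tibble::as_tibble(edges)
  edges$delay_ms <- with_preserved_seed(seed, {
    if (delay_range_ms[1] == delay_range_ms[2]) {
      rep(delay_range_ms[1], nrow(edges))
    } else {
      runif(nrow(edges), delay_range_ms[1], delay_range_ms[2])
    }
  })
  structure(list(edges = edges, tpm = tpm, contacts = contacts,
                 reversal_mV = reversal_mV),
            class = "synapse_group")
}

#' Build a simulatable network from a knowledge base
#'
#' Completes the knowledge base (filling unmeasured probabilities, synapse
#' constants and neuron models with flagged defaults), instantiates one
#' population per type via [build_populations()], and wires one synapse
#' group per connection row with positive probability via
#' [wire_bernoulli()] and [assign_synapses()]. Each pair's wiring and delay
#' draws use a substream seed derived from the master seed and the pair's
#' names, so adding or removing a type does not perturb other pairs'
#' realizations; equal `(kb, scale, seed)` give identical networks.
#'
#' @param kb A [knowledge_base()].
#' @param scale Population scaling in (0, 1\] (default 1 = census scale).
#' @param seed Master seed (default 1).
#' @param delay_range_ms Uniform conduction-delay bounds in ms (default
#'   `c(1, 2)`; the knowledge base carries no delays).
#' @param reversal_excitatory_mV,reversal_inhibitory_mV Synaptic reversal
#'   potentials by presynaptic polarity (defaults 0 and -70 mV).
#' @return A `network_spec`: list with `populations`, `izhikevich`,
#'   `groups` (tibble with one row per directed pair, edges nested in a
#'   list-column), `scale`, `master_seed`.
#' @examples
#' net <- build_network(make_toy_circuit(), scale = 0.1, seed = 42)
#' net
#' @export
build_network <- function(kb, scale = 1, seed = 1, delay_range_ms = c(1, 2),
                          reversal_excitatory_mV = 0,
                          reversal_inhibitory_mV = -70) {
  stopifnot(inherits(kb, "knowledge_base"))
  kb <- fill_missing_probabilities(kb)
  kb <- fill_missing_synapses(kb)
  kb <- fill_missing_izhikevich(kb)
  pops <- build_populations(kb, scale)
  cn <- dplyr::filter(kb$connections, .data$probability > 0)
  sy <- kb$synapses
  rows <- vector("list", nrow(cn))
  for (g in seq_len(nrow(cn))) {
    pre <- cn$pre[g]
    post <- cn$post[g]
    n_pre <- pops$size[match(pre, pops$type_name)]
    n_post <- pops$size[match(post, pops$type_name)]
    recurrent <- pre == post
    edges <- wire_bernoulli(n_pre, n_post, cn$probability[g],
                            recurrent = recurrent,
                            seed = substream_seed(seed, "wire", pre, post))
    syn_row <- sy[sy$pre == pre & sy$post == post, ]
    if (nrow(syn_row) != 1) {
      stop(sprintf("no synapse parameters for pair %s -> %s", pre, post),
           call. = FALSE)
    }
    reversal <- if (kb_polarity(kb, pre) == "excitatory") {
      reversal_excitatory_mV
    } else {
      reversal_inhibitory_mV
    }
    grp <- assign_synapses(edges, syn_row, contacts = cn$contacts[g],
                           delay_range_ms = delay_range_ms,
                           reversal_mV = reversal,
                           seed = substream_seed(seed, "delay", pre, post))
    rows[[g]] <- tibble::tibble(
      pre = pre, post = post, probability = cn$probability[g],
      contacts = cn$contacts[g], g_nS = syn_row$g_nS,
      tau_d_ms = syn_row$tau_d_ms, tau_r_ms = syn_row$tau_r_ms,
      tau_f_ms = syn_row$tau_f_ms, U = syn_row$U, reversal_mV = reversal,
      n_edges = nrow(grp$edges), edges = list(grp$edges)
    )
  }
  structure(
    list(populations = pops, izhikevich = kb$izhikevich,
         groups = dplyr::bind_rows(rows), scale = scale, master_seed = seed),
    class = "network_spec"
  )
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> %d populations, %d neurons, %d synapse groups, %d edges (scale=%g, seed=%d)\n",
              nrow(x$populations), sum(x$populations$size), nrow(x$groups),
              sum(x$groups$n_edges), x$scale, x$master_seed))
  invisible(x)
}

#' @method glance network_spec
#' @export
glance.network_spec <- function(x, ...) {
  tibble::tibble(
    n_populations = nrow(x$populations),
    n_neurons = sum(x$populations$size),
    n_groups = nrow(x$groups),
    n_edges = sum(x$groups$n_edges),
    scale = x$scale,
    master_seed = x$master_seed
  )
}

#' @method tidy network_spec
#' @export
tidy.network_spec <- function(x, ...) {
  tidyr::unnest(x$groups[, c("pre", "post", "edges")], "edges")
}

#' Write and read an instantiated network as plain text
#'
#' Four CSV files in one directory: `populations.csv`
#' (`name,size,first_index`), `groups.csv` (per directed pair: probability,
#' contacts, TPM constants, reversal), `edges.csv`
#' (`pre_index,post_index,group,delay_ms,weight_scale`, global indices) and
#' `izhikevich.csv`, plus `network_meta.csv` (scale, master seed). Re-import
#' is lossless.
#'
#' @param network A `network_spec` from [build_network()].
#' @param path Directory.
#' @return `write_network()` the file paths invisibly; `read_network()` the
#'   reconstructed `network_spec`.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "network_spec"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  pops <- network$populations
  write_csv_exact(
    tibble::tibble(name = pops$type_name, subregion = pops$subregion,
                   polarity = pops$polarity, size = pops$size,
                   first_index = pops$first_index),
    file.path(path, "populations.csv"))
  groups <- network$groups
  write_csv_exact(
    dplyr::mutate(groups[, setdiff(names(groups), "edges")],
                  group = dplyr::row_number(), .before = 1),
    file.path(path, "groups.csv"))
  first <- setNames(pops$first_index, pops$type_name)
  edge_rows <- purrr::map(seq_len(nrow(groups)), function(g) {
    e <- groups$edges[[g]]
    tibble::tibble(
      pre_index = e$pre_index + first[[groups$pre[g]]] - 1L,
      post_index = e$post_index + first[[groups$post[g]]] - 1L,
      group = g, delay_ms = e$delay_ms, weight_scale = groups$contacts[g]
    )
  })
  write_csv_exact(dplyr::bind_rows(edge_rows), file.path(path, "edges.csv"))
  write_csv_exact(network$izhikevich, file.path(path, "izhikevich.csv"))
  write_csv_exact(
    tibble::tibble(scale = network$scale, master_seed = network$master_seed),
    file.path(path, "network_meta.csv"))
  invisible(file.path(path, c("populations.csv", "groups.csv", "edges.csv",
                              "izhikevich.csv", "network_meta.csv")))
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  pops_raw <- read_csv_exact(file.path(path, "populations.csv"),
                             c(name = "c", subregion = "c", polarity = "c",
                               size = "i", first_index = "i"))
  pops <- tibble::tibble(type_name = pops_raw$name,
                         subregion = pops_raw$subregion,
                         polarity = pops_raw$polarity, size = pops_raw$size,
                         first_index = pops_raw$first_index)
  groups <- read_csv_exact(
    file.path(path, "groups.csv"),
    c(group = "i", pre = "c", post = "c", probability = "d", contacts = "d",
      g_nS = "d", tau_d_ms = "d", tau_r_ms = "d", tau_f_ms = "d", U = "d",
      reversal_mV = "d", n_edges = "i"))
  edges <- read_csv_exact(file.path(path, "edges.csv"),
                          c(pre_index = "i", post_index = "i", group = "i",
                            delay_ms = "d", weight_scale = "d"))
  izh <- read_csv_exact(file.path(path, "izhikevich.csv"),
                        kb_col_types$izhikevich)
  meta <- read_csv_exact(file.path(path, "network_meta.csv"),
                         c(scale = "d", master_seed = "i"))
  first <- setNames(pops$first_index, pops$type_name)
  nested <- purrr::map(seq_len(nrow(groups)), function(g) {
    e <- edges[edges$group == g, ]
    tibble::tibble(
      pre_index = as.integer(e$pre_index - first[[groups$pre[g]]] + 1L),
      post_index = as.integer(e$post_index - first[[groups$post[g]]] + 1L),
      delay_ms = e$delay_ms
    )
  })
  groups$edges <- nested
  groups$n_edges <- vapply(nested, nrow, integer(1))
  groups$group <- NULL
  structure(
    list(populations = pops, izhikevich = izh, groups = groups,
         scale = meta$scale[1], master_seed = as.integer(meta$master_seed[1])),
    class = "network_spec"
  )
}
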