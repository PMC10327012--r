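# Parameter-table data model: neuron types, census counts, Izhikevich neuron
# models, directed connection probabilities, and TPM synapse constants,
# cross-indexed into a single validated knowledge base.

SUBREGIONS <- c("DG", "CA3", "CA2", "CA1", "Sub", "EC")
POLARITIES <- c("excitatory", "inhibitory")
SPECIES_LEVELS <- c("rat", "mouse")

KB_TABLES <- c("neuron_types", "census", "izhikevich", "connections", "synapses")

KB_COLUMNS <- list(
  neuron_types = c("name", "subregion", "polarity", "rank", "laminar_code"),
  census       = c("name", "species", "count"),
  izhikevich   = c("name", "C_pF", "k_nS_per_mV", "Vr_mV", "Vt_mV", "Vpeak_mV",
                   "Vmin_mV", "a_per_ms", "b_nS", "d_pA", "is_default"),
  connections  = c("pre", "post", "probability", "contacts", "is_default"),
  synapses     = c("pre", "post", "g_nS", "tau_d_ms", "tau_r_ms", "tau_f_ms",
                   "U", "is_default")
)

kb_col_types <- list(
  neuron_types = c(name = "c", subregion = "c", polarity = "c", rank = "d",
                   laminar_code = "c"),
  census = c(name = "c", species = "c", count = "d"),
  izhikevich = c(name = "c", C_pF = "d", k_nS_per_mV = "d", Vr_mV = "d",
                 Vt_mV = "d", Vpeak_mV = "d", Vmin_mV = "d", a_per_ms = "d",
                 b_nS = "d", d_pA = "d", is_default = "l"),
  connections = c(pre = "c", post = "c", probability = "d", contacts = "d",
                  is_default = "l"),
  synapses = c(pre = "c", post = "c", g_nS = "d", tau_d_ms = "d",
               tau_r_ms = "d", tau_f_ms = "d", U = "d", is_default = "l")
)

empty_kb_table <- function(table) {
  proto <- list(
    neuron_types = tibble::tibble(name = character(), subregion = character(),
                                  polarity = character(), rank = double(),
                                  laminar_code = character()),
    census = tibble::tibble(name = character(), species = character(),
                            count = double()),
    izhikevich = tibble::tibble(name = character(), C_pF = double(),
                                k_nS_per_mV = double(), Vr_mV = double(),
                                Vt_mV = double(), Vpeak_mV = double(),
                                Vmin_mV = double(), a_per_ms = double(),
                                b_nS = double(), d_pA = double(),
                                is_default = logical()),
    connections = tibble::tibble(pre = character(), post = character(),
                                 probability = double(), contacts = double(),
                                 is_default = logical()),
    synapses = tibble::tibble(pre = character(), post = character(),
                              g_nS = double(), tau_d_ms = double(),
                              tau_r_ms = double(), tau_f_ms = double(),
                              U = double(), is_default = logical())
  )
  proto[[table]]
}

#' Class-averaged default connection probabilities
#'
#' Probabilities of potential connection averaged over all measured pairs of
#' each polarity class, used to fill connection rows for which no measured
#' value is available: excitatory-to-excitatory (`EE`), excitatory-to-
#' inhibitory (`EI`), inhibitory-to-excitatory (`IE`) and inhibitory-to-
#' inhibitory (`II`).
#'
#' @return Named numeric vector with elements `EE`, `EI`, `IE`, `II`.
#' @examples
#' default_connection_probabilities()
#' @export
default_connection_probabilities <- function() {
  c(EE = 0.0117, EI = 0.0237, IE = 0.00684, II = 0.00423)
}

#' Package default parameters for unmeasured neuron models and synapses
#'
#' When a knowledge base lacks an Izhikevich row for a type, or a TPM row for
#' a directed pair, these documented package constants are substituted and
#' flagged `is_default = TRUE`. The neuron default is a generic
#' regular-spiking parameterization; the synapse defaults differ only in
#' decay time and utilization by presynaptic polarity (inhibitory synapses
#' decay more slowly).
#'
#' @param pre_polarity `"excitatory"` or `"inhibitory"` (synapse defaults
#'   only).
#' @return A one-row tibble of default parameters.
#' @examples
#' default_izhikevich_row()
#' default_tpm_row("inhibitory")
#' @export
default_izhikevich_row <- function() {
  tibble::tibble(C_pF = 100, k_nS_per_mV = 0.7, Vr_mV = -60, Vt_mV = -40,
                 Vpeak_mV = 35, Vmin_mV = -50, a_per_ms = 0.03, b_nS = -2,
                 d_pA = 100, is_default = TRUE)
}

#' @rdname default_izhikevich_row
#' @export
default_tpm_row <- function(pre_polarity = c("excitatory", "inhibitory")) {
  pre_polarity <- match.arg(pre_polarity)
  if (pre_polarity == "excitatory") {
    tibble::tibble(g_nS = 1, tau_d_ms = 5, tau_r_ms = 400, tau_f_ms = 50,
                   U = 0.35, is_default = TRUE)
  } else {
    tibble::tibble(g_nS = 1, tau_d_ms = 8, tau_r_ms = 400, tau_f_ms = 50,
                   U = 0.25, is_default = TRUE)
  }
}

#' Assemble a knowledge base from parameter tables
#'
#' A knowledge base bundles five cross-indexed tables: `neuron_types`
#' (name, subregion, polarity, importance rank 1-5, laminar code), `census`
#' (per-type neuron counts for one species), `izhikevich` (nine-parameter
#' single-compartment neuron models), `connections` (directed connection
#' probability and expected contacts per connected pair) and `synapses`
#' (TPM short-term plasticity constants per directed pair). Missing tables
#' default to empty; every table is validated against the type invariants
#' (see [validate_knowledge_base()]).
#'
#' @param neuron_types,census,izhikevich,connections,synapses Data frames in
#'   the column dialect of [read_knowledge_base()].
#' @param validate Validate before returning (default `TRUE`).
#' @return An object of class `knowledge_base`.
#' @examples
#' kb <- make_toy_circuit()
#' kb
#' @export
knowledge_base <- function(neuron_types, census = NULL, izhikevich = NULL,
                           connections = NULL, synapses = NULL,
                           validate = TRUE) {
  as_tab <- function(x, table) {
    if (is.null(x)) {
      return(empty_kb_table(table))
    }
    x <- tibble::as_tibble(x)
    if ("is_default" %in% KB_COLUMNS[[table]] && !"is_default" %in% names(x)) {
      x$is_default <- rep(FALSE, nrow(x))
    }
    x
  }
  kb <- structure(
    list(
      neuron_types = as_tab(neuron_types, "neuron_types"),
      census       = as_tab(census, "census"),
      izhikevich   = as_tab(izhikevich, "izhikevich"),
      connections  = as_tab(connections, "connections"),
      synapses     = as_tab(synapses, "synapses")
    ),
    class = "knowledge_base"
  )
  if (validate) validate_knowledge_base(kb) else kb
}

#' Validate a knowledge base
#'
#' Checks the full set of invariants: required columns; unique type names;
#' subregion and polarity drawn from the closed vocabularies; rank in 1-5
#' (a missing rank is filled with the middle value 3, with a warning);
#' laminar codes matching `[0-3]+` with optional trailing `"p"`; a single
#' species per census with counts of at least 1; Izhikevich orderings
#' `Vr < Vt < Vpeak`, `Vmin < Vpeak` and positive `C`, `k`, `a`; connection
#' probabilities in \[0, 1\] with contacts of at least 1 wherever the
#' probability is positive; TPM constants positive with utilization in
#' (0, 1\]; no duplicate directed pairs; and no dangling type references.
#' Violations are reported with the offending table and row.
#'
#' @param kb A [knowledge_base()].
#' @param context Optional named character vector mapping table names to
#'   source labels (e.g. file paths) used in error messages.
#' @return `kb`, invisibly (with any defaulted ranks filled in).
#' @export
validate_knowledge_base <- function(kb, context = NULL) {
  ctx <- function(table) (context[[table]] %||% table)
  for (table in KB_TABLES) {
    tab <- kb[[table]]
    missing <- setdiff(KB_COLUMNS[[table]], names(tab))
    if (length(missing) > 0) {
      stop(sprintf("%s: missing column(s): %s", ctx(table),
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }

  nt <- kb$neuron_types
  dup <- which(duplicated(nt$name))
  if (length(dup) > 0) {
    stop_row(ctx("neuron_types"), dup, paste("duplicate type name:",
                                             nt$name[dup[1]]))
  }
  bad <- which(!nt$subregion %in% SUBREGIONS)
  if (length(bad) > 0) {
    stop_row(ctx("neuron_types"), bad,
             sprintf("subregion must be one of %s (got \"%s\")",
                     paste(SUBREGIONS, collapse = "/"), nt$subregion[bad[1]]))
  }
  bad <- which(!nt$polarity %in% POLARITIES)
  if (length(bad) > 0) {
    stop_row(ctx("neuron_types"), bad,
             sprintf("polarity must be \"excitatory\" or \"inhibitory\" (got \"%s\")",
                     nt$polarity[bad[1]]))
  }
  if (anyNA(nt$rank)) {
    warning("missing importance rank(s) filled with the middle value 3",
            call. = FALSE)
    kb$neuron_types$rank[is.na(kb$neuron_types$rank)] <- 3
    nt <- kb$neuron_types
  }
  bad <- which(!nt$rank %in% 1:5)
  if (length(bad) > 0) {
    stop_row(ctx("neuron_types"), bad,
             sprintf("rank must be an integer in 1..5 (got %s)",
                     nt$rank[bad[1]]))
  }
  bad <- which(!grepl("^[0-3]+p?$", nt$laminar_code))
  if (length(bad) > 0) {
    stop_row(ctx("neuron_types"), bad,
             sprintf("laminar_code must match [0-3]+ with optional trailing \"p\" (got \"%s\")",
                     nt$laminar_code[bad[1]]))
  }
  known <- nt$name

  cs <- kb$census
  if (nrow(cs) > 0) {
    bad <- which(!cs$species %in% SPECIES_LEVELS)
    if (length(bad) > 0) {
      stop_row(ctx("census"), bad, sprintf("species must be \"rat\" or \"mouse\" (got \"%s\")",
                                           cs$species[bad[1]]))
    }
    if (length(unique(cs$species)) > 1) {
      stop(sprintf("%s: a knowledge base holds one species at a time (found: %s)",
                   ctx("census"), paste(unique(cs$species), collapse = ", ")),
           call. = FALSE)
    }
    bad <- which(!(is.finite(cs$count) & cs$count >= 1 & cs$count == floor(cs$count)))
    if (length(bad) > 0) {
      stop_row(ctx("census"), bad, sprintf("count must be a positive integer (got %s)",
                                           cs$count[bad[1]]))
    }
    bad <- which(!cs$name %in% known)
    if (length(bad) > 0) {
      stop_row(ctx("census"), bad, paste("unknown neuron type:", cs$name[bad[1]]))
    }
    dup <- which(duplicated(cs$name))
    if (length(dup) > 0) {
      stop_row(ctx("census"), dup, paste("duplicate census row for", cs$name[dup[1]]))
    }
  }

  iz <- kb$izhikevich
  if (nrow(iz) > 0) {
    bad <- which(!iz$name %in% known)
    if (length(bad) > 0) {
      stop_row(ctx("izhikevich"), bad, paste("unknown neuron type:", iz$name[bad[1]]))
    }
    dup <- which(duplicated(iz$name))
    if (length(dup) > 0) {
      stop_row(ctx("izhikevich"), dup, paste("duplicate model row for", iz$name[dup[1]]))
    }
    bad <- which(!(iz$Vr_mV < iz$Vt_mV & iz$Vt_mV < iz$Vpeak_mV &
                     iz$Vmin_mV < iz$Vpeak_mV))
    if (length(bad) > 0) {
      stop_row(ctx("izhikevich"), bad,
               "membrane potentials must satisfy Vr < Vt < Vpeak and Vmin < Vpeak")
    }
    bad <- which(!(iz$C_pF > 0 & iz$k_nS_per_mV > 0 & iz$a_per_ms > 0))
    if (length(bad) > 0) {
      stop_row(ctx("izhikevich"), bad, "C, k and a must be positive")
    }
  }

  cn <- kb$connections
  if (nrow(cn) > 0) {
    for (col in c("pre", "post")) {
      bad <- which(!cn[[col]] %in% known)
      if (length(bad) > 0) {
        stop_row(ctx("connections"), bad,
                 paste("unknown neuron type:", cn[[col]][bad[1]]))
      }
    }
    dup <- which(duplicated(cn[, c("pre", "post")]))
    if (length(dup) > 0) {
      stop_row(ctx("connections"), dup,
               sprintf("duplicate connection row %s -> %s",
                       cn$pre[dup[1]], cn$post[dup[1]]))
    }
    bad <- which(!(is.finite(cn$probability) & cn$probability >= 0 &
                     cn$probability <= 1))
    if (length(bad) > 0) {
      stop_row(ctx("connections"), bad,
               sprintf("probability must lie in [0, 1] (got %s)",
                       cn$probability[bad[1]]))
    }
    bad <- which(cn$probability > 0 & !is.na(cn$contacts) & cn$contacts < 1)
    if (length(bad) > 0) {
      stop_row(ctx("connections"), bad,
               "contacts must be >= 1 when the connection probability is positive")
    }
  }

  sy <- kb$synapses
  if (nrow(sy) > 0) {
    for (col in c("pre", "post")) {
      bad <- which(!sy[[col]] %in% known)
      if (length(bad) > 0) {
        stop_row(ctx("synapses"), bad,
                 paste("unknown neuron type:", sy[[col]][bad[1]]))
      }
    }
    dup <- which(duplicated(sy[, c("pre", "post")]))
    if (length(dup) > 0) {
      stop_row(ctx("synapses"), dup,
               sprintf("duplicate synapse row %s -> %s",
                       sy$pre[dup[1]], sy$post[dup[1]]))
    }
    bad <- which(!(sy$g_nS > 0 & sy$tau_d_ms > 0 & sy$tau_r_ms > 0 &
                     sy$tau_f_ms > 0))
    if (length(bad) > 0) {
      stop_row(ctx("synapses"), bad,
               "g and all time constants must be positive")
    }
    bad <- which(!(sy$U > 0 & sy$U <= 1))
    if (length(bad) > 0) {
      stop_row(ctx("synapses"), bad,
               sprintf("utilization U must lie in (0, 1] (got %s)", sy$U[bad[1]]))
    }
  }

  invisible(kb)
}

#' Read and write knowledge-base tables
#'
#' The on-disk dialect is five UTF-8 comma-separated files with one header
#' row and `"."` as the decimal mark, stored in one directory:
#' `neuron_types.csv` (`name,subregion,polarity,rank,laminar_code`),
#' `census.csv` (`name,species,count`), `izhikevich.csv`
#' (`name,C_pF,k_nS_per_mV,Vr_mV,Vt_mV,Vpeak_mV,Vmin_mV,a_per_ms,b_nS,d_pA,is_default`),
#' `connections.csv` (`pre,post,probability,contacts,is_default`) and
#' `synapses.csv` (`pre,post,g_nS,tau_d_ms,tau_r_ms,tau_f_ms,U,is_default`).
#' Rows whose values were filled by package defaults rather than measured
#' carry `is_default = TRUE`. `load(export(kb))` reproduces `kb` field for
#' field.
#'
#' @param path Directory holding (or to receive) the five CSV files.
#' @param kb A [knowledge_base()].
#' @return `read_knowledge_base()` returns a validated `knowledge_base`;
#'   `write_knowledge_base()` returns the written file paths, invisibly.
#' @examples
#' dir <- tempfile()
#' write_knowledge_base(make_toy_circuit(), dir)
#' kb <- read_knowledge_base(dir)
#' @export
read_knowledge_base <- function(path) {
  files <- setNames(file.path(path, paste0(KB_TABLES, ".csv")), KB_TABLES)
  missing <- files[!file.exists(files)]
  if (length(missing) > 0) {
    stop("missing knowledge-base file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tabs <- lapply(KB_TABLES, function(table) {
    read_csv_exact(files[[table]], kb_col_types[[table]])
  })
  names(tabs) <- KB_TABLES
  kb <- knowledge_base(tabs$neuron_types, tabs$census, tabs$izhikevich,
                       tabs$connections, tabs$synapses, validate = FALSE)
  validate_knowledge_base(kb, context = files)
}

#' @rdname read_knowledge_base
#' @export
write_knowledge_base <- function(kb, path) {
  stopifnot(inherits(kb, "knowledge_base"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  files <- setNames(file.path(path, paste0(KB_TABLES, ".csv")), KB_TABLES)
  for (table in KB_TABLES) {
    write_csv_exact(kb[[table]][, KB_COLUMNS[[table]]], files[[table]])
  }
  invisible(files)
}

#' Subset a knowledge base by subregion, importance rank, or type name
#'
#' Retains exactly the neuron types passing every supplied filter and
#' restricts the census, neuron-model, connection and synapse tables to the
#' retained types (connection and synapse rows are kept only when both
#' endpoints survive).
#'
#' @param kb A [knowledge_base()].
#' @param subregions Character vector of subregions to keep (default: all).
#' @param max_rank Keep types with importance rank `<= max_rank` (1 =
#'   essential, 5 = dispensable; default 5 keeps everything).
#' @param names Character vector of type names to keep (default: all).
#'   Unknown names are an error.
#' @return A filtered `knowledge_base`.
#' @examples
#' kb <- make_toy_circuit()
#' select_types(kb, subregions = "DG")
#' @export
select_types <- function(kb, subregions = NULL, max_rank = 5, names = NULL) {
  stopifnot(inherits(kb, "knowledge_base"))
  if (!max_rank %in% 1:5) {
    stop("max_rank must be an integer in 1..5", call. = FALSE)
  }
  nt <- kb$neuron_types
  if (!is.null(names)) {
    unknown <- setdiff(names, nt$name)
    if (length(unknown) > 0) {
      stop("unknown neuron type(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  keep <- nt$rank <= max_rank
  if (!is.null(subregions)) keep <- keep & nt$subregion %in% subregions
  if (!is.null(names)) keep <- keep & nt$name %in% names
  retained <- nt$name[keep]
  knowledge_base(
    nt[keep, ],
    kb$census[kb$census$name %in% retained, ],
    kb$izhikevich[kb$izhikevich$name %in% retained, ],
    kb$connections[kb$connections$pre %in% retained &
                     kb$connections$post %in% retained, ],
    kb$synapses[kb$synapses$pre %in% retained &
                  kb$synapses$post %in% retained, ],
    validate = FALSE
  )
}

#' Polarity class of a directed connection
#'
#' Maps the presynaptic and postsynaptic polarities onto the four connection
#' classes `EE`, `EI`, `IE`, `II` (presynaptic polarity first).
#'
#' @param pre_polarity,post_polarity `"excitatory"` or `"inhibitory"`
#'   (vectorized).
#' @return Character vector of class codes.
#' @examples
#' connection_class("excitatory", "inhibitory")  # "EI"
#' @export
connection_class <- function(pre_polarity, post_polarity) {
  code <- function(p) {
    if (any(!p %in% POLARITIES)) {
      stop("polarity must be \"excitatory\" or \"inhibitory\"", call. = FALSE)
    }
    ifelse(p == "excitatory", "E", "I")
  }
  paste0(code(pre_polarity), code(post_polarity))
}

kb_polarity <- function(kb, type_names) {
  kb$neuron_types$polarity[match(type_names, kb$neuron_types$name)]
}

#' Fill unmeasured parameters with flagged defaults
#'
#' `fill_missing_probabilities()` completes the connection table over the
#' Cartesian product of retained types (self-pairs included: recurrent
#' populations are real), assigning each absent directed pair the
#' class-averaged default probability from
#' [default_connection_probabilities()] and contacts of 1, flagged
#' `is_default = TRUE`; measured rows are untouched, and the operation is
#' idempotent. `fill_missing_synapses()` and `fill_missing_izhikevich()` do
#' the same for TPM and neuron-model rows using [default_tpm_row()] and
#' [default_izhikevich_row()].
#'
#' @param kb A [knowledge_base()].
#' @return A completed `knowledge_base`.
#' @examples
#' kb <- fill_missing_probabilities(make_incomplete_kb(completeness = 0.5))
#' table(kb$connections$is_default)
#' @export
fill_missing_probabilities <- function(kb) {
  stopifnot(inherits(kb, "knowledge_base"))
  types <- kb$neuron_types$name
  grid <- tidyr::expand_grid(pre = types, post = types)
  missing <- dplyr::anti_join(grid, kb$connections, by = c("pre", "post"))
  if (nrow(missing) == 0) {
    return(kb)
  }
  cls <- connection_class(kb_polarity(kb, missing$pre),
                          kb_polarity(kb, missing$post))
  filled <- tibble::tibble(
    pre = missing$pre, post = missing$post,
    probability = unname(default_connection_probabilities()[cls]),
    contacts = 1, is_default = TRUE
  )
  kb$connections <- dplyr::arrange(
    dplyr::bind_rows(kb$connections, filled), .data$pre, .data$post
  )
  validate_knowledge_base(kb)
}

#' @rdname fill_missing_probabilities
#' @export
fill_missing_synapses <- function(kb) {
  stopifnot(inherits(kb, "knowledge_base"))
  types <- kb$neuron_types$name
  grid <- tidyr::expand_grid(pre = types, post = types)
  missing <- dplyr::anti_join(grid, kb$synapses, by = c("pre", "post"))
  if (nrow(missing) == 0) {
    return(kb)
  }
  pol <- kb_polarity(kb, missing$pre)
  filled <- dplyr::bind_cols(
    missing,
    dplyr::bind_rows(lapply(pol, default_tpm_row))
  )
  kb$synapses <- dplyr::arrange(
    dplyr::bind_rows(kb$synapses, filled), .data$pre, .data$post
  )
  validate_knowledge_base(kb)
}

#' @rdname fill_missing_probabilities
#' @export
fill_missing_izhikevich <- function(kb) {
  stopifnot(inherits(kb, "knowledge_base"))
  missing <- setdiff(kb$neuron_types$name, kb$izhikevich$name)
  if (length(missing) == 0) {
    return(kb)
  }
  filled <- dplyr::bind_cols(tibble::tibble(name = missing),
                             default_izhikevich_row()[rep(1, length(missing)), ])
  kb$izhikevich <- dplyr::arrange(
    dplyr::bind_rows(kb$izhikevich, filled), .data$name
  )
  validate_knowledge_base(kb)
}

#' @export
print.knowledge_base <- function(x, ...) {
  species <- unique(x$census$species)
  cat(sprintf("<knowledge_base> %d neuron types%s\n", nrow(x$neuron_types),
              if (length(species) == 1) paste0(" (", species, ")") else ""))
  cat(sprintf("  census: %d rows | izhikevich: %d | connections: %d (%d default) | synapses: %d (%d default)\n",
              nrow(x$census), nrow(x$izhikevich), nrow(x$connections),
              sum(x$connections$is_default), nrow(x$synapses),
              sum(x$synapses$is_default)))
  invisible(x)
}

#' Tidy and summarize a knowledge base
#'
#' `tidy()` returns one row per neuron type with its census count;
#' `glance()` returns a one-row summary of table sizes and default-fill
#' counts.
#'
#' @param x A [knowledge_base()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy knowledge_base
#' @export
tidy.knowledge_base <- function(x, ...) {
  dplyr::left_join(x$neuron_types, x$census[, c("name", "count")], by = "name")
}

#' @rdname tidy.knowledge_base
#' @method glance knowledge_base
#' @export
glance.knowledge_base <- function(x, ...) {
  tibble::tibble(
    n_types = nrow(x$neuron_types),
    n_excitatory = sum(x$neuron_types$polarity == "excitatory"),
    n_inhibitory = sum(x$neuron_types$polarity == "inhibitory"),
    n_connections = nrow(x$connections),
    n_default_connections = sum(x$connections$is_default),
    n_synapses = nrow(x$synapses),
    species = paste(unique(x$census$species), collapse = ",")
  )
}
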