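test_that("toy fixture loads into a fully cross-indexed knowledge base", {
  kb <- make_toy_circuit()
  expect_s3_class(kb, "knowledge_base")
  expect_equal(nrow(kb$neuron_types), 4)
  expect_equal(nrow(kb$connections), 12)
  expect_equal(sort(unique(c(kb$connections$pre, kb$connections$post))),
               sort(kb$neuron_types$name))
  g <- glance(kb)
  expect_equal(g$n_excitatory, 2)
  expect_equal(g$n_inhibitory, 2)
})

test_that("validation reports the offending table and row", {
  kb <- make_toy_circuit()
  bad <- kb
  bad$neuron_types$rank[2] <- 6
  expect_error(validate_knowledge_base(bad), "row 2.*rank")
  bad <- kb
  bad$neuron_types$laminar_code[3] <- "24x"
  expect_error(validate_knowledge_base(bad), "row 3.*laminar_code")
  bad <- kb
  bad$census$count[1] <- 0
  expect_error(validate_knowledge_base(bad), "census.*row 1")
  bad <- kb
  bad$connections$pre[5] <- "No Such Type"
  expect_error(validate_knowledge_base(bad), "row 5.*unknown neuron type")
  bad <- kb
  bad$connections <- dplyr::bind_rows(bad$connections, bad$connections[1, ])
  expect_error(validate_knowledge_base(bad), "duplicate connection")
  bad <- kb
  bad$synapses$U[4] <- 1.5
  expect_error(validate_knowledge_base(bad), "row 4.*U")
  bad <- kb
  bad$izhikevich$Vt_mV[1] <- -90  # below Vr
  expect_error(validate_knowledge_base(bad), "Vr < Vt")
  bad <- kb
  bad$census <- NULL
  bad$census <- data.frame(name = "DG Granule", count = 5)
  expect_error(validate_knowledge_base(bad), "missing column")
})

test_that("a missing rank is defaulted to the middle value with a warning", {
  kb <- make_toy_circuit()
  kb$neuron_types$rank[2] <- NA
  expect_warning(kb2 <- validate_knowledge_base(kb), "rank")
  expect_equal(kb2$neuron_types$rank[2], 3)
})

test_that("mixing species in one census is rejected", {
  kb <- make_toy_circuit()
  kb$census$species[1] <- "rat"
  expect_error(validate_knowledge_base(kb), "one species")
})

test_that("export then load reproduces the knowledge base field for field", {
  for (seed in c(1, 7, 23)) {
    kb <- make_random_kb(n_types = 5, completeness = 0.7, seed = seed)
    dir <- withr::local_tempdir()
    write_knowledge_base(kb, dir)
    kb2 <- read_knowledge_base(dir)
    expect_identical(lapply(kb, as.data.frame), lapply(kb2, as.data.frame))
  }
})

test_that("an empty knowledge base exports header-only files", {
  kb <- knowledge_base(NULL)
  dir <- withr::local_tempdir()
  files <- write_knowledge_base(kb, dir)
  for (f in files) {
    expect_equal(length(readLines(f)), 1)  # header only
  }
  kb2 <- read_knowledge_base(dir)
  expect_equal(nrow(kb2$neuron_types), 0)
})

test_that("select_types filters by subregion, rank and name consistently", {
  kb <- make_toy_circuit()
  expect_identical(as.data.frame(select_types(kb, max_rank = 5)$neuron_types),
                   as.data.frame(kb$neuron_types))
  # one rank-1 type per subregion in the fixture
  sel <- select_types(kb, subregions = c("DG", "CA3"), max_rank = 1)
  expect_equal(sort(sel$neuron_types$name),
               c("CA3 Pyramidal", "DG Granule"))
  # selecting a single type drops every row mentioning any other type:
  # set-difference oracle computed directly on the original tables
  one <- select_types(kb, names = "DG Granule")
  expected <- kb$connections[kb$connections$pre == "DG Granule" &
                               kb$connections$post == "DG Granule", ]
  expect_identical(as.data.frame(one$connections), as.data.frame(expected))
  expect_error(select_types(kb, names = "Nope"), "unknown neuron type")
  expect_error(select_types(kb, max_rank = 0), "max_rank")
})

test_that("select_types is idempotent", {
  kb <- make_random_kb(n_types = 8, seed = 11)
  once <- select_types(kb, subregions = c("DG", "CA3", "CA1"), max_rank = 3)
  twice <- select_types(once, subregions = c("DG", "CA3", "CA1"),
                        max_rank = 3)
  expect_identical(lapply(once, as.data.frame), lapply(twice, as.data.frame))
})

test_that("connection_class enumerates exactly the four classes", {
  expect_equal(connection_class("excitatory", "excitatory"), "EE")
  expect_equal(connection_class("excitatory", "inhibitory"), "EI")
  expect_equal(connection_class("inhibitory", "excitatory"), "IE")
  expect_equal(connection_class("inhibitory", "inhibitory"), "II")
  grid <- expand.grid(pre = c("excitatory", "inhibitory"),
                      post = c("excitatory", "inhibitory"),
                      stringsAsFactors = FALSE)
  expect_setequal(connection_class(grid$pre, grid$post),
                  c("EE", "EI", "IE", "II"))
  expect_error(connection_class("glutamate", "excitatory"), "polarity")
})

test_that("probability fill-in uses the class-averaged defaults and flags them", {
  kb <- fill_missing_probabilities(make_incomplete_kb(completeness = 0))
  expect_equal(nrow(kb$connections), 16)  # full Cartesian product, self-pairs in
  expect_true(all(kb$connections$is_default))
  pol <- function(x) kb$neuron_types$polarity[match(x, kb$neuron_types$name)]
  cls <- connection_class(pol(kb$connections$pre), pol(kb$connections$post))
  defaults <- default_connection_probabilities()
  expect_equal(kb$connections$probability, unname(defaults[cls]))
  # and specifically the four printed class averages
  expect_equal(unname(defaults), c(0.0117, 0.0237, 0.00684, 0.00423))
})

test_that("measured connection rows survive the fill untouched", {
  kb <- make_incomplete_kb(completeness = 0.5, seed = 3)
  measured <- kb$connections
  filled <- fill_missing_probabilities(kb)
  merged <- dplyr::inner_join(filled$connections, measured,
                              by = c("pre", "post"), suffix = c("", ".orig"))
  expect_equal(merged$probability, merged$probability.orig)
  expect_false(any(merged$is_default))
})

test_that("probability fill-in is idempotent and completes the pair grid", {
  kb <- fill_missing_probabilities(make_incomplete_kb(completeness = 0.25))
  again <- fill_missing_probabilities(kb)
  expect_identical(as.data.frame(kb$connections),
                   as.data.frame(again$connections))
  n <- nrow(kb$neuron_types)
  expect_equal(nrow(kb$connections), n * n)
})

test_that("synapse and neuron-model fill-in flag package defaults", {
  kb <- make_toy_circuit()
  kb$synapses <- kb$synapses[1:3, ]
  kb$izhikevich <- kb$izhikevich[1:2, ]
  filled <- fill_missing_izhikevich(fill_missing_synapses(kb))
  expect_equal(nrow(filled$synapses), 16)
  expect_equal(sum(filled$synapses$is_default), 13)
  expect_equal(nrow(filled$izhikevich), 4)
  expect_equal(sum(filled$izhikevich$is_default), 2)
  # inhibitory presynaptic defaults decay more slowly than excitatory ones
  def <- filled$synapses[filled$synapses$is_default, ]
  pol <- filled$neuron_types$polarity[match(def$pre,
                                            filled$neuron_types$name)]
  expect_true(all(def$tau_d_ms[pol == "inhibitory"] >
                    def$tau_d_ms[pol == "excitatory"][1] - 1e-9))
})

test_that("a default-filled row keeps its flag through export and reload", {
  kb <- fill_missing_probabilities(make_incomplete_kb(completeness = 0.5))
  dir <- withr::local_tempdir()
  write_knowledge_base(kb, dir)
  kb2 <- read_knowledge_base(dir)
  expect_identical(kb2$connections$is_default, kb$connections$is_default)
  expect_true(any(kb2$connections$is_default))
})
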