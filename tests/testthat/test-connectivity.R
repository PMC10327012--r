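test_that("bouton counts follow length over inter-bouton distance", {
  expect_equal(round(bouton_count(3236, 67.4)), 48)
  expect_equal(bouton_count(0, 284), 0)
  expect_equal(bouton_count(3236, 162), 3236 / 162)
  expect_error(bouton_count(100, 0), "positive")
  expect_error(bouton_count(-1, 10), "non-negative")
})

test_that("axonal length partitions multiply region and layer fractions", {
  part <- partition_axonal_length(100000, 0.275,
                                  c(SR = 0.64, SP = 0.15, SO = 0.21))
  expect_equal(part$length_um[part$layer == "SR"], 17600)
  expect_equal(part$length_um[part$layer == "SP"], 4125)
  expect_equal(part$length_um[part$layer == "SO"], 5775)
  expect_equal(sum(part$length_um), 100000 * 0.275)
  zero <- partition_axonal_length(100000, 0, c(SR = 0.64, SP = 0.36))
  expect_true(all(zero$length_um == 0))
  all_sr <- partition_axonal_length(5000, 0.5, c(SR = 1))
  expect_equal(all_sr$length_um, 2500)
  expect_error(partition_axonal_length(1, 0.5, c(SR = 0.6, SO = 0.2)),
               "sum to 1")
  expect_error(partition_axonal_length(1, 1.5, c(SR = 1)), "region_fraction")
})

test_that("inter-bouton averaging reproduces the reported display value", {
  expect_equal(round(mean_interbouton_distance(c(3.7, 4.4, 4.29)), 1), 4.1)
  expect_equal(mean_interbouton_distance(5.5), 5.5)
  expect_equal(mean_interbouton_distance(c(2, 4)), 3)
  expect_error(mean_interbouton_distance(numeric(0)), "at least one")
  expect_error(mean_interbouton_distance(c(3, -1)), "positive")
})

test_that("single-bouton hit probability is the cylinder volume fraction", {
  expect_equal(pair_hit_probability(0, 1e8), 0)
  expect_equal(pair_hit_probability(1000, 1e9, 1), pi * 1e-6)
  # saturation: dendritic cylinder as large as the parcel clamps at 1
  v <- 1000 * pi * 1
  expect_equal(pair_hit_probability(1000, v, 1), 1)
  expect_equal(pair_hit_probability(1000, v / 2, 1), 1)
  expect_error(pair_hit_probability(10, -1), "positive")
})

test_that("closed-form estimates match exact enumeration for integer boutons", {
  parcel <- function(nb, q) data.frame(
    parcel_id = "CA3:SL", volume_um3 = 1, axonal_length_um = nb,
    interbouton_um = 1, dendritic_length_um = q / pi, radius_um = 1
  )
  for (case in list(c(1, 0.2), c(2, 0.5), c(3, 0.3), c(5, 0.05))) {
    nb <- case[1]
    q <- case[2]
    est <- estimate_connection(parcel(nb, q))
    oracle <- enumerate_connection(nb, q)
    expect_equal(est$probability, oracle$probability)
    expect_equal(est$expected_synapses, oracle$expected_synapses)
    expect_equal(est$contacts, oracle$contacts)
  }
  # the printed micro-example: two boutons at q = 1/2 connect 3 times in 4
  est <- estimate_connection(parcel(2, 0.5))
  expect_equal(est$probability, 0.75)
  expect_equal(est$expected_synapses, 1)
  expect_equal(est$contacts, 4 / 3)
})

test_that("zero overlap gives zero probability and undefined contacts", {
  est <- estimate_connection(data.frame(
    parcel_id = "CA3:SL", volume_um3 = 1e8, axonal_length_um = 1000,
    interbouton_um = 100, dendritic_length_um = 0
  ))
  expect_equal(est$probability, 0)
  expect_equal(est$expected_synapses, 0)
  expect_true(is.na(est$contacts))
})

test_that("probability is bounded by the expectation and contacts exceed 1", {
  set.seed(42)
  for (i in 1:50) {
    n_parcel <- sample(1:4, 1)
    parcels <- data.frame(
      parcel_id = paste0("P", seq_len(n_parcel)),
      volume_um3 = runif(n_parcel, 1e6, 1e9),
      axonal_length_um = runif(n_parcel, 0, 5000),
      interbouton_um = runif(n_parcel, 3, 300),
      dendritic_length_um = runif(n_parcel, 0, 4000),
      radius_um = runif(n_parcel, 0.5, 2)
    )
    est <- estimate_connection(parcels)
    expect_lte(est$probability, est$expected_synapses + 1e-12)
    if (est$probability > 0) expect_gte(est$contacts, 1)
  }
})

test_that("connection probability is monotone in bouton count and hit rate", {
  base <- data.frame(parcel_id = "P", volume_um3 = 1e8,
                     axonal_length_um = 2000, interbouton_um = 50,
                     dendritic_length_um = 1500)
  p0 <- estimate_connection(base)$probability
  more_boutons <- transform(base, axonal_length_um = 4000)
  denser <- transform(base, dendritic_length_um = 3000)
  expect_gt(estimate_connection(more_boutons)$probability, p0)
  expect_gt(estimate_connection(denser)$probability, p0)
})

test_that("contacts tend to 1 in the sparse-overlap limit", {
  est <- estimate_connection(data.frame(
    parcel_id = "P", volume_um3 = 1e12, axonal_length_um = 100,
    interbouton_um = 50, dendritic_length_um = 1000
  ))
  expect_lt(est$expected_synapses, 1e-6)
  expect_equal(est$contacts, 1, tolerance = 1e-6)
})

test_that("Monte-Carlo bouton placement reproduces the closed form", {
  parcels <- data.frame(
    parcel_id = c("A", "B"), volume_um3 = 1,
    axonal_length_um = c(2, 3), interbouton_um = 1,
    dendritic_length_um = c(0.5, 0.2) / pi, radius_um = 1
  )
  est <- estimate_connection(parcels)
  mc <- simulate_connection(parcels, n_rep = 2e4, seed = 99)
  expect_lt(abs(mc$probability - est$probability), 3 * mc$probability_se)
  expect_lt(abs(mc$contacts - est$contacts), 3 * mc$contacts_se)
})

test_that("connectivity aggregates at subregion, type and pair levels", {
  kb <- make_toy_circuit()
  sub <- aggregate_connectivity(kb, "subregion")
  expect_true(all(c("DG", "CA3") %in% sub$pre))
  dg_ca3 <- sub$n_pairs[sub$pre == "DG" & sub$post == "CA3"]
  oracle <- sum(kb$neuron_types$subregion[
    match(kb$connections$pre, kb$neuron_types$name)] == "DG" &
      kb$neuron_types$subregion[
        match(kb$connections$post, kb$neuron_types$name)] == "CA3" &
      kb$connections$probability > 0)
  expect_equal(dg_ca3, oracle)
  pair <- aggregate_connectivity(kb, "pair")
  expect_equal(nrow(pair), sum(kb$connections$probability > 0))
  # type-level degree of a node equals the number of rows naming it
  typ <- aggregate_connectivity(kb, "type")
  live <- kb$connections[kb$connections$probability > 0, ]
  for (nm in kb$neuron_types$name) {
    expect_equal(sum(typ$pre == nm | typ$post == nm),
                 sum(live$pre == nm | live$post == nm))
  }
})

test_that("the transfer function is the conductance-decay product", {
  expect_equal(transfer_function(1, 1), 1)
  expect_equal(transfer_function(0.5, 4), 2)
  expect_equal(transfer_function(2 * 0.7, 3), 2 * transfer_function(0.7, 3))
  expect_error(transfer_function(0, 1), "positive")
})
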