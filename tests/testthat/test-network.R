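test_that("the default network has the reference wiring counts", {
  net <- build_network(quick_config())
  expect_identical(sum(net$neurons$kind == "feature"), 9L)
  expect_identical(sum(net$neurons$kind == "conjunctive"), 3L)
  counts <- table(net$synapses$kind)
  expect_identical(unname(counts[["feature_to_conj"]]), 27L)
  expect_identical(unname(counts[["conj_to_feature"]]), 27L)
  expect_identical(unname(counts[["lateral_inhibition"]]), 6L)
  expect_identical(unname(counts[["self_excitation"]]), 3L)
  # plasticity is confined to the bidirectional feature<->conjunctive wiring
  expect_identical(net$synapses$plastic,
                   net$synapses$kind %in% c("feature_to_conj", "conj_to_feature"))
  # lateral inhibition is negative, self-excitation positive and recurrent
  expect_true(all(net$synapses$w_fixed[net$synapses$kind == "lateral_inhibition"] < 0))
  self <- net$synapses[net$synapses$kind == "self_excitation", ]
  expect_true(all(self$w_fixed > 0))
  expect_identical(self$pre, self$post)
  # initial plastic states drawn inside the configured range
  rng <- quick_config()$init_weight_range
  x0 <- net$synapses$x[net$synapses$plastic]
  expect_true(all(x0 >= rng[1] & x0 <= rng[2]))
  # same seed, same initial weights; different seed differs
  expect_identical(build_network(quick_config())$synapses$x, net$synapses$x)
  expect_false(identical(build_network(quick_config(seed = 2))$synapses$x,
                         net$synapses$x))
})

test_that("a single conjunctive neuron has no lateral inhibition but keeps self-excitation", {
  net <- build_network(quick_config(n_conj = 1))
  counts <- table(net$synapses$kind)
  expect_false("lateral_inhibition" %in% names(counts))
  expect_identical(unname(counts[["self_excitation"]]), 1L)
  expect_identical(unname(counts[["feature_to_conj"]]), 9L)
})

test_that("LIF dynamics: resting fixed point, threshold reset, monotone f-I curve", {
  p <- lif_params()
  n <- neuron_state(p)
  out <- lif_step(n, 0, 0, 0.1, p)
  expect_identical(out$state$v, p$v_rest)
  expect_false(out$spiked)

  rate_at <- function(i_ext) {
    n <- neuron_state(p); spikes <- 0L
    for (k in 1:5000) { # 500 ms at 0.1 ms
      out <- lif_step(n, 0, i_ext, 0.1, p, t = k * 0.1)
      n <- out$state
      spikes <- spikes + out$spiked
    }
    spikes / 0.5
  }
  expect_identical(rate_at(0.9), 0)           # sub-rheobase
  rates <- vapply(c(1.2, 1.6, 2.2, 3), rate_at, numeric(1))
  expect_gt(rates[1], 0)
  expect_true(!is.unsorted(rates))            # nondecreasing in drive
})

test_that("feature-selective firing rate is nondecreasing in stimulus amplitude", {
  rates <- vapply(c(1.2, 1.5, 2, 3), function(a) {
    prot <- make_protocol(wm_objects()[1], init_time = 10, stim_dur = 80,
                          rest_dur = 10, amplitude = a)
    net <- build_network(quick_config())
    net <- ablate_synapses(net, c("conj_to_feature", "feature_to_conj"))
    sim <- run_simulation(net, prot)
    firing_rates(sim, c(10, 90))$rate_hz[1]
  }, numeric(1))
  expect_gt(rates[1], 0)
  expect_true(!is.unsorted(rates))
})

test_that("an empty protocol produces no spikes and no plasticity events", {
  prot <- make_protocol(list(), init_time = 60)
  sim <- run_simulation(build_network(quick_config()), prot)
  expect_identical(nrow(sim$spikes), 0L)
  expect_identical(nrow(sim$events), 0L)
})

test_that("simulations are deterministic under a fixed seed", {
  prot <- make_protocol(wm_objects()[1], init_time = 20, stim_dur = 60,
                        rest_dur = 20)
  a <- run_simulation(build_network(quick_config(seed = 5)), prot)
  b <- run_simulation(build_network(quick_config(seed = 5)), prot)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$weights, b$weights)
  expect_identical(a$events, b$events)
})

test_that("a grid step coarser than the plasticity timing is refused", {
  prot <- make_protocol(wm_objects()[1])
  net <- build_network(quick_config())
  expect_error(run_simulation(net, prot, dt = 1.5), "unresolvable")
  expect_error(run_simulation(net, prot, dt = 0.5,
                              rule = plasticity_rule(Tp = 0.4)),
               "unresolvable")
})

test_that("plasticity bookkeeping: every event is a qualifying pair and programming time adds up", {
  prot <- make_protocol(wm_objects()[1], init_time = 20, stim_dur = 60,
                        rest_dur = 20)
  rule <- plasticity_rule()
  sim <- run_simulation(build_network(quick_config(seed = 3)), prot,
                        rule = rule)
  expect_gt(nrow(sim$events), 0)
  # events only on plastic synapses
  plastic_ids <- sim$net$synapses$syn_id[sim$net$synapses$plastic]
  expect_true(all(sim$events$syn_id %in% plastic_ids))
  # every event matches the decision rule applied to its recorded pair
  kinds <- vapply(sim$events$dt_pair,
                  function(d) classify_pair(0, d, rule)$kind, "")
  expect_identical(kinds, sim$events$kind)
  g <- glance(sim)
  expect_identical(g$programming_time_ms,
                   sum(sim$events$kind == "LTP") * 3 + sum(sim$events$kind == "LTD"))
  # weight snapshots stay in [0, 1]
  expect_true(all(sim$weights$x >= 0 & sim$weights$x <= 1))
})
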