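test_that("protocol layout reproduces the reference timing", {
  prot <- make_protocol(wm_objects(), cues = list(partial_cue("Obj1")))
  ev <- prot$events
  # init 50, then three (100 stim + 50 rest) blocks: cue starts at 500
  expect_identical(ev$onset[ev$type == "stim"], c(50, 200, 350))
  expect_identical(ev$onset[ev$type == "cue"], 500)
  expect_identical(ev$offset - ev$onset, rep(100, 4))
  # events are ordered and non-overlapping
  expect_true(all(ev$onset[-1] >= ev$offset[-nrow(ev)]))

  empty <- make_protocol(list(), init_time = 50)
  expect_identical(protocol_duration(empty), 50)
  expect_error(make_protocol(wm_objects(),
                             cues = list(partial_cue("Obj9"))), "unknown")
})

test_that("a partial cue drives exactly its cued feature neurons", {
  prot <- make_protocol(wm_objects(), cues = list(partial_cue("Obj1", dims = 1)))
  net <- build_network(quick_config())
  steps <- as.integer(prot$duration / 0.1)
  ext <- memwm:::.protocol_ext_matrix(prot, net, 0.1, steps)
  cue_cols <- (5000 + 10):(6000 - 10)   # inside the cue window
  driven <- which(rowSums(ext[, cue_cols]) > 0)
  expect_identical(driven, feature_neuron_id(net, 1, 1))
  # each stimulus drives exactly one neuron per dimension
  stim_cols <- (500 + 10):(1500 - 10)
  expect_identical(which(rowSums(ext[, stim_cols]) > 0),
                   feature_neuron_id(net, 1:3, c(1, 1, 1)))
})

test_that("firing rates follow the count/duration definition and add over subwindows", {
  prot <- make_protocol(wm_objects()[1], init_time = 10, stim_dur = 100,
                        rest_dur = 10)
  sim <- run_simulation(build_network(quick_config()), prot)
  r <- firing_rates(sim, c(10, 110))
  n1 <- r$n_spikes[1]
  expect_equal(r$rate_hz[1], n1 / 100 * 1000)
  # count additivity over a split of the window
  r1 <- firing_rates(sim, c(10, 60))
  r2 <- firing_rates(sim, c(60, 110))
  expect_identical(r1$n_spikes + r2$n_spikes, r$n_spikes)
  # silent neurons report exactly 0 Hz
  pre <- firing_rates(sim, c(0.5, 9.5))
  expect_identical(unique(pre$rate_hz), 0)
  expect_error(firing_rates(sim, c(50, 50)), "interval")
  expect_error(firing_rates(sim, c(0, 1e5)), "interval")
})

test_that("a fresh network with no stimuli is in no working-memory state", {
  prot <- make_protocol(list(), init_time = 80)
  sim <- run_simulation(build_network(quick_config()), prot)
  rep <- classify_state(sim, c(10, 80))
  expect_identical(rep$state, "none")
  expect_true(is.na(rep$winner))
})

test_that("retrieval of a never-presented object fails with a reason", {
  prot <- make_protocol(wm_objects()[1:2],
                        cues = list(partial_cue("Obj2", dims = 1)))
  sim <- run_simulation(build_network(quick_config()), prot)
  cue <- prot$events[prot$events$type == "cue", ]
  out <- score_retrieval(sim, cue, feature_object("Obj3", c(3, 3, 3)))
  expect_false(out$success)
  expect_match(out$reason, "never encoded")
})

test_that("mapping scores identify the conjunctive neuron with the strongest forward weights", {
  net <- build_network(quick_config())
  prot <- make_protocol(list(), init_time = 20)
  sim <- run_simulation(net, prot)
  m <- mapping_scores(sim, wm_objects())
  expect_identical(nrow(m), 9L)  # 3 objects x 3 conjunctive neurons
  for (ob in split(m, m$object)) {
    expect_identical(sum(ob$is_winner), 1L)
    expect_identical(ob$mean_w[ob$is_winner], max(ob$mean_w))
    expect_equal(unique(ob$score),
                 max(ob$mean_w) - max(ob$mean_w[!ob$is_winner]))
  }
  # scores agree with direct averaging of the initial weights
  syn <- net$synapses
  ids <- feature_neuron_id(net, 1:3, c(1, 1, 1))
  w_c1 <- mean(syn$x[syn$kind == "feature_to_conj" & syn$pre %in% ids &
                       syn$post == 10])
  expect_equal(m$mean_w[m$object == "Obj1" & m$conj_id == 10], w_c1)
})
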