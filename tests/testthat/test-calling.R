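# Responder calling, archetypes, shares, overlap and clones.

mk_traces <- function(values, timestamps, protocol) {
  structure(list(values = values, timestamps = timestamps,
                 statistic = "area", protocol = protocol, mask = NULL),
            class = "spark_traces")
}

single_prot <- protocol_hormone("h", t_stim = 10, duration = 40)

test_that("a flat zero trace is a nonresponder", {
  v <- matrix(0, 1, 41, dimnames = list("1", NULL))
  calls <- call_responses(mk_traces(v, 0:40, single_prot))
  expect_false(calls$responder)
  expect_equal(calls$archetype, "nonresponder")
})

test_that("persisting droplets without new formation are not re-called", {
  # droplets formed at stimulus 1 persist into stimulus 2's window: the
  # re-anchored baseline sees no rise, so stimulus 2 gets a nonresponder
  prot <- stim_protocol(c(10, 30), c("h1", "h2"),
                        rep("receptor_agonist", 2), duration = 60,
                        baseline = 10)
  v <- numeric(61)
  v[12:61] <- 120 * exp(-(0:49) / 30)   # slow passive disassembly
  v <- matrix(v, 1, dimnames = list("1", NULL))
  calls <- call_responses(mk_traces(v, 0:60, prot))
  expect_true(calls$responder[calls$stimulus == "h1"])
  expect_false(calls$responder[calls$stimulus == "h2"])
})

test_that("dissolution is called only on cells with pre-existing droplets", {
  prot <- stim_protocol(c(10, 30), c("h1", "h2"),
                        rep("receptor_agonist", 2), duration = 60,
                        baseline = 10)
  v <- numeric(61)
  v[12:30] <- 150
  v[31:61] <- 150 * exp(-(0:30) / 2)    # fast dissolution after stimulus 2
  vm <- matrix(v, 1, dimnames = list("1", NULL))
  calls <- call_responses(mk_traces(vm, 0:60, prot))
  c2 <- calls[calls$stimulus == "h2", ]
  expect_true(c2$responder)
  expect_equal(c2$archetype, "dissolving")
  expect_lt(c2$amplitude, 0)
  # same drop but from a zero baseline: nothing to dissolve
  v0 <- matrix(0, 1, 61, dimnames = list("1", NULL))
  calls0 <- call_responses(mk_traces(v0, 0:60, prot))
  expect_true(all(calls0$archetype == "nonresponder"))
})

test_that("latent transient and sustained cells classify end to end", {
  arch <- function(a) c(transient = a == "t", sustained = a == "s",
                        dissolving = FALSE) * 1
  for (case in list(list(a = "t", want = "transient"),
                    list(a = "s", want = "sustained"))) {
    cfg <- spark_config(
      n_cells = 1, frac_capable = 1, frac_pka_responsive = 1,
      hormone_panel = list(h = list(responder_frac = 1,
                                    archetype_weights = arch(case$a),
                                    amplitude_mean = 1, amplitude_cv = 0)),
      expression_law = c(meanlog = log(130), sdlog = 0),
      frame_shape = c(128L, 128L), seed = 1)
    r <- simulate_roster(cfg)
    a <- simulate_activity(r, protocol_hormone("h"), kinetic_params())
    st <- render_stack(r, a, optics_config(frame_shape = c(128L, 128L),
                                           seed = 101))
    calls <- call_responses(build_traces(st))
    expect_true(calls$responder)
    expect_equal(calls$archetype, case$want)
  }
})

test_that("sustained responses have lower amplitude than transient ones", {
  tr_calls <- attr(study_hormone("adenosine"), "calls")
  su_calls <- attr(study_hormone("histamine"), "calls")
  amp_t <- tr_calls$amplitude[tr_calls$responder &
                                tr_calls$archetype == "transient"]
  amp_s <- su_calls$amplitude[su_calls$responder &
                                su_calls$archetype == "sustained"]
  expect_gt(length(amp_t), 20)
  expect_gt(length(amp_s), 5)
  expect_lt(median(amp_s), median(amp_t))
})

test_that("population shares aggregate replicates with mean and SE", {
  calls <- data.frame(
    cell = 1:30, stimulus = "h", stim_time = 10,
    responder = c(rep(TRUE, 4), rep(FALSE, 6),
                  rep(TRUE, 5), rep(FALSE, 5),
                  rep(TRUE, 6), rep(FALSE, 4)),
    amplitude = 1, onset_frame = 1, duration = 1,
    archetype = "transient")
  calls$archetype[!calls$responder] <- "nonresponder"
  reps <- rep(c("a", "b", "c"), each = 10)
  ps <- population_share(calls, replicate = reps)
  expect_equal(ps$share, 50)
  expect_equal(ps$se, 10 / sqrt(3))
  one <- population_share(calls[calls$responder, ], replicate = "only")
  expect_equal(one$share, 100)
  expect_equal(one$se, 0)
})

test_that("dissolving responders do not count as droplet-forming in shares", {
  calls <- data.frame(cell = 1:4, stimulus = "h", stim_time = 10,
                      responder = c(TRUE, TRUE, TRUE, FALSE),
                      amplitude = c(1, 1, -1, 0), onset_frame = 1,
                      duration = 1,
                      archetype = c("transient", "sustained", "dissolving",
                                    "nonresponder"))
  ps <- population_share(calls)
  expect_equal(ps$n_responding, 2)
  expect_equal(ps$share, 50)
})

test_that("lowering the response threshold never loses responders", {
  cfg <- tiny_config(n_cells = 3, seed = 17)
  r <- simulate_roster(cfg)
  a <- simulate_activity(r, protocol_forskolin(), kinetic_params())
  st <- render_stack(r, a, tiny_optics(seed = 5))
  tr <- build_traces(st)
  n_resp <- vapply(c(12, 8, 5, 3, 1), function(k) {
    calls <- call_responses(tr, call_params(k_resp = k,
                                            abs_min_rise = k))
    sum(calls$responder)
  }, numeric(1))
  expect_true(all(diff(n_resp) >= 0))
})

test_that("overlap tables follow set algebra", {
  calls <- data.frame(
    cell = rep(1:10, 2),
    stimulus = rep(c("h1", "h2"), each = 10),
    stim_time = rep(c(10, 30), each = 10),
    responder = c(rep(TRUE, 4), rep(FALSE, 6), rep(TRUE, 4), rep(FALSE, 6)),
    amplitude = 1, onset_frame = 1, duration = 1, archetype = "transient")
  calls$archetype[!calls$responder] <- "nonresponder"
  ov <- sequential_overlap(calls)
  expect_equal(ov$n_new, c(4, 0))
  expect_equal(ov$union_n, c(4, 4))
  expect_true(all(ov$union_share <= cumsum(100 * ov$n_responders / 10)))
  disjoint <- calls
  disjoint$cell <- c(1:10, 11:20)
  expect_error(sequential_overlap(disjoint), "disjoint")
})

test_that("clone summaries aggregate per-clone shares", {
  calls <- data.frame(cell = 1:20, stimulus = "forskolin", stim_time = 10,
                      responder = c(rep(FALSE, 10), rep(TRUE, 10)),
                      amplitude = 1, onset_frame = 1, duration = 1,
                      archetype = c(rep("nonresponder", 10),
                                    rep("transient", 10)))
  cl <- clone_summary(calls, clone = rep(c("c1", "c2"), each = 10))
  expect_equal(cl$per_clone$share, c(0, 100))
  expect_equal(cl$grand_mean, 50)
  expect_equal(cl$se, 50)
  expect_error(clone_summary(calls, clone = rep("c1", 20)), ">= 2 clones")
})

test_that("baseline windows shorter than two frames are an error", {
  v <- matrix(0, 1, 41, dimnames = list("1", NULL))
  tr <- mk_traces(v, 0:40, single_prot)
  expect_error(call_responses(tr, call_params(b_win = 1)), "fewer than 2")
})
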