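test_that("model MFPT matches geometric waiting times and conventions", {
  P <- rbind(c(0.9, 0.1), c(0.3, 0.7))
  m <- markov_model_from_transition(P, lag = 1, frame_interval = 1)
  expect_equal(mfpt(m, 1, 2), 10, tolerance = 1e-10)
  expect_equal(mfpt(m, 1, 1), 0)
  # physical time: lag 1 frame, frame_interval 1 ns -> 10 ns
  m_ns <- markov_model_from_transition(P, lag = 1, frame_interval = 1e-3)
  expect_equal(mfpt(m_ns, 1, 2), 0.01, tolerance = 1e-12)
})

test_that("model MFPT equals the analytic chain oracle on 3-5 state fixtures", {
  chains <- list(
    linear_three_chain(),
    default_binding_chain(),
    ground_truth_chain(rbind(c(0.7, 0.2, 0.1, 0),
                             c(0.1, 0.6, 0.2, 0.1),
                             c(0.05, 0.15, 0.7, 0.1),
                             c(0, 0.1, 0.2, 0.7)))
  )
  for (ch in chains) {
    m <- markov_model_from_transition(ch$transition_matrix, lag = 1,
                                      frame_interval = ch$lag_time)
    n <- ch$n_states
    expect_equal(mfpt(m, 1, n), analytic_mfpt(ch, 1, n)$time,
                 tolerance = 1e-8)
    expect_equal(mfpt(m, 2, n), analytic_mfpt(ch, 2, n)$time,
                 tolerance = 1e-8)
  }
})

test_that("box volume converts Angstrom bounds to nm^3", {
  expect_identical(box_volume(c(-20, 20, -20, 20, -20, 35)), 88)
  expect_identical(box_volume(c(0, 10, 0, 10, 0, 10)), 1)
  expect_equal(box_volume(c(-40, 40, -20, 20, -20, 35)),
               2 * box_volume(c(-20, 20, -20, 20, -20, 35)))
  expect_error(box_volume(c(20, -20, -20, 20, -20, 35)), "bounds")
})

test_that("effective concentration is the reciprocal molar volume", {
  expect_equal(effective_concentration(1.6606), 1, tolerance = 1e-4)
  expect_equal(effective_concentration(88) * 1e3, 18.9, tolerance = 0.05)
  expect_equal(effective_concentration(176),
               effective_concentration(88) / 2)
})

test_that("k_on is the reciprocal of MFPT times concentration", {
  expect_identical(k_on(1, 1), 1)
  expect_equal(k_on(7e-6, 0.0189), 1 / (7e-6 * 0.0189))
  expect_equal(k_on(1e-6, 0.005), 2 * k_on(1e-6, 0.01))
})

test_that("state free energies follow -RT log population ratios", {
  RT <- 1.98720e-3 * 298
  dg <- state_free_energies(c(0.5, 0.5), bulk_id = 1)
  expect_equal(dg$delta_g, c(0, 0))
  dg2 <- state_free_energies(c(1 / 11, 10 / 11), bulk_id = 1)
  expect_equal(dg2$delta_g[2], -RT * log(10), tolerance = 1e-10)
  pi_e <- c(1, exp(1)) / (1 + exp(1))
  dg3 <- state_free_energies(pi_e, bulk_id = 1)
  expect_equal(dg3$delta_g[2], -RT, tolerance = 1e-10)
  # artificial doubling of the bulk population shifts all dG by -RT log 2
  pi1 <- c(0.2, 0.5, 0.3)
  pi2 <- c(0.4, 0.5, 0.3) / 1.2
  a <- state_free_energies(pi1, 1)$delta_g[-1]
  b <- state_free_energies(pi2, 1)$delta_g[-1]
  expect_equal(b - a, rep(RT * log(2), 2), tolerance = 1e-10)
})

test_that("pathway classification follows the last-bulk-to-first-bound rule", {
  expect_equal(
    classify_binding_pathways(list(c(1L, 2L, 4L)), 1, 4, 3)$fractions,
    c(direct = 1, indirect = 0))
  out <- classify_binding_pathways(list(c(1L, 2L, 4L), c(1L, 2L, 3L, 4L)),
                                   1, 4, 3)
  expect_equal(out$fractions, c(direct = 0.5, indirect = 0.5))
  expect_identical(out$n_events, 2L)
  expect_warning(
    none <- classify_binding_pathways(list(c(1L, 2L, 2L)), 1, 4, 3),
    "no complete")
  expect_identical(none$n_events, 0L)
  # re-entering bulk resets the segment
  out2 <- classify_binding_pathways(list(c(1L, 3L, 1L, 2L, 4L)), 1, 4, 3)
  expect_equal(out2$fractions[["indirect"]], 0)
})

test_that("the blip filter ignores single-frame visits", {
  # one-frame bound blip inside a bulk stretch is not an event at min_dwell 2
  s <- c(1L, 1L, 4L, 1L, 1L, 2L, 2L, 4L, 4L)
  raw <- classify_binding_pathways(list(s), 1, 4, 3)
  expect_identical(raw$n_events, 2L)
  filt <- classify_binding_pathways(list(s), 1, 4, 3, min_dwell = 2)
  expect_identical(filt$n_events, 1L)
  expect_equal(filt$fractions[["direct"]], 1)
})

test_that("kinetics report is internally consistent", {
  ch <- default_binding_chain()
  dt <- sample_discrete_trajectories(ch, 100, 1500, seed = 55)
  # identity macrostate map over the 5 true states
  map <- structure(list(labels = 1:5, membership = diag(5), n_macro = 5L,
                        bulk_id = 1L, active_set = 1:5),
                   class = "macrostate_map")
  m <- estimate_reversible(trim_ergodic(count_matrix(dt, 1))$counts,
                           lag = 1, frame_interval = 0.1, active_set = 1:5)
  rep <- kinetics_report(m, map, dt, bound_id = 4, marker_id = 3)
  expect_equal(rep$k_on, 1 / (rep$mfpt_on * 1e-6 * rep$c_eff),
               tolerance = 1e-10)
  expect_equal(rep$volume_nm3, 88)
  expect_true(all(diag(rep$mfpt) == 0))
  expect_equal(sum(rep$pathway_fractions), 1)
  expect_equal(sum(rep$pi_macro), 1, tolerance = 1e-10)
})

test_that("bootstrap errors are seeded and vanish for identical trajectories", {
  ch <- default_binding_chain()
  dt <- sample_discrete_trajectories(ch, 30, 1500, seed = 56)
  map <- structure(list(labels = 1:5, membership = diag(5), n_macro = 5L,
                        bulk_id = 1L, active_set = 1:5),
                   class = "macrostate_map")
  e1 <- bootstrap_errors(dt, map, 4, 3, lag = 1, frame_interval = 0.1,
                         n_boot = 20, seed = 5)
  e2 <- bootstrap_errors(dt, map, 4, 3, lag = 1, frame_interval = 0.1,
                         n_boot = 20, seed = 5)
  expect_identical(e1$se, e2$se)
  expect_gt(e1$se[["mfpt_on"]], 0)
  # replicates of one repeated trajectory have zero spread
  one <- dt[[1]]
  same <- rep(list(one), 10)
  e3 <- suppressWarnings(
    bootstrap_errors(same, map, 4, 3, lag = 1, frame_interval = 0.1,
                     n_boot = 10, seed = 6))
  expect_equal(unname(e3$se["mfpt_on"]), 0, tolerance = 1e-12)
})
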