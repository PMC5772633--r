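block_chain_model <- function() {
  # two metastable 2-state blocks: intra 0.45, inter 0.05 (rows sum to 1)
  P <- rbind(c(0.45, 0.45, 0.05, 0.05),
             c(0.45, 0.45, 0.05, 0.05),
             c(0.05, 0.05, 0.45, 0.45),
             c(0.05, 0.05, 0.45, 0.45))
  C <- round(1e4 * P)  # symmetric counts from the uniform stationary law
  estimate_reversible(C)
}

test_that("PCCA recovers block structure from the spectrum", {
  m <- block_chain_model()
  map <- pcca_lump(m, n_macro = 2)
  expect_identical(map$labels[1], map$labels[2])
  expect_identical(map$labels[3], map$labels[4])
  expect_false(map$labels[1] == map$labels[3])
  expect_equal(rowSums(map$membership), rep(1, 4), tolerance = 1e-10)
})

test_that("PCCA with n_macro equal to n gives singleton macrostates", {
  m <- block_chain_model()
  map <- pcca_lump(m, n_macro = 4)
  expect_identical(sort(map$labels), 1:4)
  expect_error(pcca_lump(m, n_macro = 5), "exceeds")
})

test_that("memberships are a proper fuzzy partition on rough chains", {
  set.seed(41)
  ch <- default_binding_chain()
  dt <- sample_discrete_trajectories(ch, 30, 1000, seed = 41)
  emb <- embed_chain_features(dt, 5, seed = 41)
  tica <- fit_tica(emb$contacts, lag = 2)
  proj <- lapply(emb$contacts, function(x) tica_transform(tica, x))
  cl <- cluster_microstates(proj, k = 30, seed = 41)
  m <- estimate_reversible(trim_ergodic(count_matrix(cl$dtrajs, 1))$counts,
                           active_set = trim_ergodic(count_matrix(cl$dtrajs, 1))$active)
  map <- pcca_lump(m, 4)
  expect_true(all(map$membership >= 0 & map$membership <= 1))
  expect_equal(rowSums(map$membership), rep(1, nrow(map$membership)),
               tolerance = 1e-10)
})

test_that("bulk split moves majority-flag-0 clusters to a new state", {
  # 3 microstates; hand-built map
  map <- structure(list(labels = c(1L, 1L, 2L),
                        membership = rbind(c(1, 0), c(1, 0), c(0, 1)),
                        n_macro = 2L, bulk_id = NA_integer_,
                        active_set = 1:3),
                   class = "macrostate_map")
  dtrajs <- list(c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 2L, 3L, 3L))
  flags <- list(c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L, 1L, 0L, 1L, 1L))
  # cluster 1: 100% flag0 -> bulk; cluster 2: 1/6 flag0 -> stays; cluster 3 stays
  out <- split_bulk(map, dtrajs, flags)
  expect_identical(out$n_macro, 3L)
  expect_identical(out$bulk_id, 3L)
  expect_identical(out$labels, c(3L, 1L, 2L))
  # tie at exactly 50 % goes to bulk
  flags2 <- list(c(0L, 0L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 0L, 1L, 1L))
  map2 <- split_bulk(map, list(c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 2L,
                                 3L, 3L)), flags2)
  expect_identical(map2$labels[1], map2$bulk_id)
  # all-interacting flags leave the map unchanged with a warning
  expect_warning(out3 <- split_bulk(map, dtrajs, list(rep(1L, 12))),
                 "no bulk")
  expect_identical(out3$labels, map$labels)
})

test_that("bulk split recovers the true bulk state on generated data", {
  ch <- default_binding_chain()
  dt <- sample_discrete_trajectories(ch, 50, 1000, seed = 44)
  emb <- embed_chain_features(dt, 5, flag_prob_bulk0 = 0.95, seed = 44)
  cfg <- pipeline_config(k = 40, tica_lag = 2, msm_lag = 2,
                         frame_interval = 0.1, seed = 44, use_cores = FALSE)
  fit <- fit_binding_msm(emb$contacts, emb$flags, cfg)
  map <- fit$map
  # which true state dominates each bulk-labeled cluster?
  truth <- unlist(dt)
  micro <- unlist(fit$dtrajs)
  idx <- match(micro, map$active_set)
  bulk_clusters <- which(map$labels == map$bulk_id)
  true_bulk_clusters <- which(vapply(seq_along(map$active_set), function(c_id) {
    fr <- truth[which(idx == c_id)]
    length(fr) > 0 && mean(fr == 1) > 0.5
  }, logical(1)))
  expect_gte(mean(true_bulk_clusters %in% bulk_clusters), 0.99)
})

test_that("core milestoning follows the last-visited-core rule", {
  map <- structure(list(labels = c(1L, 1L, 2L),
                        membership = rbind(c(0.95, 0.05), c(0.6, 0.4),
                                           c(0.05, 0.95)),
                        n_macro = 2L, bulk_id = NA_integer_,
                        active_set = 1:3),
                   class = "macrostate_map")
  # cores: cluster 1 (macro 1), cluster 3 (macro 2); cluster 2 is no core
  core <- core_assign(map, list(c(1L, 2L, 2L, 3L)), threshold = 0.9)
  expect_identical(core$dtrajs[[1]], c(1L, 1L, 1L, 3L))
  # leading non-core frames are dropped
  core2 <- core_assign(map, list(c(2L, 2L, 1L, 3L)), threshold = 0.9)
  expect_identical(core2$dtrajs[[1]], c(1L, 3L))
  # all clusters above threshold: milestoning is the identity
  map_hi <- map
  map_hi$membership <- rbind(c(1, 0), c(1, 0), c(0, 1))
  core3 <- core_assign(map_hi, list(c(1L, 2L, 3L)), threshold = 0.9)
  expect_identical(core3$dtrajs[[1]], c(1L, 2L, 3L))
})

test_that("core re-estimation removes excursion-mediated recrossings", {
  ch <- default_binding_chain()
  dt <- sample_discrete_trajectories(ch, 200, 1000, seed = 46)
  emb <- embed_chain_features(dt, 5, seed = 46)
  cfg <- pipeline_config(k = 50, tica_lag = 5, msm_lag = 5,
                         frame_interval = 0.1, seed = 46)
  fit <- suppressWarnings(fit_binding_msm(emb$contacts, emb$flags, cfg))
  # number of macrostates never increases under core re-estimation
  core_macros <- unique(fit$core_map$labels)
  expect_lte(length(core_macros), fit$map$n_macro)
})

test_that("milestoning suppresses excursions into foreign non-core clusters", {
  # clusters: 1 = core of A, 2 = non-core boundary of B, 3 = core of B
  map <- structure(list(labels = c(1L, 2L, 2L),
                        membership = rbind(c(0.97, 0.03), c(0.4, 0.6),
                                           c(0.02, 0.98)),
                        n_macro = 2L, bulk_id = NA_integer_,
                        active_set = 1:3),
                   class = "macrostate_map")
  # a brief excursion from core A into B's boundary, never reaching B's core
  traj <- list(c(1L, 2L, 1L, 1L, 2L, 2L, 1L))
  core <- core_assign(map, traj, threshold = 0.9)
  C_raw <- count_matrix(traj, 1, n_states = 3)
  C_core <- count_matrix(core$dtrajs, 1, n_states = 3)
  macroC <- function(C) {
    K <- matrix(0, 2, 2)
    for (a in 1:2) for (b in 1:2) {
      K[a, b] <- sum(C[map$labels == a, map$labels == b, drop = FALSE])
    }
    K
  }
  expect_gt(macroC(C_raw)[1, 2], 0)       # raw counts show fake A -> B flux
  expect_equal(macroC(C_core)[1, 2], 0)   # milestoned counts do not
  expect_equal(macroC(C_core)[2, 1], 0)
})
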