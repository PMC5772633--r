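# End-to-end orchestration: contact features -> TICA -> mini-batch k-means
# -> reversible MSM -> PCCA lumping -> bulk split (-> optional core-set
# re-estimation) -> kinetics report, under a single seeded configuration.

#' Default pipeline configuration
#'
#' Records every tunable of the analysis: contact cutoffs (5 and 10
#' Angstrom), TICA lag and dimensionality (5 slow components), number of
#' k-means microstates (800), MSM lag, number of kinetic macrostates before
#' the bulk split (4), core membership threshold (0.9), the flat-bottom box
#' and temperature, bootstrap size and the master seed. Per-stage seeds are
#' expanded deterministically from the master seed.
#'
#' @param ... named overrides of the defaults.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    contact_cutoff = 5,
    bulk_cutoff = 10,
    tica_lag = 20L,
    n_components = 5L,
    k = 800L,
    msm_lag = 20L,
    n_macro = 4L,
    core_threshold = 0.9,
    use_cores = TRUE,
    pathway_min_dwell = 2L,
    box_bounds = c(-20, 20, -20, 20, -20, 35),
    temperature = 298,
    n_boot = 100L,
    frame_interval = 1,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

stage_seed <- function(cfg, stage) {
  offs <- c(cluster = 11L, bootstrap = 23L)
  as.integer((as.numeric(cfg$seed) * 131 + offs[[stage]]) %% 2147483647)
}

#' Fit the featurization-to-macrostates chain of the pipeline
#'
#' Runs TICA on the binary contact tracks, discretizes the projection with
#' mini-batch k-means, estimates a reversible Markov model on the largest
#' ergodic component, lumps microstates by PCCA and splits out the bulk
#' macrostate by the interaction flag. With `use_cores = TRUE`, the model
#' is re-estimated on core-set milestoned trajectories.
#'
#' @param contacts list of frames x features 0/1 matrices (the residue
#'   contact map tracks).
#' @param flags list of per-frame 0/1 interaction flags aligned with
#'   `contacts`.
#' @param config a [pipeline_config()].
#' @return list with `tica`, `clusters`, `dtrajs`, `model`, `map`
#'   (macrostate map with bulk split applied) and, when cores are used,
#'   `core` and `core_model`.
#' @export
fit_binding_msm <- function(contacts, flags, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  tica <- fit_tica(contacts, lag = config$tica_lag,
                   n_components = config$n_components)
  proj <- lapply(contacts, function(x) tica_transform(tica, x))
  cl <- cluster_microstates(proj, k = config$k,
                            seed = stage_seed(config, "cluster"))
  C <- count_matrix(cl$dtrajs, config$msm_lag, n_states = config$k)
  tr <- trim_ergodic(C)
  model <- estimate_reversible(tr$counts, lag = config$msm_lag,
                               frame_interval = config$frame_interval,
                               active_set = tr$active)
  map <- pcca_lump(model, n_macro = config$n_macro)
  map <- split_bulk(map, cl$dtrajs, flags)
  out <- list(tica = tica, clusters = cl, dtrajs = cl$dtrajs,
              model = model, map = map, config = config)
  if (isTRUE(config$use_cores)) {
    core <- core_assign(map, cl$dtrajs, threshold = config$core_threshold)
    Cc <- count_matrix(core$dtrajs, config$msm_lag, n_states = config$k)
    trc <- trim_ergodic(Cc)
    out$core <- core
    out$core_model <- estimate_reversible(trc$counts, lag = config$msm_lag,
                                          frame_interval = config$frame_interval,
                                          active_set = trc$active)
    out$core_map <- restrict_map(map, trc$active)
  }
  out
}

# restrict a macrostate map to a new active set (original cluster numbering)
restrict_map <- function(map, active) {
  idx <- match(active, map$active_set)
  stopifnot(!any(is.na(idx)))
  structure(
    list(labels = map$labels[idx],
         membership = map$membership[idx, , drop = FALSE],
         n_macro = map$n_macro, bulk_id = map$bulk_id,
         active_set = active),
    class = "macrostate_map"
  )
}

# entry (vestibule-like) state: among non-bulk, non-bound macrostates, the
# one with the largest aggregated transition probability back to bulk --
# deeper intermediates and off-pathway states have essentially none
detect_entry_state <- function(model, map, bound_id) {
  cand <- setdiff(seq_len(map$n_macro), c(map$bulk_id, bound_id))
  if (!length(cand)) return(integer(0))
  pi <- model$stationary_distribution
  T_mat <- model$transition_matrix
  to_bulk <- vapply(cand, function(s) {
    rows <- which(map$labels == s)
    cols <- which(map$labels == map$bulk_id)
    if (!length(rows) || !length(cols)) return(0)
    w <- pi[rows] / sum(pi[rows])
    sum(w * rowSums(T_mat[rows, cols, drop = FALSE]))
  }, numeric(1))
  if (max(to_bulk) <= 0) return(integer(0))
  cand[which.max(to_bulk)]
}

#' Run the full binding-kinetics pipeline
#'
#' [fit_binding_msm()] followed by [kinetics_report()] and (optionally)
#' [bootstrap_errors()]. The bound and marker macrostates are identified
#' automatically as, respectively, the most populated non-bulk macrostate
#' and the remaining macrostate(s) on the indirect route, unless given.
#'
#' @inheritParams fit_binding_msm
#' @param bound_id,marker_id macrostate ids; `NULL` for automatic choice
#'   (bound = highest stationary mass among non-bulk states; marker = the
#'   non-bulk, non-bound states excluding the entry state first reached
#'   from bulk, i.e. the intermediate(s) defining the indirect route).
#' @param with_bootstrap compute bootstrap errors (default `FALSE`).
#' @return list with the `fit`, the `report`, the chosen `bound_id`,
#'   `entry_id` and `marker_id`, and optionally `errors`. Kinetics are
#'   computed on the core-set re-estimated model when the config uses
#'   cores, as the protocol prescribes.
#' @export
run_binding_pipeline <- function(contacts, flags,
                                 config = pipeline_config(),
                                 bound_id = NULL, marker_id = NULL,
                                 with_bootstrap = FALSE) {
  fit <- fit_binding_msm(contacts, flags, config)
  if (isTRUE(config$use_cores)) {
    model <- fit$core_model
    map <- fit$core_map
    dtrajs <- fit$core$dtrajs
  } else {
    model <- fit$model
    map <- fit$map
    dtrajs <- fit$dtrajs
  }
  pi_macro <- vapply(seq_len(map$n_macro), function(m) {
    sum(model$stationary_distribution[map$labels == m])
  }, numeric(1))
  if (is.null(bound_id)) {
    cand <- setdiff(seq_len(map$n_macro), map$bulk_id)
    bound_id <- cand[which.max(pi_macro[cand])]
  }
  entry_id <- detect_entry_state(model, map, bound_id)
  if (is.null(marker_id)) {
    marker_id <- setdiff(seq_len(map$n_macro),
                         c(map$bulk_id, bound_id, entry_id))
  }
  report <- kinetics_report(model, map, dtrajs, bound_id, marker_id,
                            box_bounds = config$box_bounds,
                            temperature = config$temperature,
                            min_dwell = config$pathway_min_dwell)
  out <- list(fit = fit, report = report, bound_id = bound_id,
              entry_id = entry_id, marker_id = marker_id)
  if (isTRUE(with_bootstrap)) {
    out$errors <- bootstrap_errors(dtrajs, map, bound_id, marker_id,
                                   lag = config$msm_lag,
                                   frame_interval = config$frame_interval,
                                   box_bounds = config$box_bounds,
                                   temperature = config$temperature,
                                   n_boot = config$n_boot,
                                   seed = stage_seed(config, "bootstrap"),
                                   min_dwell = config$pathway_min_dwell)
  }
  out
}

#' Match recovered macrostates to ground-truth states
#'
#' Majority-vote mapping: each recovered macrostate is assigned the
#' ground-truth state most frequent among its frames; agreement is the
#' fraction of frames whose mapped label equals the truth.
#'
#' @param macro_trajs recovered macrostate sequences (`NA` ignored).
#' @param true_trajs ground-truth state sequences, frame-aligned.
#' @return list with `agreement` (fraction), `mapping` (named vector
#'   macrostate -> truth state) and `n_macro_used`.
#' @export
macrostate_agreement <- function(macro_trajs, true_trajs) {
  a <- unlist(macro_trajs, use.names = FALSE)
  b <- unlist(true_trajs, use.names = FALSE)
  stopifnot(length(a) == length(b))
  ok <- !is.na(a)
  a <- a[ok]
  b <- b[ok]
  tab <- table(a, b)
  mapping <- apply(tab, 1, function(r) as.integer(colnames(tab)[which.max(r)]))
  mapped <- mapping[as.character(a)]
  list(agreement = mean(mapped == b),
       mapping = mapping,
       n_macro_used = length(unique(a)))
}
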