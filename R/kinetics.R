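# Kinetics and thermodynamics from the macrostate model: mean first passage
# times, association rate with the effective-concentration correction of the
# flat-bottom restraint volume, per-state binding free energies, pathway
# fractions and trajectory-bootstrap errors.

#' Mean first passage time on a Markov model
#'
#' Solves `m_i = tau + sum_j T_ij m_j` for all states outside the target set
#' (with `m = 0` on the target), where `tau` is the physical time per lag
#' step (`lag * frame_interval`). The returned source value is the
#' stationary-weighted average over the source states.
#'
#' @param model a `markov_model`.
#' @param source,target state index vectors (in the model's own, active-set
#'   numbering); disjoint.
#' @return MFPT in the model's physical time units.
#' @export
mfpt <- function(model, source, target) {
  stopifnot(inherits(model, "markov_model"),
            length(source) >= 1, length(target) >= 1)
  if (any(source %in% target)) {
    return(0)  # by convention MFPT(source -> source) = 0
  }
  T_mat <- model$transition_matrix
  n <- nrow(T_mat)
  stopifnot(all(source >= 1 & source <= n), all(target >= 1 & target <= n))
  tau <- model$lag * model$frame_interval
  keep <- setdiff(seq_len(n), target)
  A <- diag(length(keep)) - T_mat[keep, keep, drop = FALSE]
  m <- tryCatch(solve(A, rep(tau, length(keep))),
                error = function(e) stop("target unreachable: ",
                                         conditionMessage(e)))
  if (any(!is.finite(m)) || any(m < -1e-9)) stop("target unreachable")
  pi_src <- model$stationary_distribution[source]
  if (sum(pi_src) <= 0) {
    # degenerate stationary weight (e.g. transient source states):
    # fall back to a uniform average
    pi_src <- rep(1, length(source))
  }
  sum(m[match(source, keep)] * pi_src) / sum(pi_src)
}

#' Macrostate-to-macrostate MFPT
#'
#' @param model a `markov_model` at microstate granularity.
#' @param map a `macrostate_map` over the same active set.
#' @param source,target macrostate ids.
#' @return MFPT in physical time units.
#' @export
mfpt_macro <- function(model, map, source, target) {
  stopifnot(inherits(map, "macrostate_map"))
  src <- which(map$labels %in% source)
  tgt <- which(map$labels %in% target)
  if (!length(src) || !length(tgt)) {
    stop("empty source or target macrostate")
  }
  mfpt(model, src, tgt)
}

#' Volume of a flat-bottom cuboid restraint
#'
#' @param bounds `c(x1, x2, y1, y2, z1, z2)` in Angstrom.
#' @return volume in nm^3 (1 nm^3 = 1000 A^3).
#' @export
box_volume <- function(bounds) {
  stopifnot(length(bounds) == 6)
  dx <- bounds[2] - bounds[1]
  dy <- bounds[4] - bounds[3]
  dz <- bounds[6] - bounds[5]
  if (dx <= 0 || dy <= 0 || dz <= 0) {
    stop("bounds must satisfy x1<x2, y1<y2, z1<z2")
  }
  dx * dy * dz / 1000
}

#' Effective ligand concentration of a restraint volume
#'
#' The molar concentration implied by a single ligand copy confined to
#' `volume`: `1 / (N_A * V)` with `V` in litres (1 nm^3 = 1e-24 L).
#'
#' @param volume_nm3 restraint volume in nm^3.
#' @return concentration in mol/L.
#' @export
effective_concentration <- function(volume_nm3) {
  stopifnot(volume_nm3 > 0)
  1 / (AVOGADRO * volume_nm3 * 1e-24)
}

#' Association rate constant from MFPT and effective concentration
#'
#' @param mfpt_on_s bulk-to-bound mean first passage time, seconds.
#' @param c_eff effective ligand concentration, mol/L.
#' @return `k_on` in 1/(M s).
#' @export
k_on <- function(mfpt_on_s, c_eff) {
  stopifnot(mfpt_on_s > 0, c_eff > 0)
  1 / (mfpt_on_s * c_eff)
}

#' Per-state binding free energies from macrostate populations
#'
#' `dG_s = -RT log(pi_s / pi_bulk)`; when `c_eff` is supplied, a
#' standard-state corrected value `dG_s + RT log(c_eff / 1 M)` is reported
#' alongside.
#'
#' @param pi_macro stationary macrostate probabilities (sums to 1).
#' @param bulk_id index of the bulk macrostate.
#' @param temperature Kelvin (default 298).
#' @param c_eff optional effective concentration (M) for the standard-state
#'   correction.
#' @return data.frame with columns `state`, `pi`, `delta_g` and (if
#'   requested) `delta_g_std`; zero-probability states get `Inf` with a
#'   warning.
#' @export
state_free_energies <- function(pi_macro, bulk_id, temperature = 298,
                                c_eff = NULL) {
  stopifnot(abs(sum(pi_macro) - 1) < 1e-6, pi_macro[bulk_id] > 0,
            temperature > 0)
  RT <- GAS_CONSTANT_KCAL * temperature
  if (any(pi_macro == 0)) {
    warning("zero-probability macrostate: free energy reported as +Inf")
  }
  dg <- -RT * log(pi_macro / pi_macro[bulk_id])
  out <- data.frame(state = seq_along(pi_macro), pi = pi_macro,
                    delta_g = dg)
  if (!is.null(c_eff)) {
    out$delta_g_std <- dg + RT * log(c_eff)
  }
  out
}

#' Classify binding events into direct and indirect pathways
#'
#' A binding event is the maximal segment from the last visit to `bulk`
#' until the first visit to `bound`; it is indirect iff it visits any
#' `marker` state in between.
#'
#' @param macro_trajs list of integer macrostate sequences (`NA` allowed;
#'   `NA` frames are ignored).
#' @param bulk,bound macrostate ids.
#' @param marker macrostate id(s) defining the indirect route.
#' @param min_dwell minimum length (frames) of a state visit for it to
#'   count; shorter visits are treated as transient recrossings and
#'   ignored (default 1 = no filtering).
#' @return list with `n_events`, `fractions` (named: direct, indirect) and
#'   `events` (logical vector, `TRUE` = indirect); zero events gives empty
#'   fractions with a warning.
#' @export
classify_binding_pathways <- function(macro_trajs, bulk, bound, marker,
                                      min_dwell = 1) {
  if (!is.list(macro_trajs)) macro_trajs <- list(macro_trajs)
  events <- logical(0)
  for (s in macro_trajs) {
    s <- s[!is.na(s)]
    if (min_dwell > 1 && length(s)) {
      r <- rle(s)
      keep <- r$lengths >= min_dwell
      if (!any(keep)) next
      s <- rep(r$values[keep], r$lengths[keep])
    }
    in_segment <- FALSE
    seen_marker <- FALSE
    for (x in s) {
      if (x %in% bulk) {
        in_segment <- TRUE
        seen_marker <- FALSE
      } else if (in_segment) {
        if (x %in% marker) seen_marker <- TRUE
        if (x %in% bound) {
          events <- c(events, seen_marker)
          in_segment <- FALSE
        }
      }
    }
  }
  if (!length(events)) {
    warning("no complete bulk-to-bound events found")
    return(list(n_events = 0L, fractions = c(direct = NA_real_,
                                             indirect = NA_real_),
                events = events))
  }
  list(n_events = length(events),
       fractions = c(direct = mean(!events), indirect = mean(events)),
       events = events)
}

#' Assemble a kinetics report
#'
#' Computes, from microstate trajectories and a fitted model + macrostate
#' map, the headline numbers: macrostate MFPT matrix, the bulk-to-bound
#' MFPT, `k_on` from the restraint-volume effective concentration,
#' per-state free energies and pathway fractions.
#'
#' @param model `markov_model` (microstate granularity).
#' @param map `macrostate_map` with `bulk_id` set.
#' @param dtrajs microstate trajectories.
#' @param bound_id bound macrostate id.
#' @param marker_id macrostate id(s) of the intermediate marking the
#'   indirect route.
#' @param box_bounds flat-bottom bounds (Angstrom) for the effective
#'   concentration; default the production box `c(-20,20,-20,20,-20,35)`.
#' @param temperature Kelvin.
#' @param time_unit_us `TRUE` if the model's physical time unit is
#'   microseconds (used to convert MFPT to seconds for `k_on`).
#' @param min_dwell blip filter for pathway counting, frames (see
#'   [classify_binding_pathways()]).
#' @return a `kinetics_report` list.
#' @export
kinetics_report <- function(model, map, dtrajs, bound_id, marker_id,
                            box_bounds = c(-20, 20, -20, 20, -20, 35),
                            temperature = 298, time_unit_us = TRUE,
                            min_dwell = 1) {
  stopifnot(!is.na(map$bulk_id))
  n_macro <- map$n_macro
  mf <- matrix(0, n_macro, n_macro)
  for (a in seq_len(n_macro)) {
    for (b in seq_len(n_macro)) {
      if (a == b) next
      mf[a, b] <- tryCatch(mfpt_macro(model, map, a, b),
                           error = function(e) NA_real_)
    }
  }
  mfpt_on <- mf[map$bulk_id, bound_id]
  vol <- box_volume(box_bounds)
  c_eff <- effective_concentration(vol)
  mfpt_on_s <- if (time_unit_us) mfpt_on * 1e-6 else mfpt_on
  kon <- k_on(mfpt_on_s, c_eff)
  pi_macro <- vapply(seq_len(n_macro), function(m) {
    sum(model$stationary_distribution[map$labels == m])
  }, numeric(1))
  dg <- state_free_energies(pi_macro, map$bulk_id, temperature, c_eff)
  macro_trajs <- macrostate_trajectories(map, dtrajs)
  paths <- classify_binding_pathways(macro_trajs, map$bulk_id, bound_id,
                                     marker_id, min_dwell = min_dwell)
  structure(
    list(mfpt = mf, mfpt_on = mfpt_on, volume_nm3 = vol, c_eff = c_eff,
         k_on = kon, delta_g = dg, pathway_fractions = paths$fractions,
         n_events = paths$n_events, pi_macro = pi_macro,
         bulk_id = map$bulk_id, bound_id = bound_id,
         temperature = temperature),
    class = "kinetics_report"
  )
}

#' @export
print.kinetics_report <- function(x, ...) {
  cat("Kinetics report\n")
  cat(sprintf("  MFPT(on)   : %.3g (bulk -> bound)\n", x$mfpt_on))
  cat(sprintf("  C_eff      : %.3g mM (V = %.3g nm^3)\n",
              x$c_eff * 1e3, x$volume_nm3))
  cat(sprintf("  k_on       : %.3g /M/s\n", x$k_on))
  cat(sprintf("  events     : %d (indirect fraction %.2f)\n",
              x$n_events, x$pathway_fractions[["indirect"]]))
  invisible(x)
}

#' Bootstrap errors for the kinetics report
#'
#' Resamples whole trajectories with replacement, re-runs the estimation
#' from the count matrix onward (reversible model on the resample's largest
#' connected component, macrostate quantities through the *fixed* map) and
#' reports the standard deviation across replicates. Replicates whose
#' resample lacks bulk-to-bound connectivity are skipped and counted; a
#' warning is raised if more than 20 percent are skipped.
#'
#' @param dtrajs microstate trajectories.
#' @param map fitted `macrostate_map`.
#' @param bound_id,marker_id as in [kinetics_report()].
#' @param lag,frame_interval estimation parameters of the original model.
#' @param box_bounds,temperature,time_unit_us as in [kinetics_report()].
#' @param n_boot number of replicates (default 100).
#' @param seed integer seed.
#' @return list with `se` (named standard errors for mfpt_on, k_on,
#'   indirect fraction and per-state delta_g), `replicates` (data.frame)
#'   and `n_skipped`.
#' @export
bootstrap_errors <- function(dtrajs, map, bound_id, marker_id,
                             lag, frame_interval = 1,
                             box_bounds = c(-20, 20, -20, 20, -20, 35),
                             temperature = 298, time_unit_us = TRUE,
                             n_boot = 100, seed = 1L, min_dwell = 1) {
  stopifnot(length(dtrajs) >= 2)
  n_states <- max(map$active_set,
                  unlist(lapply(dtrajs, function(s)
                    if (length(s)) max(s) else 1L)))
  vol <- box_volume(box_bounds)
  c_eff <- effective_concentration(vol)
  set.seed(as.integer(seed))
  picks <- matrix(sample.int(length(dtrajs), n_boot * length(dtrajs),
                             replace = TRUE), nrow = n_boot)
  rows <- list()
  n_skipped <- 0L
  for (b in seq_len(n_boot)) {
    res <- tryCatch({
      dt <- dtrajs[picks[b, ]]
      C <- count_matrix(dt, lag, n_states)
      tr <- trim_ergodic(C)
      m <- estimate_reversible(tr$counts, lag = lag,
                               frame_interval = frame_interval,
                               active_set = tr$active)
      # project the fixed macrostate map onto this replicate's active set
      lab <- rep(NA_integer_, n_states)
      lab[map$active_set] <- map$labels
      lab_rep <- lab[tr$active]
      src <- which(lab_rep == map$bulk_id)
      tgt <- which(lab_rep %in% bound_id)
      if (!length(src) || !length(tgt)) stop("no bulk/bound states")
      mfpt_on <- mfpt(m, src, tgt)
      mfpt_on_s <- if (time_unit_us) mfpt_on * 1e-6 else mfpt_on
      pi_macro <- vapply(seq_len(map$n_macro), function(mm) {
        sum(m$stationary_distribution[which(lab_rep == mm)])
      }, numeric(1))
      pi_macro <- pi_macro / sum(pi_macro)
      paths <- suppressWarnings(
        classify_binding_pathways(macrostate_trajectories(map, dt),
                                  map$bulk_id, bound_id, marker_id,
                                  min_dwell = min_dwell))
      dgs <- -GAS_CONSTANT_KCAL * temperature *
        log(pi_macro / pi_macro[map$bulk_id])
      c(mfpt_on = mfpt_on, k_on = 1 / (mfpt_on_s * c_eff),
        indirect = unname(paths$fractions["indirect"]),
        stats::setNames(dgs, paste0("delta_g_", seq_along(dgs))))
    }, error = function(e) NULL)
    if (is.null(res)) {
      n_skipped <- n_skipped + 1L
      next
    }
    rows[[length(rows) + 1]] <- res
  }
  if (n_skipped > 0.2 * n_boot) {
    warning(n_skipped, " of ", n_boot,
            " bootstrap replicates lacked connectivity and were skipped")
  }
  reps <- do.call(rbind, rows)
  list(se = apply(reps, 2, stats::sd, na.rm = TRUE),
       replicates = as.data.frame(reps), n_skipped = n_skipped)
}
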