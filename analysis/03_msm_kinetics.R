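#!/usr/bin/env Rscript
# The central analysis: contact features -> TICA (5 components) ->
# mini-batch k-means -> reversible MSM -> PCCA + bulk split -> core-set
# re-estimation -> kinetics, on trajectories generated from the
# ground-truth binding chain, with bootstrap errors.
#
# Finding: the recovered model has 5 macrostates at >99 % frame agreement;
# MFPT(on) lands within ~10 % of the analytic truth and the indirect
# pathway fraction within ~1 percentage point; k_on follows from the
# 18.9 mM effective concentration of the 88 nm^3 flat-bottom box.

library(bindkin)
dir.create("results", showWarnings = FALSE)

chain <- default_binding_chain()
dtrajs <- sample_discrete_trajectories(chain, 1000, 1000, seed = 131)
emb <- embed_chain_features(dtrajs, chain$n_states, seed = 132)

cfg <- pipeline_config(k = 50, tica_lag = 5, msm_lag = 5,
                       frame_interval = chain$lag_time, n_boot = 50,
                       seed = 7)
res <- suppressWarnings(
  run_binding_pipeline(emb$contacts, emb$flags, cfg, with_bootstrap = TRUE))
print(res$report)

# implied timescales across lags for the working-lag choice
its <- suppressWarnings(
  implied_timescales(res$fit$dtrajs[1:200], lags = c(1, 2, 5, 10, 20),
                     n_timescales = 3, frame_interval = chain$lag_time))
write.csv(its, "results/implied_timescales.csv", row.names = FALSE)

mt <- macrostate_trajectories(res$fit$map, res$fit$dtrajs)
ag <- macrostate_agreement(mt, dtrajs)
truth <- analytic_mfpt(chain, "bulk", "bound")$time
truth_ind <- analytic_indirect_fraction(chain)
se <- res$errors$se

kin <- data.frame(
  quantity = c("n_macrostates", "frame_agreement", "mfpt_on_us",
               "mfpt_on_truth_us", "mfpt_on_se_us", "k_on_per_M_s",
               "k_on_se_per_M_s", "c_eff_mM", "box_volume_nm3",
               "indirect_fraction", "indirect_fraction_truth",
               "indirect_se", "n_binding_events"),
  value = c(res$fit$map$n_macro, ag$agreement, res$report$mfpt_on, truth,
            se[["mfpt_on"]], res$report$k_on, se[["k_on"]],
            res$report$c_eff * 1e3, res$report$volume_nm3,
            res$report$pathway_fractions[["indirect"]], truth_ind,
            se[["indirect"]], res$report$n_events)
)
write.csv(kin, "results/kinetics.csv", row.names = FALSE)

dg <- res$report$delta_g
dg$truth_state <- ag$mapping[as.character(dg$state)]
write.csv(dg, "results/macrostate_free_energies.csv", row.names = FALSE)
cat(sprintf("MFPT(on) %.2f +/- %.2f us (truth %.2f); indirect %.1f%% (truth %.1f%%)\n",
            res$report$mfpt_on, se[["mfpt_on"]], truth,
            100 * res$report$pathway_fractions[["indirect"]],
            100 * truth_ind))
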