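#!/usr/bin/env Rscript
# Ground truth for the study: the five-state binding chain (bulk,
# vestibule, intermediate, bound, off-pathway), its analytic kinetics, and
# a seeded trajectory sample.
#
# Finding: at 0.1 us per lag step the default chain has an analytic
# bulk->bound MFPT of ~7.4 us and ~30 % of binding events pass through the
# intermediate, i.e. the magnitudes the downstream pipeline must recover.

library(bindkin)
dir.create("results", showWarnings = FALSE)

chain <- default_binding_chain()
print(round(chain$transition_matrix, 4))

mfpt_on <- analytic_mfpt(chain, "bulk", "bound")
indirect <- analytic_indirect_fraction(chain)

# pairwise analytic MFPTs (in microseconds)
n <- chain$n_states
M <- matrix(0, n, n, dimnames = list(chain$state_labels, chain$state_labels))
for (a in seq_len(n)) for (b in seq_len(n)) {
  if (a != b) M[a, b] <- analytic_mfpt(chain, a, b)$time
}
write.csv(round(M, 3), "results/ground_truth_mfpt_us.csv")

dtrajs <- sample_discrete_trajectories(chain, n_traj = 200, n_steps = 2000,
                                       seed = 1)
occ <- tabulate(unlist(dtrajs), n) / (200 * 2000)
ev <- classify_binding_pathways(dtrajs, 1, 4, 3)

summary <- data.frame(
  quantity = c("mfpt_on_us", "indirect_fraction_analytic",
               "indirect_fraction_sampled", "n_binding_events",
               paste0("occupancy_", chain$state_labels)),
  value = c(mfpt_on$time, indirect, ev$fractions[["indirect"]],
            ev$n_events, occ)
)
write.csv(summary, "results/ground_truth_summary.csv", row.names = FALSE)
cat(sprintf("analytic MFPT(on) %.2f us; indirect fraction %.3f (sampled %.3f over %d events)\n",
            mfpt_on$time, indirect, ev$fractions[["indirect"]], ev$n_events))
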