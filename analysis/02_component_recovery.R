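#!/usr/bin/env Rscript
# Stage 2: parameter recovery of the extraction chain.
#
# Synthetic sessions are drawn from the per-modality population
# calibrations (one subject-level ground truth each) and pushed through
# the full continuous chain: 1-40 Hz zero-phase FIR, epoching with
# baseline correction, 150 uV artifact rejection, montage derivation,
# 3 dB SNR gate, rule-based N1/N2/P2 marking. Recovered group means are
# compared with the generating population means. 40 sessions per modality
# keep this stage to a few minutes; the test suite runs the same
# experiment at 100 sessions per modality.

suppressPackageStartupMessages(library(noxep))

dir.create("results", showWarnings = FALSE)
n_sessions <- 40

for (modality in c("lep", "chep")) {
  df <- recovery_experiment(modality, n_sessions = n_sessions, seed = 7)
  write.csv(df, sprintf("results/recovery_%s.csv", modality),
            row.names = FALSE)
  cat(sprintf("\n%s (%d sessions, %d excluded by the 3 dB gate):\n",
              toupper(modality), n_sessions, sum(df$excluded)))
  cat(sprintf("  N2 latency  %6.1f ms recovered vs %6.1f ms generated\n",
              mean(df$n2_latency, na.rm = TRUE), mean(df$true_n2_latency)))
  cat(sprintf("  P2 latency  %6.1f ms recovered vs %6.1f ms generated\n",
              mean(df$p2_latency, na.rm = TRUE), mean(df$true_p2_latency)))
  cat(sprintf("  N2P2        %6.1f uV recovered vs %6.1f uV generated\n",
              mean(df$n2p2_amplitude), mean(df$true_n2p2)))
  cat(sprintf("  N1 marked present in %d/%d sessions\n",
              sum(df$n1_present), n_sessions))
}
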