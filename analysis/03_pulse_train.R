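#!/usr/bin/env Rscript

# Repeated rapid increases: the 6/10/8 hr pulse protocol with 5 hr gaps
# re-triggers a near-full response at every pulse, while sustained exposure
# peaks once and adapts; the pulsed protocol drives more adaptive-gene
# output from less integrated ligand.
# Writes results/pulse_train*.{csv,json}.

suppressPackageStartupMessages(library(smaddyn))

rep <- run_pulse_train(high = 30, pulse_durations = c(6, 10, 8), gap = 5,
                       out_dir = "results")
print(rep$pulse_peaks)
cat(sprintf("\nresponse peaks: pulses %d, sustained %d\n",
            rep$pulses_n_peaks, rep$sustained_n_peaks))
cat(sprintf("adaptive-gene output (AUC): pulses %.2f vs sustained %.2f\n",
            rep$gene_auc_pulses, rep$gene_auc_sustained))
cat(sprintf("integrated ligand exposure: pulses %.0f vs sustained %.0f ng/ml x hr\n",
            rep$ligand_exposure_pulses, rep$ligand_exposure_sustained))
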