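#!/usr/bin/env Rscript

# Self-organized micropattern colony dynamics: kymograph generation,
# channel normalization, half-maximum front tracking. Recovers the
# programmed edge restriction (~by 12 hr), wave onset (25 hr) and inward
# wave velocity (10 um/hr), both directly from the kymograph and through
# the full imaging pipeline (rendered frames -> watershed segmentation ->
# per-cell nuc:cyt ratios -> radial profiles).
# Writes results/colony_wave*.{csv,json}.

suppressPackageStartupMessages(library(smaddyn))

rep <- run_colony_wave(colony_params(), seed = 1, render = TRUE,
                       out_dir = "results")
cat(sprintf("direct kymograph:  velocity %.2f um/hr, onset %.1f hr, edge restriction by %.1f hr\n",
            rep$velocity, rep$onset, rep$edge_restriction))
cat(sprintf("rendered pipeline: velocity %.2f um/hr, onset %.1f hr, edge restriction by %.1f hr\n",
            rep$rendered$velocity, rep$rendered$onset,
            rep$rendered$edge_restriction))
cat(sprintf("programmed truth:  velocity %.2f um/hr, onset %.1f hr, restriction crossing %.1f hr\n",
            rep$truth$wave_velocity, rep$truth$wave_onset,
            rep$truth$edge_restriction_time))
cat(sprintf("pSMAD1 front movement %.1f um (stationary: %s)\n",
            rep$psmad1_front_movement, rep$psmad1_stationary))
cat(sprintf("BRA domain inner boundary %.0f um trails the SMAD2/3 front at %.0f um\n",
            rep$bra_inner_boundary, rep$smad23_final_front))
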