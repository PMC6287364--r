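#!/usr/bin/env Rscript
# Trajectory-style flexibility metrics on the donor ensemble: backbone RMSD
# of every frame against the reference structure and per-residue RMSF about
# the ensemble mean. Writes results/rmsd_series.csv and results/rmsf.csv.

library(acidbridge)
donor <- read_pdb("results/donor_synthetic.pdb")
ensemble <- read_pdb("results/donor_ensemble_synthetic.pdb")

rs <- backbone_rmsd_series(ensemble, donor)
write.csv(data.frame(frame = rs$frame, rmsd = rs$rmsd),
          "results/rmsd_series.csv", row.names = FALSE)
cat(sprintf("mean backbone RMSD over %d frames: %.3f A\n",
            length(rs$rmsd), rs$mean_rmsd))

rmsf <- per_residue_rmsf(ensemble)
write.csv(rmsf, "results/rmsf.csv", row.names = FALSE)
cat(sprintf("per-residue RMSF: median %.3f A, max %.3f A at residue %d\n",
            median(rmsf$rmsf), max(rmsf$rmsf),
            rmsf$resnum[which.max(rmsf$rmsf)]))
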