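#!/usr/bin/env Rscript
# Exposure-design arithmetic: the ADI-anchored bioreactor dose and the
# flask/inoculum enumerators of the paired in vivo design. Writes
# results/dose_design.json.

library(vamrbiome)

dose <- bioreactor_dose(adi = 0.2, fraction_of_adi = 0.1, body_weight = 70,
                        reactor_volume = 250, molar_mass = 403.4)
des <- exposure_design()

cat(sprintf("Bioreactor dose: %.4f mg/ml (%.1f uM truncated; %.3f uM exact)\n",
            dose$conc_mg_ml, floor(dose$conc_um * 10) / 10, dose$conc_um))
cat(sprintf("Design: %d flasks, %.0e inoculum cells per bioreactor\n",
            des$n_flasks, des$inoculum_cells))

dir.create("results", showWarnings = FALSE)
jsonlite::write_json(
  list(dose_mg_per_ml = dose$conc_mg_ml,
       dose_um_truncated = floor(dose$conc_um * 10) / 10,
       dose_um_exact = dose$conc_um,
       n_flasks = des$n_flasks,
       inoculum_cells = des$inoculum_cells),
  "results/dose_design.json", auto_unbox = TRUE, digits = NA)
cat("Wrote results/dose_design.json\n")
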