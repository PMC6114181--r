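#!/usr/bin/env Rscript
# Emit a synthetic RI-panel input set with ground truth.
#
# Usage: Rscript scripts/simulate_panel.R --scenario full_mediation \
#          --n-strains 60 --seed 17 --out DIR

suppressPackageStartupMessages(library(mirmednet))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(scenario = "full_mediation", `n-strains` = 60L, seed = 1L,
            out = "panel", `n-mirna` = 60L, `n-genes` = 60L,
            `n-phenotypes` = 2L, `n-quadruples` = 1L)
i <- 1L
while (i <= length(args)) {
  key <- sub("^--", "", args[i])
  if (!key %in% names(opt)) stop("unknown argument: ", args[i])
  opt[[key]] <- if (is.numeric(opt[[key]])) as.integer(args[i + 1L])
    else args[i + 1L]
  i <- i + 2L
}

panel <- simulate_panel(n_strains = opt$`n-strains`,
                        n_mirna = opt$`n-mirna`, n_genes = opt$`n-genes`,
                        n_phenotypes = opt$`n-phenotypes`,
                        n_embedded_quadruples = opt$`n-quadruples`,
                        scenario = opt$scenario, seed = opt$seed)
write_panel(panel, opt$out)
cat(sprintf("wrote panel (%d strains, seed %d) to %s\n",
            opt$`n-strains`, opt$seed, opt$out))
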