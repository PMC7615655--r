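#!/usr/bin/env Rscript
# Regenerates the packaged topology preset JSON files from the in-code
# constructors. Run from the repository root after editing presets.
devtools::load_all(".", quiet = TRUE)
dir.create("inst/extdata/topologies", recursive = TRUE, showWarnings = FALSE)
for (p in c("glycolysis", "oxidative_tca", "reductive_branch",
            "bifurcated_tca", "ppp_shunt")) {
  write_topology(build_topology(p),
                 file.path("inst/extdata/topologies", paste0(p, ".json")))
}
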