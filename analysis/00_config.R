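## Shared configuration of the analysis workflow. Every numbered script
## sources this file, rebuilds the (deterministic) domain from it, and reads
## heavier artifacts of earlier steps from results/.
library(larvalink)

SEED <- 1L
CFG <- demo_config(seed = SEED)
RESULTS <- "results"
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

res_path <- function(...) file.path(RESULTS, ...)
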