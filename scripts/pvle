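#!/usr/bin/env Rscript
# Repository-root convenience wrapper; identical to the installed
# inst/cli/pvle script.
library(pvle)
quit(save = "no", status = pvle_cli(commandArgs(trailingOnly = TRUE)))
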