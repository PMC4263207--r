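#!/usr/bin/env Rscript
# Downloads the iJR904 genome-scale model of E. coli MG1655 from the BiGG
# Models repository into scratch/iJR904.xml, where the genome-scale test in
# tests/testthat/test-acceptance.R picks it up.  Needs network access; the
# model is not shipped with the package.

url <- "http://bigg.ucsd.edu/static/models/iJR904.xml"
dir.create("scratch", showWarnings = FALSE)
dest <- file.path("scratch", "iJR904.xml")
message("downloading ", url, " -> ", dest)
utils::download.file(url, dest, mode = "wb", quiet = FALSE)
message("done; re-run the test suite to include the genome-scale checks")
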