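# shared fixture builders: everything is generated in code, nothing binary.

meas <- function(ids, values, sd = NA_real_) {
  data.frame(reaction_id = ids, value = values, stddev = sd,
             stringsAsFactors = FALSE)
}

envdf <- function(ids, lower, upper) {
  data.frame(reaction_id = ids, lower = lower, upper = upper,
             stringsAsFactors = FALSE)
}

extdata <- function(f) system.file("extdata", f, package = "fluxkit")

# TOY-BR constrained to U = 10 with the branch ratio R1/U = 0.6: determined
toyBRDetermined <- function() {
  m <- makeFixture("TOY-BR")
  ec <- mergeConstraints(m, measurements = meas("U", 10),
                         ratios = list(fluxRatio(c(R1 = 1), c(U = 1), 0.6)))
  list(model = m, ec = ec)
}

# a small CSV model on disk, returned as paths (written into tempdir)
writeToyCSV <- function(dir = tempfile("csvmodel")) {
  dir.create(dir)
  rx <- file.path(dir, "reactions.csv")
  mt <- file.path(dir, "metabolites.csv")
  writeLines(c(
    "id,equation,lower_bound,upper_bound,gpr",
    "R2,A -> B,0,1000,",
    "R4,2 A <-> B + C,-1000,1000,g1 and g2",
    "R5,A ->,0,1000,",
    "U,-> A,0,1000,"), rx)
  writeLines(c(
    "id,name,compartment,external",
    "A,A,c,0",
    "B,B,c,0",
    "C,C,c,0"), mt)
  list(reactions = rx, metabolites = mt)
}
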