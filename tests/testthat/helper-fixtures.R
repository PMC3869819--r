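# Shared fixture builders: everything is generated in code under fixed seeds.

randomAmplicon <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A small but complete pooled screen: one amplicon, canonical 384-line
# design, a handful of planted mutations and homeologous SNPs.
smallSim <- function(len = 400L, depth = 2000L, nMutations = 4L, seed = 7L,
                     nHomeolog = 2L, errorRate = 5e-4) {
  amp <- c(amp1 = randomAmplicon(len, seed + 1L))
  params <- simParams(depth = depth, errorRate = errorRate,
                      nHomeolog = nHomeolog, seed = seed)
  truth <- simulatePopulation(amp, params, nMutations = nMutations)
  design <- buildDesign()
  counts <- simulatePoolCounts(truth, design, params)
  list(amp = amp, params = params, truth = truth, design = design,
       counts = counts)
}

# Hand-built truth object for controlled expectations (one known mutation).
handTruth <- function(amplicons, mutations, params,
                      homeologs = data.frame(amplicon = character(),
                                             pos = integer(),
                                             ref = character(),
                                             alt = character(),
                                             freq = numeric())) {
  grid <- expand.grid(column = 1:12, row = LETTERS[1:8],
                      plate = seq_len(params$nPlates),
                      stringsAsFactors = FALSE)
  structure(list(mutations = mutations, homeologs = homeologs,
                 lines = lineAddress(grid$plate, grid$row, grid$column),
                 amplicons = toupper(amplicons), params = params),
            class = "SimTruth")
}

mutationKey <- function(df) paste(df$amplicon, df$pos, df$ref, df$alt)
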