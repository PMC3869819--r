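test_that("zero density plants no mutations", {
  amp <- c(amp1 = randomAmplicon(300, 1))
  truth <- simulatePopulation(amp, simParams(density = 0, seed = 3))
  expect_equal(nrow(truth$mutations), 0L)
})

test_that("planted mutations respect the truth invariants", {
  sim <- smallSim(nMutations = 25L, seed = 11L)
  m <- sim$truth$mutations
  expect_equal(nrow(m), 25L)
  expect_true(all(m$alt != m$ref))
  expect_true(all(m$zygosity %in% c("het", "hom")))
  expect_true(all(m$pos >= 1L & m$pos <= nchar(sim$amp)))
  expect_true(all(m$line %in% sim$truth$lines))
  # homeolog sites are never mutation sites
  expect_length(intersect(paste(m$amplicon, m$pos),
                          paste(sim$truth$homeologs$amplicon,
                                sim$truth$homeologs$pos)), 0L)
})

test_that("mutation counts follow the Poisson density model", {
  # 384 lines x 1.6 kb at 1/109 per kb: lambda = 384*1.6/109 = 5.636 per run
  amp <- c(amp1 = randomAmplicon(1600, 2))
  lambda1 <- 384 * 1.6 / 109
  nRuns <- 30L
  total <- sum(vapply(seq_len(nRuns), function(s)
    nrow(simulatePopulation(amp, simParams(density = 1 / 109, seed = 100 + s,
                                           nHomeolog = 0))$mutations), 0L))
  ci <- qpois(c(0.005, 0.995), lambda1 * nRuns)
  expect_gte(total, ci[1L])
  expect_lte(total, ci[2L])
})

test_that("the planted spectrum matches the EMS fraction", {
  amp <- c(amp1 = randomAmplicon(1200, 5))
  truth <- simulatePopulation(amp, simParams(spectrumFraction = 0.99,
                                             seed = 21, nHomeolog = 0),
                              nMutations = 500L)
  isEms <- emsConsistent(truth$mutations$ref, truth$mutations$alt)
  ci <- qbinom(c(0.005, 0.995), 500L, 0.99)
  expect_gte(sum(isEms), ci[1L])
  expect_lte(sum(isEms), ci[2L])
  # non-EMS draws never produce G>A / C>T
  truth0 <- simulatePopulation(amp, simParams(spectrumFraction = 0, seed = 22,
                                              nHomeolog = 0),
                               nMutations = 200L)
  expect_false(any(emsConsistent(truth0$mutations$ref, truth0$mutations$alt)))
})

test_that("noiseless counts carry signal only in the carrier's pools", {
  amp <- c(amp1 = randomAmplicon(120, 9))
  params <- simParams(depth = 1000L, errorRate = 0, nHomeolog = 0, seed = 13)
  pos <- 50L
  ref <- substr(amp, pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1L]
  mut <- data.frame(line = lineAddress(4, "E", 5), amplicon = "amp1",
                    pos = pos, ref = ref, alt = alt, zygosity = "het",
                    stringsAsFactors = FALSE)
  truth <- handTruth(amp, mut, params)
  design <- buildDesign()
  counts <- simulatePoolCounts(truth, design, params)
  altMat <- SummarizedExperiment::assay(counts, alt)
  carrier <- as.character(poolsForLine(design, 4, "E", 5))
  expect_true(all(altMat[pos, carrier] > 0L))
  # other positions carry alt-base counts only where the reference IS that base
  refs <- SummarizedExperiment::rowData(counts)$ref
  expect_true(all(altMat[-pos, ][refs[-pos] != alt, ] == 0L))
  expect_true(all(altMat[pos, setdiff(colnames(counts), carrier)] == 0L))
  # with no mutations at all, counts are pure reference
  truth0 <- handTruth(amp, mut[0L, ], params)
  counts0 <- simulatePoolCounts(truth0, design, params)
  rd <- SummarizedExperiment::rowData(counts0)
  for (b in c("A", "C", "G", "T")) {
    m <- SummarizedExperiment::assay(counts0, b)
    expect_true(all(m[rd$ref != b, ] == 0L))
    expect_true(all(m[rd$ref == b, ] == params$depth))
  }
})

test_that("mean alt fraction converges to the allele-copy expectation", {
  # one heterozygote in a 96-line pool contributes 1 of 192 alleles (~0.5%);
  # a homozygote contributes 2 of 192 (~1%)
  amp <- c(amp1 = randomAmplicon(60, 15))
  pos <- 30L
  ref <- substr(amp, pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1L]
  design <- buildDesign()
  for (zyg in c("het", "hom")) {
    copies <- if (zyg == "het") 1L else 2L
    totalAlt <- 0L
    nRuns <- 25L
    depth <- 2000L
    for (s in seq_len(nRuns)) {
      params <- simParams(depth = depth, errorRate = 0, nHomeolog = 0,
                          seed = 500 + s)
      mut <- data.frame(line = lineAddress(1, "A", 1), amplicon = "amp1",
                        pos = pos, ref = ref, alt = alt, zygosity = zyg,
                        stringsAsFactors = FALSE)
      counts <- simulatePoolCounts(handTruth(amp, mut, params), design,
                                   params)
      totalAlt <- totalAlt + SummarizedExperiment::assay(counts, alt)[pos, "1"]
    }
    expected <- copies / 192
    ci <- qbinom(c(0.005, 0.995), nRuns * depth, expected)
    expect_gte(totalAlt, ci[1L])
    expect_lte(totalAlt, ci[2L])
  }
})

test_that("homeolog positions sit near their fixed frequency in every pool", {
  sim <- smallSim(len = 200L, depth = 4000L, nMutations = 0L, seed = 31L,
                  nHomeolog = 2L, errorRate = 0)
  h <- sim$truth$homeologs
  depth <- SummarizedExperiment::assay(sim$counts, "depth")
  for (k in seq_len(nrow(h))) {
    f <- SummarizedExperiment::assay(sim$counts, h$alt[k])[h$pos[k], ] /
      depth[h$pos[k], ]
    expect_true(all(abs(f - h$freq[k]) < 0.05))
  }
})

test_that("simulation and fixtures are deterministic under a fixed seed", {
  s1 <- smallSim(seed = 19L)
  s2 <- smallSim(seed = 19L)
  expect_identical(s1$truth$mutations, s2$truth$mutations)
  expect_identical(SummarizedExperiment::assays(s1$counts),
                   SummarizedExperiment::assays(s2$counts))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeFixture(s1$truth, s1$counts, d1, s1$design)
  writeFixture(s2$truth, s2$counts, d2, s2$design)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("an empty truth still writes valid reference-only fixtures", {
  amp <- c(amp1 = randomAmplicon(40, 23))
  params <- simParams(depth = 50L, errorRate = 0, nHomeolog = 0, seed = 23)
  truth <- handTruth(amp, data.frame(line = character(), amplicon = character(),
                                     pos = integer(), ref = character(),
                                     alt = character(), zygosity = character(),
                                     stringsAsFactors = FALSE), params)
  design <- buildDesign()
  counts <- simulatePoolCounts(truth, design, params)
  dir <- withr::local_tempdir()
  writeFixture(truth, counts, dir)
  tab <- readCountsTsv(file.path(dir, "pool1.counts.tsv"))
  expect_equal(tab, poolTable(counts, 1))
  expect_true(all(tab$depth == 50L))
})
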