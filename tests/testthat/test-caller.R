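# Hand-built PoolCounts: `len` positions all with reference base `ref`,
# every pool at `depth`, plus spikes = list(list(pos, alt, count, pools)).
spikeCounts <- function(len, depth, ref = "C", spikes = list(),
                        poolIds = 1:12, design = buildDesign()) {
  bases <- c("A", "C", "G", "T")
  counts <- lapply(bases, function(b)
    matrix(0L, len, length(poolIds),
           dimnames = list(NULL, as.character(poolIds))))
  names(counts) <- bases
  counts[[ref]][] <- as.integer(depth)
  for (s in spikes) {
    for (p in as.character(s$pools)) {
      counts[[s$alt]][s$pos, p] <- as.integer(s$count)
      counts[[ref]][s$pos, p] <- as.integer(depth - s$count)
    }
  }
  poolCounts(counts, data.frame(amplicon = "amp1", pos = seq_len(len),
                                ref = ref, stringsAsFactors = FALSE),
             poolIds = poolIds,
             dimension = unname(design@dimension[as.character(poolIds)]))
}

test_that("background noise model is plain mean/sd over other positions", {
  ft <- data.frame(pool = 1, amplicon = "amp1", pos = 1:4, ref = "C",
                   alt = "T", count = 0, depth = 100,
                   freq = c(0.001, 0.002, 0.003, 0.5), noData = FALSE)
  bg <- fitBackground(ft, pool = 1, ref = "C", alt = "T", excludePos = 4L)
  expect_equal(bg$mean, 0.002)
  expect_equal(bg$sd, 0.001)
  expect_equal(bg$n, 3L)
  # excluding the focal position changes n by exactly one
  bg2 <- fitBackground(ft, 1, "C", "T", excludePos = c(3L, 4L))
  expect_equal(bg2$n, bg$n - 1L)
  expect_error(fitBackground(ft, 1, "C", "T", excludePos = 2:4),
               ">= 2 background positions")
  # an all-zero background has mean 0 and sd 0
  ft0 <- transform(ft, freq = 0)
  bg0 <- fitBackground(ft0, 1, "C", "T")
  expect_equal(c(bg0$mean, bg0$sd), c(0, 0))
})

test_that("the one-sided t-test behaves at and around the background mean", {
  bg <- list(mean = 2e-4, sd = 2e-4, n = 50L)
  expect_equal(testPosition(2e-4, bg), 0.5)
  expect_gt(testPosition(1e-4, bg), 0.5)   # below the mean: never significant
  expect_lt(testPosition(1e-3, bg), 0.05)
})

test_that("the t-test p-value is monotone decreasing in the frequency", {
  bg <- list(mean = 3e-4, sd = 1.5e-4, n = 200L)
  freqs <- seq(0, 0.02, length.out = 60)
  p <- vapply(freqs, testPosition, 0, background = bg, depth = 5000)
  expect_true(all(diff(p) < 0))
})

test_that("the t-test matches an independent tail integration to 1e-10", {
  # reference oracle: numerical integration of the t density
  tailByIntegration <- function(t, df)
    integrate(stats::dt, lower = t, upper = Inf, df = df,
              rel.tol = 1e-13, abs.tol = 0)$value
  cases <- data.frame(freq = c(0.005, 0.001, 0.0008),
                      mean = c(2e-4, 2e-4, 5e-4),
                      sd = c(2e-4, 3e-4, 2e-4),
                      n = c(1000L, 40L, 7L))
  for (i in seq_len(nrow(cases))) {
    bg <- list(mean = cases$mean[i], sd = cases$sd[i], n = cases$n[i])
    t <- (cases$freq[i] - bg$mean) / (bg$sd * sqrt(1 + 1 / bg$n))
    expect_equal(testPosition(cases$freq[i], bg),
                 tailByIntegration(t, bg$n - 1L), tolerance = 1e-10)
  }
})

test_that("the sd floor keeps the statistic finite on all-zero backgrounds", {
  bg <- list(mean = 0, sd = 0, n = 100L)
  p <- testPosition(0.005, bg, depth = 2000)   # floor = 1/(2*2000)
  expect_true(is.finite(p))
  expect_lt(p, 1e-6)
  # without depth the degenerate background falls back to a step decision
  expect_equal(testPosition(0.005, bg), 0)
  expect_equal(testPosition(0, bg), 0.5)
})

test_that("homeolog classification uses both thresholds", {
  expect_true(classifyHomeolog(rep(0.5, 12)))
  expect_false(classifyHomeolog(c(rep(0.005, 3), rep(1e-4, 9))))
  expect_true(classifyHomeolog(c(rep(0.25, 11), 0.01)))   # 11/12 = 0.917
  expect_false(classifyHomeolog(c(rep(0.25, 10), 0.01, 0.01)))  # 10/12
  expect_error(classifyHomeolog(rep(NA_real_, 12)), "no pool has data")
})

test_that("EMS consistency is G>A / C>T on the reference strand", {
  expect_true(emsConsistent("C", "T"))
  expect_true(emsConsistent("G", "A"))
  expect_false(emsConsistent("A", "G"))
  expect_false(emsConsistent("T", "C"))
  expect_error(emsConsistent("C", "C"), "must differ")
})

test_that("candidates require a full pool triple", {
  design <- buildDesign()
  # spike in two pools only (column + row, no plate): not a candidate
  two <- spikeCounts(60, 2000, spikes = list(
    list(pos = 10, alt = "T", count = 20, pools = c(1, 5))))
  expect_equal(nrow(callCandidates(two, design)), 0L)
  # same spike in a full triple: one candidate, decoded to 6 lines
  three <- spikeCounts(60, 2000, spikes = list(
    list(pos = 10, alt = "T", count = 20, pools = c(1, 5, 9))))
  cand <- callCandidates(three, design)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$pools, "1,5,9")
  expect_equal(cand$nLines, 6L)
  expect_setequal(strsplit(cand$lines, ",")[[1]], decodePools(design, c(1, 5, 9)))
  expect_true(cand$emsConsistent)
  expect_false(cand$review)
})

test_that("high-frequency variants present in all pools are homeolog, not candidates", {
  design <- buildDesign()
  hom <- spikeCounts(60, 2000, spikes = list(
    list(pos = 20, alt = "T", count = 1000, pools = 1:12)))
  cand <- callCandidates(hom, design)
  expect_equal(nrow(cand), 0L)
  h <- attr(cand, "homeologs")
  expect_equal(h$pos, 20L)
  expect_equal(h$alt, "T")
})

test_that("extra positive pools are flagged for review, below-depth pools are not tested", {
  design <- buildDesign()
  four <- spikeCounts(60, 2000, spikes = list(
    list(pos = 10, alt = "T", count = 20, pools = c(1, 2, 5, 9))))
  cand <- callCandidates(four, design)
  expect_equal(nrow(cand), 1L)
  expect_true(cand$review)
  # the review line set is still consistent with the evidence
  expect_true(all(strsplit(cand$lines, ",")[[1]] %in%
                    unlist(design@membership[c("1", "2")])))
  shallow <- spikeCounts(60, 50, spikes = list(
    list(pos = 10, alt = "T", count = 5, pools = c(1, 5, 9))))
  expect_equal(nrow(callCandidates(shallow, design, minDepth = 100L)), 0L)
})

test_that("planted mutations are recovered end-to-end with correct pool triples", {
  sim <- smallSim(len = 400L, depth = 5000L, nMutations = 4L, seed = 7L)
  cand <- callCandidates(sim$counts, sim$design)
  truthKeys <- unique(mutationKey(sim$truth$mutations))
  expect_setequal(mutationKey(cand), truthKeys)
  expect_true(all(cand$nLines == 6L))
  for (i in seq_len(nrow(cand))) {
    carriers <- sim$truth$mutations[
      mutationKey(sim$truth$mutations) == mutationKey(cand)[i], "line"]
    decoded <- strsplit(cand$lines[i], ",")[[1]]
    expect_true(all(carriers %in% decoded))
    expect_equal(sort(as.integer(strsplit(cand$pools[i], ",")[[1]])),
                 poolsForLine(sim$design, carriers[1]))
  }
  # emsOnly drops non-EMS candidates
  ems <- callCandidates(sim$counts, sim$design, emsOnly = TRUE)
  expect_true(all(ems$emsConsistent))
})

test_that("calling fails loudly when pools are missing", {
  sim <- smallSim(len = 60L, depth = 200L, nMutations = 1L, seed = 53L)
  expect_error(callCandidates(sim$counts[, 1:11], sim$design),
               "pools missing")
})
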