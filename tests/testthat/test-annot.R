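# single-exon, fully coding model around a given sequence
codingModel <- function(seq, amplicon = "amp1")
  geneModel(amplicon, seq, data.frame(start = 1, end = nchar(seq)),
            cdsStart = 1, cdsEnd = nchar(seq))

test_that("stop gains, amino-acid changes and synonymous changes classify", {
  # TGG (Trp) -> TAG (stop) at codon position 2
  m <- codingModel("ATGTGGGCATAA")
  expect_equal(annotateEffect(m, 5, "G", "A"), "nonsense")
  # GGA (Gly) -> GAA (Glu)
  m2 <- codingModel("ATGGGAGCATAA")
  expect_equal(annotateEffect(m2, 5, "G", "A"), "missense")
  # GCA -> GCG: third-position wobble, synonymous
  expect_equal(annotateEffect(m2, 9, "A", "G"), "silent")
  # vectorised call keeps order
  expect_equal(annotateEffect(m2, c(5, 9), c("G", "A"), c("A", "G")),
               c("missense", "silent"))
})

test_that("synonymy is decided by the genetic code across all codons", {
  # brute force: every codon, every single-base change; compare against the
  # standard code directly
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  codons <- names(code)
  set.seed(5)
  for (codon in sample(codons, 16)) {
    seq <- paste0("ATG", codon, "TAA")   # ATG + codon + stop
    m <- codingModel(seq)
    for (cp in 1:3) {
      ref <- substr(codon, cp, cp)
      for (alt in setdiff(bases, ref)) {
        newCodon <- codon
        substr(newCodon, cp, cp) <- alt
        expected <- if (code[[newCodon]] == "*" && code[[codon]] != "*")
          "nonsense"
        else if (code[[newCodon]] == code[[codon]]) "silent"
        else "missense"
        expect_equal(annotateEffect(m, 3 + cp, ref, alt), expected,
                     label = paste(codon, cp, alt))
      }
    }
  }
})

test_that("splice-window, intron and UTR positions classify by region", {
  # exon1 1-9 | intron 10-17 (GT......AG) | exon2 18-26; CDS 1-9 + 18-26
  seq <- paste0("ATGGCAGCA", "GTAAAAAG", "GCAGCATAA")
  m <- geneModel("amp1", seq, data.frame(start = c(1, 18), end = c(9, 26)),
                 cdsStart = 1, cdsEnd = 26)
  expect_equal(annotateEffect(m, 10, "G", "A"), "splice")  # donor G of GT
  expect_equal(annotateEffect(m, 11, "T", "A"), "splice")
  expect_equal(annotateEffect(m, 16, "A", "T"), "splice")  # acceptor A of AG
  expect_equal(annotateEffect(m, 17, "G", "A"), "splice")
  expect_equal(annotateEffect(m, 13, "A", "G"), "noncoding")  # intron interior
  # coding frame spans the junction: position 18 is codon 4 base 1
  expect_equal(annotateEffect(m, 18, "G", "A"), "missense")   # GCA -> ACA
  # UTR beyond the CDS
  m2 <- geneModel("amp1", seq, data.frame(start = c(1, 18), end = c(9, 26)),
                  cdsStart = 4, cdsEnd = 26)
  expect_equal(annotateEffect(m2, 2, "T", "C"), "noncoding")
})

test_that("reverse-strand models translate the complementary frame", {
  # coding strand is the reverse complement: amplicon TTATGCCCCAT encodes
  # ATG GGG CAT AA... reading right-to-left; build: revcomp(ATGGGGCATTAA)
  cds <- "ATGGGGCATTAA"
  amp <- paste(rev(strsplit(chartr("ACGT", "TGCA", cds), "")[[1]]),
               collapse = "")
  m <- geneModel("amp1", amp, data.frame(start = 1, end = nchar(amp)),
                 cdsStart = 1, cdsEnd = nchar(amp), strand = "-")
  # amplicon C>T at the position pairing codon 2's G (GGG -> AGG, missense)
  pos <- nchar(amp) - 3L   # coding position 4
  expect_equal(annotateEffect(m, pos, substr(amp, pos, pos), "T"), "missense")
  # wobble of codon 2 (coding pos 6) is synonymous: GGG -> GGA means
  # amplicon C>T at pairing position
  pos2 <- nchar(amp) - 5L
  expect_equal(annotateEffect(m, pos2, substr(amp, pos2, pos2), "T"),
               "silent")
})

test_that("annotation is invariant under a constant coordinate shift", {
  seq <- paste0("ATGGCAGCA", "GTAAAAAG", "GCAGCATAA")
  exons <- data.frame(start = c(1, 18), end = c(9, 26))
  m <- geneModel("amp1", seq, exons, 1, 26)
  shift <- 120L
  padded <- paste0(randomAmplicon(shift, 61), seq)
  mShift <- geneModel("amp1", padded, exons + shift, 1 + shift, 26 + shift)
  for (pos in c(2, 5, 10, 13, 16, 19, 25)) {
    ref <- substr(seq, pos, pos)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    expect_equal(annotateEffect(mShift, pos + shift, ref, alt),
                 annotateEffect(m, pos, ref, alt), label = pos)
  }
})

test_that("reference mismatches signal coordinate errors", {
  m <- codingModel("ATGGGAGCATAA")
  expect_error(annotateEffect(m, 5, "C", "T"), "mismatch")
  expect_error(annotateEffect(m, 99, "G", "A"), "outside")
})

test_that("effect groups and percentages reproduce the reporting convention", {
  s <- summarizeEffects(counts = c(nonsense = 18, missense = 181,
                                   silent = 233))
  expect_equal(s$percent, c(4.2, 41.9, 53.9))
  expect_equal(sum(s$count), 432L)
  expect_lt(abs(sum(s$percent) - 100), 0.1)
  # class-to-group mapping: splice counts as nonsense, noncoding as silent
  s2 <- summarizeEffects(c("splice", "nonsense", "noncoding", "silent",
                           "missense"))
  expect_equal(s2$count, c(2L, 1L, 2L))
  # degenerate cases
  expect_equal(summarizeEffects("silent")$percent, c(0, 0, 100))
  expect_error(summarizeEffects(character()), "no annotated records")
  expect_error(summarizeEffects("frameshift"), "unknown effect class")
})

test_that("gene models load from the feature TSV dialect", {
  seq <- paste0("ATGGCAGCA", "GTAAAAAG", "GCAGCATAA")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("amplicon\tfeature\tstart\tend\tstrand",
               "amp1\texon\t1\t9\t+",
               "amp1\texon\t18\t26\t+",
               "amp1\tCDS\t1\t9\t+",
               "amp1\tCDS\t18\t26\t+"), tsv)
  m <- readGeneModelTsv(tsv, "amp1", seq)
  expect_equal(m@cdsStart, 1L)
  expect_equal(m@cdsEnd, 26L)
  expect_equal(annotateEffect(m, 10, "G", "A"), "splice")
  expect_error(readGeneModelTsv(tsv, "amp9", seq), "no features")
})
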