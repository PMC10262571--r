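test_that("the Haldane map function matches its closed form", {
  expect_equal(recombFraction(0), 0)
  expect_equal(recombFraction(10), 0.5, tolerance = 1e-8)
  expect_equal(recombFraction(0.1), 0.0906346, tolerance = 1e-6)
  cgrid <- seq(0, 5, by = 0.01)
  expect_true(all(diff(recombFraction(cgrid)) > 0))  # monotone in c
  expect_true(all(recombFraction(cgrid) < 0.5))
  expect_error(recombFraction(-0.1), "non-negative")
})

test_that("recombination models map cM gaps to fractions per locus", {
  map <- uniformMap(11, nChr = 2, lengthCM = 100)
  mod <- recombinationModel(map)
  expect_equal(sum(mod@chrFirst), 2)
  gap <- diff(map@pos[map@chr == 1])[1] / 100
  expect_equal(mod@r[2], recombFraction(gap))
})

test_that("gametes from homozygous parents equal the parental haplotype", {
  map <- uniformMap(50)
  mod <- recombinationModel(map)
  h <- rep(c(0L, 1L), 25)
  set.seed(1)
  for (i in 1:5) expect_identical(sampleGamete(h, h, mod), h)
})

test_that("complete linkage copies one whole parental chromosome", {
  map <- uniformMap(30, nChr = 2, lengthCM = 100)
  L <- nLoci(map)
  mod <- new("RecombinationModel", r = rep(0, L),
             chrFirst = c(TRUE, map@chr[-1] != map@chr[-L]))
  h1 <- rep(0L, L); h2 <- rep(1L, L)
  set.seed(2)
  for (i in 1:10) {
    g <- sampleGamete(h1, h2, mod)
    for (c in 1:2) {
      seg <- g[map@chr == c]
      expect_true(all(seg == seg[1]))  # no within-chromosome switch
    }
  }
})

test_that("observed switch frequency matches the recombination fraction", {
  # two loci 5 cM apart; fully informative parent
  map <- new("GenomeMap", chr = c(1L, 1L), pos = c(10, 15),
             role = c("marker", "marker"), nChr = 1L, lengthCM = 100)
  mod <- recombinationModel(map)
  r <- recombFraction(0.05)
  set.seed(3)
  n <- 10000
  g <- vapply(seq_len(n), function(i)
    sampleGamete(c(0L, 0L), c(1L, 1L), mod), integer(2))
  sw <- mean(g[1, ] != g[2, ])
  se <- sqrt(r * (1 - r) / n)
  expect_lt(abs(sw - r), 3 * se)
})

test_that("expected crossovers on a 1-Morgan chromosome are about one", {
  map <- uniformMap(101, lengthCM = 100)
  mod <- recombinationModel(map)
  set.seed(4)
  n <- 3000
  h1 <- rep(0L, 101); h2 <- rep(1L, 101)
  switches <- vapply(seq_len(n), function(i) {
    g <- sampleGamete(h1, h2, mod)
    sum(diff(g) != 0)
  }, numeric(1))
  expected <- sum(mod@r[-1])  # sum of adjacent fractions, ~1 for 1 Morgan
  se <- sd(switches) / sqrt(n)
  expect_lt(abs(mean(switches) - expected), 3 * se)
  expect_equal(expected, 1, tolerance = 0.05)
})

test_that("offspring satisfy Mendelian structure and parental origin", {
  fx <- tinyFounderSet()
  f <- fx$founders
  set.seed(5)
  sire <- f@id[f@sex == "M"][1]; dam <- f@id[f@sex == "F"][1]
  off <- makeOffspring(f, sire, dam, 10, fx$model)
  expect_equal(nInd(off), 10)
  expect_equal(sum(off@sex == "M"), 5)
  expect_true(all(off@sire == sire) && all(off@dam == dam))
  d <- dosage(off)
  expect_true(all(d %in% 0:2))
  # dosage bounded by what the parents can transmit
  ds <- dosage(f)[match(sire, f@id), ]; dd <- dosage(f)[match(dam, f@id), ]
  lo <- (ds == 2) + (dd == 2); hi <- 2 - ((ds == 0) + (dd == 0))
  expect_true(all(t(d) >= lo & t(d) <= hi))
  # forced heterozygote at loci where sire is 0/0 and dam is 1/1
  j <- which(ds == 0 & dd == 2)
  if (length(j)) expect_true(all(d[, j] == 1))
  # paternal strand comes from the sire's alleles
  sH <- f@hap1[match(sire, f@id), ] + f@hap2[match(sire, f@id), ]
  j0 <- which(sH == 0)
  expect_true(all(off@hap1[, j0] == 0))
})

test_that("offspring cohort allele frequency matches the parental mean", {
  fx <- tinyFounderSet()
  f <- fx$founders
  set.seed(6)
  sire <- f@id[f@sex == "M"][2]; dam <- f@id[f@sex == "F"][2]
  off <- makeOffspring(f, sire, dam, 2000, fx$model)
  pPar <- (dosage(f)[match(sire, f@id), ] + dosage(f)[match(dam, f@id), ]) / 4
  pOff <- colMeans(dosage(off)) / 2
  # pooled z-statistic over loci stays within Monte-Carlo bounds
  keep <- pPar > 0 & pPar < 1
  se <- sqrt(pPar[keep] * (1 - pPar[keep]) / (2 * 2000))
  z <- (pOff[keep] - pPar[keep]) / se
  expect_lt(abs(mean(z)), 3 / sqrt(sum(keep)) * 3)
  expect_lt(max(abs(z)), 6)
})

test_that("odd litters alternate the extra-animal sex", {
  fx <- tinyFounderSet()
  f <- fx$founders
  sires <- f@id[f@sex == "M"][1:2]; dams <- f@id[f@sex == "F"][1:2]
  plan <- new("MatingPlan", sire = sires, dam = dams,
              nOffspring = c(3L, 3L), capacity = 1L)
  set.seed(7)
  off <- gmatesim:::offspringFromPlan(f, plan, fx$model)
  bySire <- split(off@sex, off@sire)
  counts <- vapply(bySire, function(s) sum(s == "M"), integer(1))
  expect_setequal(counts, c(2L, 1L))
})
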