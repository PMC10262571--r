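test_that("VanRaden GRM: clone identity, HWE diagonal, relabeling invariance", {
  set.seed(30)
  p <- runif(500, 0.1, 0.9)
  M <- vapply(p, function(q) rbinom(1000, 2, q), numeric(1000))
  G <- relMatrix(grmVanRaden(M))
  # average diagonal of a Hardy-Weinberg cohort is about 1
  se <- sd(diag(G)) / sqrt(nrow(M))
  expect_lt(abs(mean(diag(G)) - 1), 3 * se + 0.02)
  # symmetric by construction
  expect_lt(max(abs(G - t(G))), 1e-12)
  # clone rows: off-diagonal equals the clone diagonal
  M2 <- rbind(M[1, ], M[1, ], M[2:50, ])
  G2 <- relMatrix(grmVanRaden(M2))
  expect_equal(G2[1, 2], G2[1, 1])
  # allele relabeling x -> 2 - x leaves G unchanged
  G3 <- relMatrix(grmVanRaden(2 - M[1:50, ]))
  G4 <- relMatrix(grmVanRaden(M[1:50, ]))
  expect_equal(G3, G4, tolerance = 1e-12)
  expect_error(grmVanRaden(matrix(2, 5, 4)), "monomorphic")
})

test_that("segment kinship: autozygosity, disjoint haplotypes, sib ordering", {
  map <- uniformMap(100, nChr = 2, lengthCM = 100)
  L <- nLoci(map)
  set.seed(31)
  h <- matrix(as.integer(runif(3 * L) < 0.5), 3, L)
  # ind1 fully autozygous; ind2 disjoint from ind3 everywhere
  hap1 <- rbind(h[1, ], h[2, ], 1L - h[2, ])
  hap2 <- rbind(h[1, ], h[2, ], 1L - h[2, ])
  pop <- manualPopulation(hap1, hap2, map)
  G <- relMatrix(segmentKinship(pop, minLengthCM = 1, minMarkers = 5))
  expect_equal(G[1, 1], 2)
  expect_equal(G[2, 3], 0)
  expect_equal(G[2, 2], 2)  # identical own strands
  expect_true(all(G >= 0 & G <= 2))
  # thresholds can only remove shared length
  Gloose <- relMatrix(segmentKinship(pop, minLengthCM = 0, minMarkers = 1))
  Gstrict <- relMatrix(segmentKinship(pop, minLengthCM = 20, minMarkers = 40))
  expect_true(all(Gloose - Gstrict >= -1e-12))
})

test_that("full sibs share more segment kinship than unrelated founders", {
  fx <- tinyFounderSet()
  f <- fx$founders
  set.seed(32)
  off <- makeOffspring(f, f@id[f@sex == "M"][1], f@id[f@sex == "F"][1],
                       10, fx$model)
  both <- gmatesim:::subsetPopulation(f, 1:20)
  Gf <- relMatrix(segmentKinship(both, 1, 10))
  Gs <- relMatrix(segmentKinship(off, 1, 10))
  offdiag <- function(G) mean(G[upper.tri(G)])
  expect_gt(offdiag(Gs), offdiag(Gf))
})

test_that("pedigree inbreeding matches classical closed forms", {
  # offspring of full sibs (unrelated grandparents): F = 0.25
  ped <- data.frame(id = 1:5,
                    sire = c(NA, NA, 1, 1, 3),
                    dam = c(NA, NA, 2, 2, 4))
  F <- fPed(ped)
  expect_equal(unname(F["5"]), 0.25)
  expect_equal(unname(F["1"]), 0)
  # offspring of half sibs: F = 0.125
  ped2 <- data.frame(id = 1:6,
                     sire = c(NA, NA, NA, 1, 1, 4),
                     dam = c(NA, NA, NA, 2, 3, 5))
  expect_equal(unname(fPed(ped2)["6"]), 0.125)
  # any individual with an unknown parent is a founder with F = 0
  ped3 <- data.frame(id = 1:2, sire = c(NA, 1), dam = c(NA, NA))
  expect_equal(unname(fPed(ped3)["2"]), 0)
  # order independence: shuffled rows give the same answer
  F2 <- fPed(ped[c(3, 5, 1, 4, 2), ])
  expect_equal(F2[names(F)], F)
  # cycles are rejected
  pedC <- data.frame(id = 1:2, sire = c(2, 1), dam = c(NA, NA))
  expect_error(fPed(pedC), "cycle")
})

test_that("pedigree inbreeding equals Wright path counting on random pedigrees", {
  set.seed(33)
  for (rep in 1:5) {
    n <- 15
    ped <- data.frame(id = 1:n, sire = NA_integer_, dam = NA_integer_)
    for (i in 5:n) {
      ped$sire[i] <- sample(1:(i - 1), 1)
      repeat {
        d <- sample(1:(i - 1), 1)
        if (d != ped$sire[i]) break
      }
      ped$dam[i] <- d
    }
    expect_equal(fPed(ped), pathCountingF(ped), tolerance = 1e-12)
  }
})

test_that("marker inbreeding estimators behave and agree with the GRM diagonal", {
  # fully homozygous individuals at p = 1/2 loci have F = 1
  M <- rbind(rep(c(0, 2), 10), rep(c(2, 0), 10))
  expect_equal(unname(fGrm(M)), c(1, 1))
  # HWE cohort mean is about 0
  set.seed(34)
  p <- runif(400, 0.2, 0.8)
  Mh <- vapply(p, function(q) rbinom(800, 2, q), numeric(800))
  f <- fGrm(Mh)
  expect_lt(abs(mean(f)), 3 * sd(f) / sqrt(800))
  # allele relabeling invariance
  expect_equal(fGrm(2 - Mh), fGrm(Mh), tolerance = 1e-12)
  # pooled-denominator estimator is exactly the VanRaden diagonal minus one
  G <- relMatrix(grmVanRaden(Mh))
  expect_equal(unname(fGrmVanRaden(Mh)), unname(diag(G) - 1),
               tolerance = 1e-12)
})

test_that("cohort mean pedigree inbreeding never decreases across generations", {
  fx <- tinyFounderSet()
  f <- fx$founders
  set.seed(35)
  ped <- pedigree(f)[, c("id", "sire", "dam")]
  pop <- f
  means <- c()
  for (gen in 1:3) {
    sires <- pop@id[pop@sex == "M"][1:5]
    dams <- pop@id[pop@sex == "F"][1:20]
    plan <- randomMating(sires, dams, 4, 4)
    pop <- gmatesim:::offspringFromPlan(pop, plan, fx$model,
                                        idStart = max(ped$id) + 1L)
    ped <- rbind(ped, pedigree(pop)[, c("id", "sire", "dam")])
    F <- fPed(ped)
    means <- c(means, mean(F[as.character(pop@id)]))
  }
  expect_true(all(diff(means) >= 0))
})
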