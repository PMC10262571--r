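test_that("random mating deals balanced blocks and is uniform over sires", {
  set.seed(40)
  plan <- randomMating(1:30, 101:1000, capacity = 30)
  expect_equal(as.integer(table(plan@sire)), rep(30L, 30))
  expect_equal(sort(plan@dam), 101:1000)
  # one sire takes everything
  p1 <- randomMating(7L, 101:110, capacity = 10)
  expect_true(all(p1@sire == 7L))
  # each (sire, dam) pair appears with frequency 1/nSires
  counts <- matrix(0, 3, 9)
  for (s in 1:2000) {
    pl <- randomMating(1:3, 11:19, capacity = 3)
    counts[cbind(pl@sire, pl@dam - 10)] <- counts[cbind(pl@sire, pl@dam - 10)] + 1
  }
  freq <- counts / 2000
  se <- sqrt((1 / 3) * (2 / 3) / 2000)
  expect_true(all(abs(freq - 1 / 3) < 3.5 * se))
  expect_error(randomMating(1:2, 1:10, capacity = 3), "infeasible")
})

test_that("positive assortative mating pairs like ranks blockwise", {
  gv <- setNames(c(30:21, 120:81), c(1:10, 101:140))
  plan <- positiveAssortative(1:10, 101:140, gv, capacity = 4)
  tab <- planTable(plan)
  # best sire (id 1) gets the four best dams (101:104)
  expect_setequal(tab$dam[tab$sire == 1], 101:104)
  # worst sire gets the four worst dams
  expect_setequal(tab$dam[tab$sire == 10], 137:140)
  # ties are resolved by id: equal-GEBV sires keep ascending order
  gvT <- setNames(c(rep(5, 10), 120:81), c(1:10, 101:140))
  planT <- positiveAssortative(1:10, 101:140, gvT, capacity = 4)
  expect_setequal(planTable(planT)$dam[planT@sire == 1], 101:104)
})

test_that("negative assortative mating inverts the sire ranking", {
  gv <- setNames(c(30:21, 120:81), c(1:10, 101:140))
  plan <- negativeAssortative(1:10, 101:140, gv, capacity = 4)
  tab <- planTable(plan)
  # best sire (highest GEBV, id 1) gets the four worst dams
  expect_setequal(tab$dam[tab$sire == 10], 101:104)
  expect_setequal(tab$dam[tab$sire == 1], 137:140)
  # with flat GEBVs the two assortative schemes coincide (tie rule)
  gvT <- setNames(rep(1, 50), c(1:10, 101:140))
  pP <- positiveAssortative(1:10, 101:140, gvT, capacity = 4)
  pN <- negativeAssortative(1:10, 101:140, gvT, capacity = 4)
  expect_equal(planTable(pP), planTable(pN))
  # pairing permutes, never selects: midparent mean is pairing-invariant
  mid <- function(pl) mean((gv[as.character(pl@sire)] +
                            gv[as.character(pl@dam)]) / 2)
  pP2 <- positiveAssortative(1:10, 101:140, gv, capacity = 4)
  expect_equal(mid(plan), mid(pP2))
})

test_that("assortative pairing shrinks within-pair GEBV distance vs random", {
  set.seed(41)
  gv <- setNames(c(rnorm(5, 0, 10), rnorm(20, 0, 10)), c(1:5, 101:120))
  dist <- function(pl) mean(abs(gv[as.character(pl@sire)] -
                                gv[as.character(pl@dam)]))
  dP <- dist(positiveAssortative(1:5, 101:120, gv, capacity = 4))
  dR <- mean(vapply(1:100, function(i)
    dist(randomMating(1:5, 101:120, capacity = 4)), numeric(1)))
  expect_lt(dP, dR)
})

test_that("incidence matrices have half-entries and unit row sums", {
  plan <- randomMating(1:2, 11:14, capacity = 2)
  P <- incidenceMatrix(plan, c(1:2, 11:14))
  expect_equal(rowSums(P), rep(1, 4))
  expect_true(all(P %in% c(0, 0.5)))
  expect_equal(colSums(P)[as.character(11:14)], rep(0.5, 4),
               ignore_attr = TRUE)
})

test_that("Mendelian dispersion counts heterozygous effect variance", {
  map <- uniformMap(10)
  hap1 <- rbind(rep(0L, 10), rep(0L, 10))
  hap2 <- rbind(rep(0L, 10), rep(0L, 10))
  hap2[2, 4] <- 1L  # dam heterozygous at marker 4 only
  pop <- manualPopulation(hap1, hap2, map, sex = c("M", "F"))
  eff <- new("MarkerEffects", a = c(rep(0, 3), 2, rep(0, 6)),
             inclusionProb = rep(1, 10), intercept = 0, hyper = list())
  plan <- new("MatingPlan", sire = 1L, dam = 2L, nOffspring = 1L,
              capacity = 1L)
  D <- mendelianDispersion(plan, pop, eff)
  expect_equal(unname(D), 2^2 / 4)  # single het marker with effect 2
  # both parents homozygous everywhere: zero dispersion
  eff0 <- new("MarkerEffects", a = rep(1, 10), inclusionProb = rep(1, 10),
              intercept = 0, hyper = list())
  popHom <- manualPopulation(hap1, hap1, map, sex = c("M", "F"))
  expect_equal(unname(mendelianDispersion(plan, popHom, eff0)), 0)
  # direction-symmetric in the pair
  load <- gmatesim:::heterozygosityLoad(pop, eff)
  expect_equal(unname((load["1"] + load["2"]) / 4),
               unname((load["2"] + load["1"]) / 4))
})

test_that("plan objectives reduce to midparent sums under an identity GRM", {
  ids <- c(1, 2, 11, 12)
  G <- diag(4); dimnames(G) <- list(ids, ids)
  merit <- setNames(c(4, 2, 3, 1), ids)
  plan <- new("MatingPlan", sire = c(1L, 2L), dam = c(11L, 12L),
              nOffspring = c(1L, 1L), capacity = 1L)
  o <- evaluatePlan(plan, G, merit)
  expect_equal(o$gain, (4 + 3) / 2 + (2 + 1) / 2)
  expect_equal(o$inbreeding, 2 / 2)  # Nc / 2 for distinct non-inbred parents
  # duplicating every mating doubles both objectives (via offspring rows)
  plan2 <- new("MatingPlan", sire = c(1L, 2L, 1L, 2L),
               dam = c(11L, 12L, 13L, 14L),
               nOffspring = rep(1L, 4), capacity = 2L)
  G6 <- diag(6); dimnames(G6) <- list(c(ids, 13, 14), c(ids, 13, 14))
  merit6 <- setNames(c(4, 2, 3, 1, 3, 1), c(ids, 13, 14))
  o2 <- evaluatePlan(plan2, G6, merit6)
  expect_equal(o2$gain, 2 * o$gain)
  # a clone mating raises group coancestry
  G3 <- matrix(c(1, 0, 1, 0, 1, 0, 1, 0, 1), 3)
  dimnames(G3) <- list(1:3, 1:3)  # parent 3 is a clone of parent 1
  mer <- setNames(rep(1, 3), 1:3)
  pUnrel <- new("MatingPlan", sire = 1L, dam = 2L, nOffspring = 1L,
                capacity = 1L)
  pClone <- new("MatingPlan", sire = 1L, dam = 3L, nOffspring = 1L,
                capacity = 1L)
  expect_gt(evaluatePlan(pClone, G3, mer)$inbreeding,
            evaluatePlan(pUnrel, G3, mer)$inbreeding)
})

test_that("optimizer plans are feasible and the frontier is nondominated", {
  set.seed(42)
  nS <- 4; nD <- 12
  ids <- c(1:nS, 100 + 1:nD)
  G <- randomGLike(nS + nD, ids)
  merit <- setNames(rnorm(nS + nD), ids)
  fr <- optimizeMating(1:nS, 100 + 1:nD, G, merit, capacity = 5,
                       gaPopSize = 20, nIter = 60)
  for (pl in fr@plans) {
    expect_true(validObject(pl))
    expect_setequal(pl@dam, 100 + 1:nD)
    expect_lte(max(table(pl@sire)), 5)
  }
  # pairwise nondomination scan
  k <- length(fr@gain)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    dominates <- fr@gain[j] >= fr@gain[i] + 1e-12 &&
      fr@inbreeding[j] <= fr@inbreeding[i] - 1e-12
    expect_false(dominates)
  }
  expect_equal(fr@gain[fr@maxGain], max(fr@gain))
  expect_equal(fr@inbreeding[fr@minInbreeding], min(fr@inbreeding))
})

test_that("optimizer endpoints match exhaustive enumeration on toy instances", {
  set.seed(43)
  for (k in 1:5) {
    nS <- sample(2:3, 1); nD <- sample(4:5, 1)
    cap <- sample(2:3, 1)
    while (nD > nS * cap) cap <- cap + 1
    ids <- c(seq_len(nS), 100 + seq_len(nD))
    G <- randomGLike(nS + nD, ids)
    merit <- setNames(rnorm(nS + nD), ids)
    bf <- enumeratePlans(seq_len(nS), 100 + seq_len(nD), G, merit, cap)
    fr <- optimizeMating(seq_len(nS), 100 + seq_len(nD), G, merit,
                         capacity = cap, gaPopSize = 30, nIter = 80)
    expect_equal(fr@gain[fr@maxGain], bf$maxGain, tolerance = 1e-9)
    expect_equal(fr@inbreeding[fr@minInbreeding], bf$minInbreeding,
                 tolerance = 1e-9)
  }
})

test_that("a flat objective collapses the frontier's gain dimension", {
  ids <- c(1:2, 11:14)
  G <- diag(6); dimnames(G) <- list(ids, ids)
  merit <- setNames(rep(1, 6), ids)
  set.seed(44)
  fr <- optimizeMating(1:2, 11:14, G, merit, capacity = 3,
                       gaPopSize = 10, nIter = 30)
  expect_lt(diff(range(fr@gain)), 1e-9)
})
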