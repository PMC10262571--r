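#' Rate of genetic gain
#'
#' Mean generation-to-generation change of the per-generation cohort means,
#' which telescopes to \code{(last - first) / (n - 1)}.
#'
#' @param means numeric vector of per-generation cohort means (length >= 2).
#' @return scalar rate of gain.
#' @export
deltaG <- function(means) {
  if (length(means) < 2) stop("need at least two generations")
  mean(diff(means))
}

#' Rate of inbreeding
#'
#' \eqn{\Delta F = 1 - e^\beta} with \eqn{\beta} the ordinary least-squares
#' slope of \eqn{\ln(1 - F_u)} on the generation number \eqn{u}.
#'
#' @param F numeric vector of per-generation mean inbreeding coefficients,
#'   all < 1, indexed by consecutive generations starting at the first
#'   element.
#' @return scalar rate of inbreeding.
#' @export
deltaF <- function(F) {
  if (length(F) < 2) stop("need at least two generations")
  if (any(F >= 1)) stop("inbreeding coefficients must be < 1")
  u <- seq_along(F) - 1
  beta <- coef(lm(log(1 - F) ~ u))[["u"]]
  1 - exp(beta)
}

#' Desk-scale experiment preset
#'
#' A reduced configuration sized for interactive use and continuous
#' testing: 2 chromosomes x 50 cM with 200 markers + 10 QTL each, a
#' 200 -> 120 historical population run 200 + 200 generations, 5 sires and
#' 50 dams selected per generation, litter size 4, 3 scheme generations, a
#' 4000/500/10 BayesB chain and a 50 x 200 genetic algorithm.
#'
#' @return a nested configuration list (see \code{\link{runExperiment}}).
#' @export
deskPreset <- function() {
  list(
    genome = list(nChr = 2L, lengthCM = 50, markersPerChr = 200L,
                  qtlPerChr = 10L),
    historical = list(nPhase1 = 200L, gensPhase1 = 200L, nPhase2 = 120L,
                      gensPhase2 = 200L, mutationRate = 2.5e-5),
    founders = list(nMales = 5L, nFemales = 50L),
    selection = list(nSires = 5L, nDams = 50L),
    litterSize = 4L,
    nGenerations = 3L,
    trait = list(sigmaP2 = 1000, shape = 0.4, mu = 0),
    tbvMode = "recursive",
    bayesb = list(nIter = 4000L, burnIn = 500L, thin = 10L, piZero = 0.95),
    ga = list(popSize = 50L, nIter = 200L),
    roh = list(minLengthCM = 1, minMarkers = 20L),
    gmCapacityFactor = 2
  )
}

#' Full-scale experiment preset
#'
#' The full study conditions: 18 chromosomes x 100 cM with 1700 markers +
#' 17 QTL each, a 2000 -> 400 historical population run 1000 + 1000
#' generations at mutation rate 2.5e-5, 30 sires and 900 dams, litter size
#' 10, five scheme generations, a 20000/1000/20 BayesB chain and a
#' 200 x 800 genetic algorithm. Intended for cluster runs.
#'
#' @return a nested configuration list (see \code{\link{runExperiment}}).
#' @export
fullScalePreset <- function() {
  list(
    genome = list(nChr = 18L, lengthCM = 100, markersPerChr = 1700L,
                  qtlPerChr = 17L),
    historical = list(nPhase1 = 2000L, gensPhase1 = 1000L, nPhase2 = 400L,
                      gensPhase2 = 1000L, mutationRate = 2.5e-5),
    founders = list(nMales = 30L, nFemales = 900L),
    selection = list(nSires = 30L, nDams = 900L),
    litterSize = 10L,
    nGenerations = 5L,
    trait = list(sigmaP2 = 1000, shape = 0.4, mu = 0),
    tbvMode = "recursive",
    bayesb = list(nIter = 20000L, burnIn = 1000L, thin = 20L, piZero = 0.95),
    ga = list(popSize = 200L, nIter = 800L),
    roh = list(minLengthCM = 1, minMarkers = 20L),
    gmCapacityFactor = 2
  )
}

#' Read an experiment configuration from YAML
#'
#' Keys follow the preset structure (\code{genome.n_chr} style flat keys are
#' also accepted and mapped onto it). Unspecified keys fall back to the
#' desk preset.
#'
#' @param path YAML file path.
#' @return a configuration list.
#' @export
readConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- deskPreset()
  alias <- list(n_chr = "nChr", length_cM = "lengthCM",
                markers_per_chr = "markersPerChr", qtl_per_chr = "qtlPerChr",
                n_phase1 = "nPhase1", gens_phase1 = "gensPhase1",
                n_phase2 = "nPhase2", gens_phase2 = "gensPhase2",
                mutation_rate = "mutationRate")
  fix <- function(x) {
    if (!is.list(x)) return(x)
    names(x) <- vapply(names(x), function(nm)
      if (nm %in% names(alias)) alias[[nm]] else nm, character(1))
    lapply(x, fix)
  }
  raw <- fix(raw)
  modifyList(cfg, raw)
}

# internal: valid scheme identifiers
schemeIds <- function() c("rand", "p_assort", "n_assort",
                          "gm_snp_gain", "gm_snp_inb",
                          "gm_roh_gain", "gm_roh_inb")

# internal: per-cohort metric row
cohortMetrics <- function(pop, gebvs, ped, u) {
  Fp <- fPed(ped)
  Fg <- fGrm(dosage(pop)[, markerIndex(pop@map), drop = FALSE])
  data.frame(generation = u,
             meanGEBV = mean(gebvs),
             meanTBV = mean(pop@traits$g),
             meanFPED = mean(Fp[as.character(pop@id)]),
             meanFGRM = mean(Fg))
}

# internal: traits for a new cohort given its parents' state
assignCohortTraits <- function(off, parentPop, arch, ped, mode) {
  if (mode == "genomic") {
    g <- trueBVGenomic(off, arch)
    w <- rep(NA_real_, length(g))
  } else {
    Fp <- fPed(ped)
    gPar <- setNames(parentPop@traits$g, as.character(parentPop@id))
    res <- trueBVRecursive(gPar[as.character(off@sire)],
                           gPar[as.character(off@dam)],
                           Fp[as.character(off@sire)],
                           Fp[as.character(off@dam)], arch@sigmaA2)
    g <- res$g; w <- res$w
  }
  y <- phenotype(g, arch)$y
  attachTraits(off, g, w, y)
}

#' Initialize an experiment replicate up to scheme divergence
#'
#' Builds the genome, runs the historical simulation, samples the modern
#' founders, draws the trait architecture, runs the burn-in foundation
#' generations (founders -> cohort 1 -> cohort 2, random mating with random
#' within-cohort parent choice), fits BayesB on the two-generation
#' reference, assigns GEBVs to the generation-0 candidate cohort and
#' selects its top parents. Every mating scheme of the replicate continues
#' from the state returned here, so generation-0 metrics are identical
#' across schemes by construction.
#'
#' @param config configuration list (see \code{\link{deskPreset}}).
#' @param h2 heritability of the simulated trait.
#' @param seed integer seed for the replicate.
#' @return a state list consumed by \code{\link{runGeneration}}.
#' @export
initExperimentState <- function(config, h2, seed) {
  cfg <- config
  map <- buildGenomeMap(cfg$genome$nChr, cfg$genome$lengthCM,
                        cfg$genome$markersPerChr, cfg$genome$qtlPerChr,
                        seed = seed)
  hist <- do.call(simulateHistorical,
                  c(list(map = map), cfg$historical, list(seed = seed + 1L)))
  founders <- sampleModernFounders(hist, cfg$founders$nMales,
                                   cfg$founders$nFemales, seed = seed + 2L)
  set.seed(seed + 3L)
  arch <- sampleQtlEffects(map, founders, h2, cfg$trait$sigmaP2,
                           cfg$trait$shape, cfg$trait$mu)
  g0 <- trueBVGenomic(founders, arch)
  founders <- attachTraits(founders, g0, rep(0, length(g0)),
                           phenotype(g0, arch)$y)
  model <- recombinationModel(map)
  capacity <- as.integer(ceiling(cfg$selection$nDams / cfg$selection$nSires))
  ped <- pedigree(founders)[, c("id", "sire", "dam")]

  # burn-in generation 1: founders random-mate
  sires <- founders@id[founders@sex == "M"]
  dams <- founders@id[founders@sex == "F"]
  plan <- randomMating(sires, dams, capacity, cfg$litterSize)
  cohortA <- offspringFromPlan(founders, plan, model)
  ped <- rbind(ped, pedigree(cohortA)[, c("id", "sire", "dam")])
  cohortA <- assignCohortTraits(cohortA, founders, arch, ped, cfg$tbvMode)

  # burn-in generation 2: random parents from cohort 1 (no GEBV exists yet)
  aM <- cohortA@id[cohortA@sex == "M"]; aF <- cohortA@id[cohortA@sex == "F"]
  sires <- sample(aM, cfg$selection$nSires)
  dams <- sample(aF, cfg$selection$nDams)
  plan <- randomMating(sires, dams, capacity, cfg$litterSize)
  cohortB <- offspringFromPlan(cohortA, plan, model,
                               idStart = max(cohortA@id) + 1L)
  ped <- rbind(ped, pedigree(cohortB)[, c("id", "sire", "dam")])
  cohortB <- assignCohortTraits(cohortB, cohortA, arch, ped, cfg$tbvMode)

  # first BayesB fit on the two-generation reference; generation-0 metrics
  mi <- markerIndex(map)
  refM <- rbind(dosage(cohortA)[, mi, drop = FALSE],
                dosage(cohortB)[, mi, drop = FALSE])
  refY <- c(cohortA@traits$y, cohortB@traits$y)
  fit <- do.call(fitBayesB, c(list(M = refM, y = refY), cfg$bayesb))
  gebv0 <- gebv(dosage(cohortB)[, mi, drop = FALSE], fit)
  sel <- selectParents(cohortB@id, cohortB@sex, gebv0,
                       cfg$selection$nSires, cfg$selection$nDams)

  list(config = cfg, h2 = h2, seed = seed, map = map, model = model,
       arch = arch, capacity = capacity, ped = ped,
       prev = cohortA, cur = cohortB, fit = fit, gebvCur = gebv0,
       selected = sel, generation = 0L,
       metrics = cohortMetrics(cohortB, gebv0, ped, 0L))
}

# internal: build the mating plan a scheme dictates from the current state
buildSchemePlan <- function(state, scheme) {
  cfg <- state$config
  sel <- state$selected
  gebvs <- state$gebvCur
  cap <- state$capacity
  litter <- cfg$litterSize
  if (scheme == "rand")
    return(randomMating(sel$sires, sel$dams, cap, litter))
  if (scheme == "p_assort")
    return(positiveAssortative(sel$sires, sel$dams, gebvs, cap, litter))
  if (scheme == "n_assort")
    return(negativeAssortative(sel$sires, sel$dams, gebvs, cap, litter))
  # genomic mating: optimize over the frontier, read off the endpoint
  mi <- markerIndex(state$map)
  parents <- subsetPopulation(state$cur,
                              match(c(sel$sires, sel$dams), state$cur@id))
  M <- dosage(parents)[, mi, drop = FALSE]
  G <- if (grepl("snp", scheme)) grmVanRaden(M) else
    segmentKinship(parents, cfg$roh$minLengthCM, cfg$roh$minMarkers)
  merit <- setNames(as.numeric(M %*% state$fit@a), as.character(parents@id))
  load <- heterozygosityLoad(parents, state$fit)
  gmCap <- as.integer(ceiling(cap * cfg$gmCapacityFactor))
  front <- optimizeMating(sel$sires, sel$dams, G, merit, capacity = gmCap,
                          hetLoad = load, gaPopSize = cfg$ga$popSize,
                          nIter = cfg$ga$nIter, nOffspring = litter)
  idx <- if (grepl("gain", scheme)) front@maxGain else front@minInbreeding
  front@plans[[idx]]
}

#' Advance one generation of a breeding scheme
#'
#' Builds the scheme's mating plan from the currently selected parents,
#' creates the offspring cohort (meiosis, true breeding values,
#' phenotypes), refits BayesB on the rolling two-generation reference,
#' assigns GEBVs to the new candidate cohort, records its metrics and
#' selects the next parents.
#'
#' @param state a state list from \code{\link{initExperimentState}} or a
#'   previous \code{runGeneration} call.
#' @param scheme one of \code{"rand"}, \code{"p_assort"}, \code{"n_assort"},
#'   \code{"gm_snp_gain"}, \code{"gm_snp_inb"}, \code{"gm_roh_gain"},
#'   \code{"gm_roh_inb"}.
#' @return the advanced state; \code{state$metrics} accumulates one row per
#'   generation.
#' @export
runGeneration <- function(state, scheme) {
  scheme <- match.arg(scheme, schemeIds())
  cfg <- state$config
  plan <- buildSchemePlan(state, scheme)
  off <- offspringFromPlan(state$cur, plan, state$model,
                           idStart = max(state$cur@id) + 1L)
  ped <- rbind(state$ped, pedigree(off)[, c("id", "sire", "dam")])
  off <- assignCohortTraits(off, state$cur, state$arch, ped, cfg$tbvMode)

  mi <- markerIndex(state$map)
  refM <- rbind(dosage(state$cur)[, mi, drop = FALSE],
                dosage(off)[, mi, drop = FALSE])
  refY <- c(state$cur@traits$y, off@traits$y)
  fit <- do.call(fitBayesB, c(list(M = refM, y = refY), cfg$bayesb))
  gebvs <- gebv(dosage(off)[, mi, drop = FALSE], fit)
  sel <- selectParents(off@id, off@sex, gebvs,
                       cfg$selection$nSires, cfg$selection$nDams)
  u <- state$generation + 1L
  state$prev <- state$cur
  state$cur <- off
  state$ped <- ped
  state$fit <- fit
  state$gebvCur <- gebvs
  state$selected <- sel
  state$generation <- u
  state$metrics <- rbind(state$metrics, cohortMetrics(off, gebvs, ped, u))
  state
}

#' Run the full replicated mating-scheme experiment
#'
#' Loops replicates x heritabilities x schemes. Within a replicate all
#' schemes share the same genome, founders, burn-in generations and
#' generation-0 BayesB fit (the state from
#' \code{\link{initExperimentState}}), so schemes diverge only at the first
#' scheme mating. Replicate r uses seed \code{baseSeed + r}.
#'
#' @param config configuration list (\code{\link{deskPreset}} /
#'   \code{\link{fullScalePreset}} / \code{\link{readConfig}}).
#' @param schemes character vector of scheme ids (default all seven).
#' @param h2Values heritabilities to simulate (default c(0.1, 0.3, 0.5)).
#' @param replicates number of replicates (default 5).
#' @param baseSeed base integer seed.
#' @param verbose print progress lines.
#' @return list with \code{generation} (per-generation cohort means, long),
#'   \code{scheme} (one row per scheme x h2 x replicate with \code{deltaG}
#'   and \code{deltaF}) and \code{summary} (mean +/- SD over replicates).
#' @export
runExperiment <- function(config = deskPreset(), schemes = schemeIds(),
                          h2Values = c(0.1, 0.3, 0.5), replicates = 5L,
                          baseSeed = 1L, verbose = FALSE) {
  schemes <- match.arg(schemes, schemeIds(), several.ok = TRUE)
  genRows <- list(); schemeRows <- list()
  for (r in seq_len(replicates)) {
    for (h2 in h2Values) {
      state0 <- initExperimentState(config, h2, baseSeed + r)
      for (sc in schemes) {
        if (verbose)
          message(sprintf("replicate %d h2=%.1f scheme=%s", r, h2, sc))
        set.seed(baseSeed + r + 7919L * match(sc, schemeIds()))
        st <- state0
        for (u in seq_len(config$nGenerations)) st <- runGeneration(st, sc)
        m <- st$metrics
        genRows[[length(genRows) + 1L]] <-
          cbind(scheme = sc, h2 = h2, replicate = r, m)
        schemeRows[[length(schemeRows) + 1L]] <- data.frame(
          scheme = sc, h2 = h2, replicate = r,
          deltaG = deltaG(m$meanGEBV), deltaGtbv = deltaG(m$meanTBV),
          deltaF = deltaF(m$meanFPED),
          finalFPED = m$meanFPED[nrow(m)], finalFGRM = m$meanFGRM[nrow(m)])
      }
    }
  }
  generation <- do.call(rbind, genRows)
  scheme <- do.call(rbind, schemeRows)
  summary <- do.call(rbind, lapply(
    split(scheme, list(scheme$scheme, scheme$h2), drop = TRUE),
    function(d) data.frame(
      scheme = d$scheme[1], h2 = d$h2[1], n = nrow(d),
      deltaG = mean(d$deltaG), deltaG_sd = sd(d$deltaG),
      deltaF = mean(d$deltaF), deltaF_sd = sd(d$deltaF))))
  rownames(summary) <- NULL
  list(generation = generation, scheme = scheme, summary = summary)
}

#' Format a replicate summary in mean +/- SD style
#'
#' @param summary the \code{summary} element of \code{\link{runExperiment}}.
#' @param digits digits after the decimal point (default 3).
#' @return data.frame with formatted \code{deltaG} and \code{deltaF} columns.
#' @export
formatSummary <- function(summary, digits = 3) {
  fmt <- function(m, s) sprintf(paste0("%.", digits, "f ± %.",
                                       digits, "f"), m, s)
  data.frame(h2 = summary$h2, scheme = summary$scheme,
             deltaG = fmt(summary$deltaG, summary$deltaG_sd),
             deltaF = fmt(summary$deltaF, summary$deltaF_sd))
}
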