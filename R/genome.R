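#' Build a random genome map
#'
#' Draws marker and QTL positions independently and uniformly on
#' \code{(0, lengthCM)} per chromosome, then sorts them into map order.
#' Positions are rounded to 1e-6 cM; ties (within a chromosome, across both
#' roles) are resolved by redrawing the clashing positions.
#'
#' @param nChr number of chromosomes (default 18).
#' @param lengthCM chromosome length in cM (default 100).
#' @param nMarkersPerChr markers per chromosome (default 1700).
#' @param nQtlPerChr QTL per chromosome (default 17).
#' @param seed integer seed; the map is deterministic given the seed.
#' @param maxDensity maximum loci per cM allowed before the map is rejected
#'   as too dense to hold distinct rounded positions.
#' @return a \linkS4class{GenomeMap}.
#' @examples
#' map <- buildGenomeMap(2, 50, 20, 2, seed = 1)
#' nMarkers(map); nQtl(map)
#' @export
buildGenomeMap <- function(nChr = 18L, lengthCM = 100, nMarkersPerChr = 1700L,
                           nQtlPerChr = 17L, seed = 1L,
                           maxDensity = 1e4) {
  stopifnot(nChr >= 1, lengthCM > 0, nMarkersPerChr >= 0, nQtlPerChr >= 0,
            nMarkersPerChr + nQtlPerChr >= 1)
  perChr <- nMarkersPerChr + nQtlPerChr
  if (perChr / lengthCM > maxDensity)
    stop("locus density exceeds the configured limit; ",
         "distinct rounded positions cannot be guaranteed")
  set.seed(seed)
  chr <- integer(0); pos <- numeric(0); role <- character(0)
  for (c in seq_len(nChr)) {
    p <- round(runif(perChr, 0, lengthCM), 6)
    r <- c(rep("marker", nMarkersPerChr), rep("qtl", nQtlPerChr))
    # re-draw duplicates until positions are distinct
    for (tries in 1:100) {
      dup <- duplicated(p) | p == 0
      if (!any(dup)) break
      p[dup] <- round(runif(sum(dup), 0, lengthCM), 6)
    }
    if (anyDuplicated(p)) stop("could not resolve tied positions")
    o <- order(p)
    chr <- c(chr, rep(c, perChr)); pos <- c(pos, p[o]); role <- c(role, r[o])
  }
  new("GenomeMap", chr = as.integer(chr), pos = pos, role = role,
      nChr = as.integer(nChr), lengthCM = as.numeric(lengthCM))
}

# internal constructor: population from components
newPopulation <- function(id, sex, sire, dam, generation, hap1, hap2, map,
                          traits = data.frame()) {
  new("Population", id = as.integer(id), sex = as.character(sex),
      sire = as.integer(sire), dam = as.integer(dam),
      generation = as.integer(generation),
      hap1 = hap1, hap2 = hap2, map = map, traits = traits)
}

# internal: subset a population by row index, keeping traits aligned
subsetPopulation <- function(pop, idx) {
  tr <- pop@traits
  if (nrow(tr)) tr <- tr[idx, , drop = FALSE]
  newPopulation(pop@id[idx], pop@sex[idx], pop@sire[idx], pop@dam[idx],
                pop@generation[idx],
                pop@hap1[idx, , drop = FALSE], pop@hap2[idx, , drop = FALSE],
                pop@map, tr)
}

#' Simulate the historical (mutation-drift) population
#'
#' Initializes every locus at allele frequency 0.5 (haplotype alleles drawn
#' independently), then runs discrete generations of random pair mating at a
#' 1:1 sex ratio with recurrent symmetric allele-flip mutation, in two
#' phases: a large phase-1 population followed by a bottlenecked phase-2
#' population. Gametes are sampled through the Haldane-map meiosis engine,
#' so linkage disequilibrium accumulates by drift. The final generation is
#' returned as a phased \linkS4class{Population} (generation index -1,
#' unknown parents).
#'
#' @param map a \linkS4class{GenomeMap}.
#' @param nPhase1,gensPhase1 phase-1 population size and generation count
#'   (defaults 2000 and 1000).
#' @param nPhase2,gensPhase2 bottleneck population size and generation count
#'   (defaults 400 and 1000).
#' @param mutationRate per-locus per-gamete allele-flip probability
#'   (default 2.5e-5, identical for markers and QTL).
#' @param seed integer seed.
#' @return a \linkS4class{Population} of the final historical generation.
#' @export
simulateHistorical <- function(map, nPhase1 = 2000L, gensPhase1 = 1000L,
                               nPhase2 = 400L, gensPhase2 = 1000L,
                               mutationRate = 2.5e-5, seed = 1L) {
  stopifnot(nPhase1 >= 2, nPhase2 >= 2, gensPhase1 >= 0, gensPhase2 >= 0,
            mutationRate >= 0)
  if (nPhase1 %% 2L || nPhase2 %% 2L)
    stop("population sizes must be even to hold a 1:1 sex ratio")
  set.seed(seed)
  L <- nLoci(map)
  model <- recombinationModel(map)
  n <- as.integer(nPhase1)
  hap1 <- matrix(as.integer(runif(n * L) < 0.5), n, L)
  hap2 <- matrix(as.integer(runif(n * L) < 0.5), n, L)
  sex <- rep(c("M", "F"), each = n / 2L)

  stepGen <- function(hap1, hap2, sex, nOut) {
    males <- which(sex == "M"); females <- which(sex == "F")
    sires <- sample(males, nOut, replace = TRUE)
    dams <- sample(females, nOut, replace = TRUE)
    g1 <- cpp_sample_gametes(hap1, hap2, model@r, model@chrFirst, sires - 1L)
    g2 <- cpp_sample_gametes(hap1, hap2, model@r, model@chrFirst, dams - 1L)
    if (mutationRate > 0) {
      nf1 <- rbinom(1L, nOut * L, mutationRate)
      if (nf1 > 0) { i <- sample.int(nOut * L, nf1); g1[i] <- 1L - g1[i] }
      nf2 <- rbinom(1L, nOut * L, mutationRate)
      if (nf2 > 0) { i <- sample.int(nOut * L, nf2); g2[i] <- 1L - g2[i] }
    }
    list(hap1 = g1, hap2 = g2,
         sex = sample(rep(c("M", "F"), each = nOut / 2L)))
  }

  for (g in seq_len(gensPhase1)) {
    st <- stepGen(hap1, hap2, sex, n)
    hap1 <- st$hap1; hap2 <- st$hap2; sex <- st$sex
  }
  n2 <- as.integer(nPhase2)
  for (g in seq_len(gensPhase2)) {
    st <- stepGen(hap1, hap2, sex, n2)
    hap1 <- st$hap1; hap2 <- st$hap2; sex <- st$sex
    n <- n2
  }
  newPopulation(seq_len(n), sex, rep(NA_integer_, n), rep(NA_integer_, n),
                rep(-1L, n), hap1, hap2, map)
}

#' Sample modern founders from the historical population
#'
#' Uniform sampling without replacement within each sex. The selected
#' animals become pedigree roots: parents set unknown, generation 0,
#' pedigree inbreeding 0 by convention. Loci monomorphic in the selected
#' founders (see \code{\link{monomorphicLoci}}) are retained in the map;
#' downstream relationship matrices and BayesB exclude them from frequency
#' sums instead.
#'
#' @param pop historical \linkS4class{Population}.
#' @param nMales,nFemales founder counts per sex (full-scale 30 and 900).
#' @param seed integer seed.
#' @return a founder \linkS4class{Population} with ids 1..(nMales+nFemales).
#' @export
sampleModernFounders <- function(pop, nMales = 30L, nFemales = 900L,
                                 seed = 1L) {
  males <- which(pop@sex == "M"); females <- which(pop@sex == "F")
  if (length(males) < nMales) stop("not enough male candidates")
  if (length(females) < nFemales) stop("not enough female candidates")
  set.seed(seed)
  idx <- c(sample(males, nMales), sample(females, nFemales))
  n <- length(idx)
  newPopulation(seq_len(n), pop@sex[idx],
                rep(NA_integer_, n), rep(NA_integer_, n), rep(0L, n),
                pop@hap1[idx, , drop = FALSE], pop@hap2[idx, , drop = FALSE],
                pop@map)
}

#' Loci fixed (monomorphic) in a population
#'
#' @param pop a \linkS4class{Population}.
#' @return logical vector over map loci, \code{TRUE} where the genotype
#'   dosage has zero variance in \code{pop}.
#' @export
monomorphicLoci <- function(pop) {
  d <- pop@hap1 + pop@hap2
  apply(d, 2, function(x) length(unique(x)) == 1L)
}
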