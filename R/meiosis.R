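#' Haldane recombination fraction
#'
#' Maps a genetic distance \eqn{c} (Morgan) to a recombination fraction
#' \eqn{r = \frac{1}{2}(1 - e^{-2c})}: 0 at zero distance, approaching 1/2
#' (free recombination) as the distance grows. Vectorized.
#'
#' @param c genetic distance in Morgan, \code{c >= 0}.
#' @return recombination fraction(s) in \code{[0, 0.5)}.
#' @examples
#' recombFraction(c(0, 0.1, 10))
#' @export
recombFraction <- function(c) {
  if (any(c < 0)) stop("genetic distance must be non-negative")
  0.5 * (1 - exp(-2 * c))
}

#' Per-locus recombination model for a genome map
#'
#' Converts adjacent-locus cM distances to Morgan and applies the Haldane
#' map function. The fraction stored at the first locus of each chromosome
#' is unused (chromosomes assort independently).
#'
#' @slot r adjacent-locus recombination fraction per locus.
#' @slot chrFirst logical, \code{TRUE} at the first locus of a chromosome.
#' @exportClass RecombinationModel
setClass("RecombinationModel",
  representation(r = "numeric", chrFirst = "logical"))

setValidity("RecombinationModel", function(object) {
  r <- object@r[!object@chrFirst]
  if (length(r) && (min(r) < 0 || max(r) >= 0.5))
    "recombination fractions must lie in [0, 0.5)" else TRUE
})

#' @rdname RecombinationModel-class
#' @param map a \linkS4class{GenomeMap}.
#' @return a \code{RecombinationModel} aligned with the map's loci.
#' @export
recombinationModel <- function(map) {
  L <- nLoci(map)
  chrFirst <- c(TRUE, map@chr[-1] != map@chr[-L])
  d <- c(0, diff(map@pos)) / 100  # cM -> Morgan
  d[chrFirst] <- 0
  new("RecombinationModel", r = recombFraction(d), chrFirst = chrFirst)
}

#' Sample one gamete from a phased parent
#'
#' Implements the stepwise inheritance rule: the first locus of each
#' chromosome is copied from a uniformly chosen parental strand; each
#' subsequent locus switches strand iff an independent uniform draw falls
#' below the adjacent recombination fraction. Draws come from R's RNG
#' stream, so results are reproducible under \code{set.seed}.
#'
#' @param h1,h2 the parent's two haplotypes (0/1 integer vectors).
#' @param model a \linkS4class{RecombinationModel}.
#' @return an integer 0/1 haplotype of the same length.
#' @export
sampleGamete <- function(h1, h2, model) {
  if (length(h1) != length(h2) || length(h1) != length(model@r))
    stop("haplotype length does not match the map")
  m1 <- matrix(as.integer(h1), 1); m2 <- matrix(as.integer(h2), 1)
  as.integer(cpp_sample_gametes(m1, m2, model@r, model@chrFirst, 0L))
}

#' Create offspring from a sire-dam pair
#'
#' Each offspring receives one sire gamete as its first (paternal) haplotype
#' and one dam gamete as its second (maternal) haplotype. Sexes are assigned
#' as an equal split per litter (5M/5F for a litter of 10); odd litters
#' alternate which sex gets the extra animal.
#'
#' @param pop \linkS4class{Population} holding both parents.
#' @param sireId,damId parent ids in \code{pop}.
#' @param nOffspring litter size (default 10).
#' @param model a \linkS4class{RecombinationModel} for \code{pop}'s map.
#' @param idStart first id to assign to the offspring.
#' @return a \linkS4class{Population} of the litter (generation =
#'   max(parent generations) + 1).
#' @export
makeOffspring <- function(pop, sireId, damId, nOffspring = 10L, model,
                          idStart = max(pop@id) + 1L) {
  plan <- new("MatingPlan", sire = as.integer(sireId), dam = as.integer(damId),
              nOffspring = as.integer(nOffspring), capacity = NA_integer_)
  offspringFromPlan(pop, plan, model, idStart)
}

# internal batch engine: all litters of a plan in two C++ calls
offspringFromPlan <- function(pop, plan, model, idStart = max(pop@id) + 1L) {
  sRow <- match(plan@sire, pop@id); dRow <- match(plan@dam, pop@id)
  if (anyNA(sRow) || anyNA(dRow)) stop("parent id not found in population")
  sires <- rep(sRow, plan@nOffspring); dams <- rep(dRow, plan@nOffspring)
  n <- length(sires)
  h1 <- cpp_sample_gametes(pop@hap1, pop@hap2, model@r, model@chrFirst,
                           sires - 1L)
  h2 <- cpp_sample_gametes(pop@hap1, pop@hap2, model@r, model@chrFirst,
                           dams - 1L)
  # equal sex split within each litter, males first; odd litters alternate
  oddSeen <- 0L
  sex <- unlist(lapply(plan@nOffspring, function(k) {
    nM <- k %/% 2L
    if (k %% 2L == 1L) {
      oddSeen <<- oddSeen + 1L
      if (oddSeen %% 2L == 1L) nM <- nM + 1L
    }
    rep(c("M", "F"), c(nM, k - nM))
  }), use.names = FALSE)
  gen <- max(pop@generation[c(sRow, dRow)]) + 1L
  newPopulation(idStart + seq_len(n) - 1L, sex,
                pop@id[sires], pop@id[dams], rep(gen, n), h1, h2, pop@map)
}
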