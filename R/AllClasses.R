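#' Genome map of marker and QTL positions
#'
#' Positions are genetic (cM) on equally sized chromosomes. Every locus has
#' exactly one role, \code{"marker"} or \code{"qtl"}; loci are stored in map
#' order (chromosome, then position).
#'
#' @slot chr integer chromosome index per locus (1-based).
#' @slot pos numeric position in cM per locus, strictly increasing within a
#'   chromosome.
#' @slot role character, \code{"marker"} or \code{"qtl"} per locus.
#' @slot nChr number of chromosomes.
#' @slot lengthCM chromosome length in cM (common to all chromosomes).
#' @exportClass GenomeMap
setClass("GenomeMap",
  representation(chr = "integer", pos = "numeric", role = "character",
                 nChr = "integer", lengthCM = "numeric"))

setValidity("GenomeMap", function(object) {
  msgs <- character()
  L <- length(object@pos)
  if (length(object@chr) != L || length(object@role) != L)
    msgs <- c(msgs, "chr/pos/role lengths differ")
  if (!all(object@role %in% c("marker", "qtl")))
    msgs <- c(msgs, "role must be 'marker' or 'qtl'")
  if (any(object@pos < 0) || any(object@pos > object@lengthCM))
    msgs <- c(msgs, "positions must lie in [0, lengthCM]")
  for (c in unique(object@chr)) {
    p <- object@pos[object@chr == c]
    if (any(diff(p) <= 0)) {
      msgs <- c(msgs, "positions must be strictly increasing within chromosome")
      break
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Phased population of diploid individuals
#'
#' Haplotypes are biallelic with alleles coded 0/1 (the 1/2 coding used by
#' breeding software maps through the fixed bijection 1 -> 0, 2 -> 1).
#' \code{hap1} is the paternally inherited strand, \code{hap2} the maternal
#' one. Pedigree links use \code{NA} for unknown (founder) parents.
#'
#' @slot id integer individual ids, unique.
#' @slot sex character, \code{"M"} or \code{"F"}.
#' @slot sire,dam integer ids of the parents (\code{NA} for founders).
#' @slot generation integer cohort index of each individual.
#' @slot hap1,hap2 integer 0/1 matrices, individuals x loci.
#' @slot map the \linkS4class{GenomeMap} the haplotypes are laid out on.
#' @slot traits data.frame with 0 or n rows carrying per-individual trait
#'   state (columns \code{g}, \code{w}, \code{y}).
#' @exportClass Population
setClass("Population",
  representation(id = "integer", sex = "character", sire = "integer",
                 dam = "integer", generation = "integer",
                 hap1 = "matrix", hap2 = "matrix",
                 map = "GenomeMap", traits = "data.frame"))

setValidity("Population", function(object) {
  n <- length(object@id)
  L <- length(object@map@pos)
  msgs <- character()
  if (anyDuplicated(object@id)) msgs <- c(msgs, "ids must be unique")
  if (length(object@sex) != n || length(object@sire) != n ||
      length(object@dam) != n || length(object@generation) != n)
    msgs <- c(msgs, "metadata vectors must match number of individuals")
  if (!all(object@sex %in% c("M", "F"))) msgs <- c(msgs, "sex must be M/F")
  if (nrow(object@hap1) != n || nrow(object@hap2) != n)
    msgs <- c(msgs, "haplotype matrices must have one row per individual")
  if (ncol(object@hap1) != L || ncol(object@hap2) != L)
    msgs <- c(msgs, "haplotype length must equal number of map loci")
  if (n > 0 && (!all(object@hap1 %in% 0:1) || !all(object@hap2 %in% 0:1)))
    msgs <- c(msgs, "alleles must be coded 0/1")
  if (nrow(object@traits) != 0 && nrow(object@traits) != n)
    msgs <- c(msgs, "traits must have 0 or n rows")
  if (length(msgs)) msgs else TRUE
})

#' Additive trait architecture
#'
#' One QTL allele-substitution effect per QTL locus, rescaled so the founder
#' cohort's true breeding values realize exactly the genetic variance
#' \eqn{\sigma_g^2 = h^2 \sigma_p^2}. \code{sigmaA2} is the base-generation
#' additive variance used in the Mendelian-sampling variance and is never
#' updated in later generations.
#'
#' @slot qtlEffects numeric, one per QTL locus in map order.
#' @slot mu population mean of the phenotype.
#' @slot sigmaP2,h2,sigmaG2,sigmaE2,sigmaA2 variance components.
#' @slot gammaShape shape of the gamma distribution effects are drawn from.
#' @slot center founder-mean offset subtracted from the raw QTL sum so
#'   founder TBVs average zero.
#' @exportClass TraitArchitecture
setClass("TraitArchitecture",
  representation(qtlEffects = "numeric", mu = "numeric", sigmaP2 = "numeric",
                 h2 = "numeric", sigmaG2 = "numeric", sigmaE2 = "numeric",
                 sigmaA2 = "numeric", gammaShape = "numeric",
                 center = "numeric"))

setValidity("TraitArchitecture", function(object) {
  msgs <- character()
  if (abs(object@sigmaG2 + object@sigmaE2 - object@sigmaP2) > 1e-9)
    msgs <- c(msgs, "sigmaG2 + sigmaE2 must equal sigmaP2")
  if (object@h2 < 0 || object@h2 > 1) msgs <- c(msgs, "h2 must be in [0,1]")
  if (length(msgs)) msgs else TRUE
})

#' Posterior marker effects from a BayesB fit
#'
#' @slot a posterior-mean allele substitution effect per marker (monomorphic
#'   markers are pinned at zero).
#' @slot inclusionProb posterior probability each marker is in the model.
#' @slot intercept posterior-mean intercept.
#' @slot hyper list of hyperparameters used (\code{pi}, \code{nu}, \code{S2},
#'   \code{nuE}, \code{Se2}) plus the posterior-mean residual variance.
#' @exportClass MarkerEffects
setClass("MarkerEffects",
  representation(a = "numeric", inclusionProb = "numeric",
                 intercept = "numeric", hyper = "list"))

setValidity("MarkerEffects", function(object) {
  msgs <- character()
  if (length(object@a) != length(object@inclusionProb))
    msgs <- c(msgs, "a and inclusionProb lengths differ")
  ip <- object@inclusionProb
  if (length(ip) && (min(ip) < 0 || max(ip) > 1))
    msgs <- c(msgs, "inclusionProb must lie in [0,1]")
  if (length(msgs)) msgs else TRUE
})

#' Genomic or pedigree relationship matrix
#'
#' @slot G symmetric n x n relationship matrix.
#' @slot kind \code{"snp"} (VanRaden method 1), \code{"roh"} (2 x
#'   segment-based kinship) or \code{"pedigree"}.
#' @slot ids subject ids (row/column order of \code{G}).
#' @slot p allele-frequency vector used for centering (\code{kind = "snp"}),
#'   else length 0.
#' @exportClass RelationshipMatrix
setClass("RelationshipMatrix",
  representation(G = "matrix", kind = "character", ids = "integer",
                 p = "numeric"))

setValidity("RelationshipMatrix", function(object) {
  msgs <- character()
  G <- object@G
  if (nrow(G) != ncol(G)) msgs <- c(msgs, "G must be square")
  else if (nrow(G) && max(abs(G - t(G))) > 1e-10)
    msgs <- c(msgs, "G must be symmetric (tol 1e-10)")
  if (length(object@ids) != nrow(G))
    msgs <- c(msgs, "ids must match matrix order")
  if (!object@kind %in% c("snp", "roh", "pedigree"))
    msgs <- c(msgs, "kind must be snp/roh/pedigree")
  if (object@kind == "roh" && nrow(G) &&
      (min(G) < -1e-10 || max(G) > 2 + 1e-10))
    msgs <- c(msgs, "roh entries must lie in [0, 2]")
  if (length(msgs)) msgs else TRUE
})

#' Mating plan (sire-dam pair list)
#'
#' Each row of the derived incidence matrix P carries 1/2 on its sire and dam
#' columns, so row sums are 1 and \code{P \%*\% merit} is the midparent merit.
#'
#' @slot sire,dam integer parent ids per mating.
#' @slot nOffspring planned litter size per mating.
#' @slot capacity maximum number of matings per sire the plan was built under.
#' @exportClass MatingPlan
setClass("MatingPlan",
  representation(sire = "integer", dam = "integer", nOffspring = "integer",
                 capacity = "integer"))

setValidity("MatingPlan", function(object) {
  msgs <- character()
  k <- length(object@sire)
  if (length(object@dam) != k || length(object@nOffspring) != k)
    msgs <- c(msgs, "sire/dam/nOffspring lengths differ")
  if (anyDuplicated(object@dam))
    msgs <- c(msgs, "every dam must appear in exactly one mating")
  if (length(object@capacity) == 1 && !is.na(object@capacity) && k &&
      max(table(object@sire)) > object@capacity)
    msgs <- c(msgs, "sire usage exceeds capacity")
  if (k && any(object@nOffspring < 1))
    msgs <- c(msgs, "nOffspring must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Nondominated frontier of mating plans
#'
#' The archive of plans for which no other member has gain >= and
#' inbreeding <= with one inequality strict. \code{maxGain} and
#' \code{minInbreeding} index the two endpoint schemes.
#'
#' @slot gain,inbreeding objective values per archived plan.
#' @slot plans list of \linkS4class{MatingPlan}.
#' @slot maxGain,minInbreeding indices of the endpoint plans.
#' @exportClass MatingFrontier
setClass("MatingFrontier",
  representation(gain = "numeric", inbreeding = "numeric", plans = "list",
                 maxGain = "integer", minInbreeding = "integer"))

setValidity("MatingFrontier", function(object) {
  msgs <- character()
  k <- length(object@gain)
  if (length(object@inbreeding) != k || length(object@plans) != k)
    msgs <- c(msgs, "gain/inbreeding/plans lengths differ")
  if (k) {
    if (object@gain[object@maxGain] < max(object@gain) - 1e-9)
      msgs <- c(msgs, "maxGain endpoint is not the maximum-gain member")
    if (object@inbreeding[object@minInbreeding] >
        min(object@inbreeding) + 1e-9)
      msgs <- c(msgs, "minInbreeding endpoint is not the minimum member")
  }
  if (length(msgs)) msgs else TRUE
})
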