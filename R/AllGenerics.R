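#' @name gmatesim-accessors
#' @title Accessors for gmatesim classes
#' @description Small accessor layer over the S4 containers: counts and
#'   index vectors for \linkS4class{GenomeMap}, genotype dosages and pedigree
#'   for \linkS4class{Population}, the numeric matrix behind a
#'   \linkS4class{RelationshipMatrix}, and the pair table of a
#'   \linkS4class{MatingPlan}.
#' @param x an object of the documented class.
#' @return See the individual generics.
NULL

#' @rdname gmatesim-accessors
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))
#' @rdname gmatesim-accessors
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))
#' @rdname gmatesim-accessors
#' @export
setGeneric("nQtl", function(x) standardGeneric("nQtl"))
#' @rdname gmatesim-accessors
#' @export
setGeneric("markerIndex", function(x) standardGeneric("markerIndex"))
#' @rdname gmatesim-accessors
#' @export
setGeneric("qtlIndex", function(x) standardGeneric("qtlIndex"))
#' @rdname gmatesim-accessors
#' @export
setGeneric("nInd", function(x) standardGeneric("nInd"))
#' @rdname gmatesim-accessors
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))
#' @rdname gmatesim-accessors
#' @export
setGeneric("pedigree", function(x) standardGeneric("pedigree"))
#' @rdname gmatesim-accessors
#' @export
setGeneric("relMatrix", function(x) standardGeneric("relMatrix"))
#' @rdname gmatesim-accessors
#' @export
setGeneric("planTable", function(x) standardGeneric("planTable"))

setMethod("nLoci", "GenomeMap", function(x) length(x@pos))
setMethod("nMarkers", "GenomeMap", function(x) sum(x@role == "marker"))
setMethod("nQtl", "GenomeMap", function(x) sum(x@role == "qtl"))
setMethod("markerIndex", "GenomeMap", function(x) which(x@role == "marker"))
setMethod("qtlIndex", "GenomeMap", function(x) which(x@role == "qtl"))

setMethod("nInd", "Population", function(x) length(x@id))
setMethod("nLoci", "Population", function(x) nLoci(x@map))

#' @describeIn gmatesim-accessors genotype dosage matrix
#'   \code{hap1 + hap2} (individuals x loci, entries 0/1/2), rownames set to
#'   individual ids.
setMethod("dosage", "Population", function(x) {
  d <- x@hap1 + x@hap2
  rownames(d) <- as.character(x@id)
  d
})

#' @describeIn gmatesim-accessors pedigree data.frame with columns
#'   \code{id}, \code{sire}, \code{dam}, \code{sex}, \code{generation}.
setMethod("pedigree", "Population", function(x) {
  data.frame(id = x@id, sire = x@sire, dam = x@dam, sex = x@sex,
             generation = x@generation)
})

setMethod("relMatrix", "RelationshipMatrix", function(x) {
  G <- x@G
  dimnames(G) <- list(as.character(x@ids), as.character(x@ids))
  G
})

#' @describeIn gmatesim-accessors pair list of a mating plan as a data.frame
#'   with columns \code{sire}, \code{dam}, \code{nOffspring}.
setMethod("planTable", "MatingPlan", function(x) {
  data.frame(sire = x@sire, dam = x@dam, nOffspring = x@nOffspring)
})

setMethod("show", "GenomeMap", function(object) {
  cat(sprintf("GenomeMap: %d chromosomes x %g cM, %d markers + %d QTL\n",
              object@nChr, object@lengthCM, nMarkers(object), nQtl(object)))
})

setMethod("show", "Population", function(object) {
  cat(sprintf(
    "Population: %d individuals (%d M / %d F), generations %s, %d loci\n",
    nInd(object), sum(object@sex == "M"), sum(object@sex == "F"),
    paste(range(object@generation), collapse = "-"), nLoci(object)))
  if (nrow(object@traits))
    cat(sprintf("  traits attached: mean g = %.3f, mean y = %.3f\n",
                mean(object@traits$g), mean(object@traits$y)))
})

setMethod("show", "TraitArchitecture", function(object) {
  cat(sprintf(
    "TraitArchitecture: %d QTL, h2 = %.2f, sigmaP2 = %g (g %g + e %g)\n",
    length(object@qtlEffects), object@h2, object@sigmaP2, object@sigmaG2,
    object@sigmaE2))
})

setMethod("show", "MarkerEffects", function(object) {
  cat(sprintf(
    "MarkerEffects: %d markers, %d with inclusionProb > 0.5, intercept %.3f\n",
    length(object@a), sum(object@inclusionProb > 0.5), object@intercept))
})

setMethod("show", "RelationshipMatrix", function(object) {
  cat(sprintf("RelationshipMatrix (%s): %d x %d, mean diagonal %.3f\n",
              object@kind, nrow(object@G), ncol(object@G),
              if (nrow(object@G)) mean(diag(object@G)) else NA_real_))
})

setMethod("show", "MatingPlan", function(object) {
  cat(sprintf("MatingPlan: %d matings, %d sires x %d dams, litter %s\n",
              length(object@sire), length(unique(object@sire)),
              length(object@dam),
              paste(unique(object@nOffspring), collapse = "/")))
})

setMethod("show", "MatingFrontier", function(object) {
  cat(sprintf(
    "MatingFrontier: %d nondominated plans; max gain %.3f (inb %.3f), min inb %.3f (gain %.3f)\n",
    length(object@gain), object@gain[object@maxGain],
    object@inbreeding[object@maxGain],
    object@inbreeding[object@minInbreeding],
    object@gain[object@minInbreeding]))
})
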