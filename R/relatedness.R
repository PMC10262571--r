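#' SNP genomic relationship matrix (VanRaden method 1)
#'
#' \eqn{G = Z Z' / (2 \sum_j p_j (1 - p_j))} with \eqn{Z} the dosage matrix
#' column-centered by \eqn{2 p_j}. Allele frequencies are computed from the
#' supplied matrix itself; monomorphic columns are dropped from both the
#' cross-product and the denominator.
#'
#' @param M genotype dosage matrix (individuals x markers, 0/1/2). Row
#'   names, when present, become the subject ids.
#' @return a \linkS4class{RelationshipMatrix} of kind \code{"snp"}.
#' @export
grmVanRaden <- function(M) {
  stopifnot(ncol(M) >= 1)
  p <- colMeans(M) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all markers monomorphic")
  Z <- sweep(M[, poly, drop = FALSE], 2, 2 * p[poly])
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  ids <- if (!is.null(rownames(M))) as.integer(rownames(M)) else
    seq_len(nrow(M))
  new("RelationshipMatrix", G = unname(G), kind = "snp", ids = ids,
      p = unname(p[poly]))
}

#' ROH-segment relationship matrix
#'
#' Two times the shared-segment kinship computed from phased marker
#' haplotypes: for a pair of individuals, kinship is the average over their
#' four haplotype combinations of the genetic length lying in maximal
#' identical stretches passing both thresholds, divided by the assayable map
#' length. The diagonal uses an individual's own two haplotypes (self-pairs
#' included), so a fully autozygous animal has diagonal 2.
#'
#' @param pop a phased \linkS4class{Population}.
#' @param minLengthCM minimum qualifying segment length in cM (default 1).
#' @param minMarkers minimum markers per qualifying segment (default 20).
#' @return a \linkS4class{RelationshipMatrix} of kind \code{"roh"}.
#' @export
segmentKinship <- function(pop, minLengthCM = 1, minMarkers = 20L) {
  mi <- markerIndex(pop@map)
  n <- nInd(pop)
  H <- matrix(0L, 2L * n, length(mi))
  H[seq(1, 2 * n, by = 2), ] <- pop@hap1[, mi, drop = FALSE]
  H[seq(2, 2 * n, by = 2), ] <- pop@hap2[, mi, drop = FALSE]
  f <- cpp_segment_kinship(H, pop@map@pos[mi], pop@map@chr[mi],
                           minLengthCM, as.integer(minMarkers))
  new("RelationshipMatrix", G = 2 * f, kind = "roh", ids = pop@id,
      p = numeric(0))
}

#' Pedigree inbreeding coefficients
#'
#' Wright's inbreeding coefficient computed by the tabular (recursive
#' additive relationship) method, which is provably equal to path counting
#' \eqn{F = \sum (1/2)^N (1 + F_A)} over all ancestor paths. Founders (any
#' animal with at least one unknown parent) have F = 0.
#'
#' @param ped data.frame with columns \code{id}, \code{sire}, \code{dam}
#'   (\code{NA} for unknown). Parents must be listed before their offspring;
#'   the function reorders if needed and errors on cycles.
#' @return numeric vector of inbreeding coefficients named by id.
#' @export
fPed <- function(ped) {
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  if (anyDuplicated(ped$id)) stop("duplicate ids in pedigree")
  n <- nrow(ped)
  # topological order: repeatedly emit individuals whose parents are placed
  pos <- match(ped$sire, ped$id); pod <- match(ped$dam, ped$id)
  placed <- logical(n); ord <- integer(n); k <- 0L
  while (k < n) {
    sOk <- is.na(pos); sOk[!sOk] <- placed[pos[!is.na(pos)]]
    dOk <- is.na(pod); dOk[!dOk] <- placed[pod[!is.na(pod)]]
    ready <- !placed & sOk & dOk
    if (!any(ready)) stop("pedigree contains a cycle")
    idx <- which(ready)
    ord[k + seq_along(idx)] <- idx
    placed[idx] <- TRUE
    k <- k + length(idx)
  }
  o <- ord
  sire <- match(ped$sire[o], ped$id[o]); dam <- match(ped$dam[o], ped$id[o])
  sire[is.na(sire)] <- 0L; dam[is.na(dam)] <- 0L
  F <- cpp_fped(as.integer(sire), as.integer(dam))
  setNames(F[order(o)], as.character(ped$id))
}

#' Marker-based inbreeding coefficients
#'
#' Diagonal-based estimator
#' \eqn{F_{GRM,i} = \frac{1}{m}\sum_j (x_{ij} - 2p_j)^2 / (2p_j(1-p_j)) - 1}
#' over polymorphic markers; may be negative for less-homozygous-than-
#' expected individuals. Equals \code{diag(grmVanRaden(M)) - 1} only up to
#' the different weighting (this estimator normalizes per marker), so both
#' are exposed; the cross-product identity is against
#' \code{\link{fGrmVanRaden}}.
#'
#' @param M genotype dosage matrix (individuals x markers, 0/1/2).
#' @return numeric vector, named by rownames of \code{M} when present.
#' @export
fGrm <- function(M) {
  p <- colMeans(M) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all markers monomorphic")
  Z <- sweep(M[, poly, drop = FALSE], 2, 2 * p[poly])
  w <- 2 * p[poly] * (1 - p[poly])
  setNames(rowMeans(sweep(Z^2, 2, w, "/")) - 1, rownames(M))
}

#' VanRaden-diagonal inbreeding coefficients
#'
#' \code{diag(grmVanRaden(M)) - 1}: the same exclusions and centering as
#' \code{\link{grmVanRaden}}, so the identity
#' \code{fGrmVanRaden(M) == diag(relMatrix(grmVanRaden(M))) - 1} holds
#' exactly.
#'
#' @inheritParams fGrm
#' @return numeric vector, named by rownames of \code{M} when present.
#' @export
fGrmVanRaden <- function(M) {
  p <- colMeans(M) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all markers monomorphic")
  Z <- sweep(M[, poly, drop = FALSE], 2, 2 * p[poly])
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  setNames(rowSums(Z^2) / denom - 1, rownames(M))
}
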