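#' Fit a BayesB marker-effect model
#'
#' Gibbs sampler for the classical mixture prior: each marker effect is
#' exactly zero with prior probability \code{piZero} and otherwise carries
#' its own variance with a scaled-inverse-chi-square (\code{nu}, \code{S2})
#' prior. \code{S2} defaults to the Meuwissen-style value solving the
#' expected genetic variance: \eqn{S^2 = \frac{(\nu-2)}{\nu}\,
#' \tilde\sigma_a^2 / ((1-\pi) \sum_j 2 p_j (1-p_j))}, with the a-priori
#' genetic variance \eqn{\tilde\sigma_a^2} taken as half the phenotypic
#' variance. Monomorphic markers are excluded from sampling and pinned at
#' zero. Reported effects are posterior means over the kept (post burn-in,
#' thinned) samples.
#'
#' @param M genotype dosage matrix (individuals x markers, entries 0/1/2).
#' @param y phenotype vector.
#' @param nIter,burnIn,thin chain length, burn-in and thinning
#'   (defaults 20000, 1000, 20).
#' @param piZero prior exclusion probability (default 0.95).
#' @param nu slab degrees of freedom (default 4.2).
#' @param S2 slab scale; \code{NULL} (default) uses the rule above.
#' @param priorH2 a-priori proportion of variance captured by markers, used
#'   only to set default \code{S2} (default 0.5).
#' @return a \linkS4class{MarkerEffects} object.
#' @examples
#' set.seed(1)
#' M <- matrix(rbinom(200 * 50, 2, 0.5), 200, 50)
#' y <- M[, 5] * 2 + rnorm(200)
#' fit <- fitBayesB(M, y, nIter = 500, burnIn = 100, thin = 5, piZero = 0.9)
#' which.max(abs(fit@a))
#' @export
fitBayesB <- function(M, y, nIter = 20000L, burnIn = 1000L, thin = 20L,
                      piZero = 0.95, nu = 4.2, S2 = NULL, priorH2 = 0.5) {
  stopifnot(nrow(M) == length(y), nrow(M) >= 2, ncol(M) >= 1,
            piZero > 0, piZero < 1, nu > 2)
  if (nIter <= burnIn) stop("nIter must exceed burnIn")
  m <- ncol(M)
  vy <- var(y)
  if (!is.finite(vy) || vy <= 0) {
    warning("zero phenotypic variance: returning zero effects")
    return(new("MarkerEffects", a = rep(0, m), inclusionProb = rep(0, m),
               intercept = mean(y),
               hyper = list(pi = piZero, nu = nu, S2 = 0, nuE = 4,
                            Se2 = 0, varE = 0)))
  }
  p <- colMeans(M) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) {
    warning("all markers monomorphic: returning zero effects")
    return(new("MarkerEffects", a = rep(0, m), inclusionProb = rep(0, m),
               intercept = mean(y),
               hyper = list(pi = piZero, nu = nu, S2 = 0, nuE = 4,
                            Se2 = vy, varE = vy)))
  }
  sum2pq <- sum(2 * p[poly] * (1 - p[poly]))
  if (is.null(S2))
    S2 <- (nu - 2) / nu * priorH2 * vy / ((1 - piZero) * sum2pq)
  nuE <- 4
  Se2 <- (1 - priorH2) * vy * (nuE - 2) / nuE
  Xc <- sweep(M[, poly, drop = FALSE], 2, 2 * p[poly])  # center by 2p
  fit <- cpp_bayesb(Xc, as.numeric(y), as.integer(nIter), as.integer(burnIn),
                    as.integer(thin), piZero, nu, S2, nuE, Se2)
  a <- rep(0, m); ip <- rep(0, m)
  a[poly] <- fit$a; ip[poly] <- fit$inclusionProb
  # fold the centering back into the intercept so gebv() can use raw dosages
  intercept <- fit$intercept - sum(a[poly] * 2 * p[poly])
  new("MarkerEffects", a = a, inclusionProb = ip, intercept = intercept,
      hyper = list(pi = piZero, nu = nu, S2 = S2, nuE = nuE, Se2 = Se2,
                   varE = fit$varE))
}

#' Genomic estimated breeding values
#'
#' \eqn{GEBV_i = \hat\mu + \sum_j \hat a_j x_{ij}} on raw dosages.
#'
#' @param M genotype dosage matrix (individuals x markers).
#' @param effects a \linkS4class{MarkerEffects} fit.
#' @return numeric vector, named by rownames of \code{M} when present.
#' @export
gebv <- function(M, effects) {
  if (ncol(M) != length(effects@a)) stop("marker count mismatch")
  setNames(effects@intercept + as.numeric(M %*% effects@a), rownames(M))
}

#' Truncation selection of parents by GEBV
#'
#' Top \code{nSires} males and \code{nDams} females by GEBV; ties are broken
#' by id (ascending), so selection is stable.
#'
#' @param ids candidate ids.
#' @param sex candidate sexes ("M"/"F").
#' @param gebvs candidate GEBVs (same order).
#' @param nSires,nDams numbers to select (full-scale 30 and 900).
#' @return list with integer id vectors \code{sires} and \code{dams},
#'   ordered best-first.
#' @export
selectParents <- function(ids, sex, gebvs, nSires = 30L, nDams = 900L) {
  stopifnot(length(ids) == length(sex), length(ids) == length(gebvs))
  males <- sex == "M"; females <- sex == "F"
  if (sum(males) < nSires) stop("not enough male candidates")
  if (sum(females) < nDams) stop("not enough female candidates")
  pick <- function(keep, k) {
    o <- order(-gebvs[keep], ids[keep])
    ids[keep][o][seq_len(k)]
  }
  list(sires = pick(males, nSires), dams = pick(females, nDams))
}
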