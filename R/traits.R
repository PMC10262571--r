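#' Sample QTL allele-substitution effects
#'
#' Raw absolute effects are drawn from Gamma(shape, scale 1); signs are
#' assigned + or - with probability 1/2 each. The whole vector is then
#' rescaled by a single scalar so that the variance of the QTL dosage sum
#' over the supplied founder cohort equals \eqn{h^2 \sigma_p^2} exactly -
#' i.e. the QTL explain all of the genetic variance. A centering constant is
#' stored so founder true breeding values average zero.
#'
#' @param map a \linkS4class{GenomeMap} (supplies QTL count and order).
#' @param founders founder \linkS4class{Population} used for rescaling.
#' @param h2 narrow-sense heritability (study values 0.1, 0.3 or 0.5).
#' @param sigmaP2 phenotypic variance (default 1000).
#' @param shape gamma shape parameter (default 0.4).
#' @param mu population mean of the phenotype (default 0).
#' @return a \linkS4class{TraitArchitecture} with \code{sigmaA2} set to the
#'   base-generation genetic variance \eqn{h^2 \sigma_p^2}.
#' @export
sampleQtlEffects <- function(map, founders, h2, sigmaP2 = 1000,
                             shape = 0.4, mu = 0) {
  stopifnot(h2 >= 0, h2 <= 1, sigmaP2 > 0, shape > 0)
  nq <- nQtl(map)
  raw <- rgamma(nq, shape = shape, scale = 1) *
    sample(c(-1, 1), nq, replace = TRUE)
  X <- dosage(founders)[, qtlIndex(map), drop = FALSE]
  g0 <- as.numeric(X %*% raw)
  v0 <- var(g0) * (length(g0) - 1) / length(g0)  # population variance
  sigmaG2 <- h2 * sigmaP2
  if (h2 == 0) {
    eff <- rep(0, nq)
  } else {
    if (v0 <= 0)
      stop("all QTL monomorphic in founders: genetic variance cannot be rescaled")
    eff <- raw * sqrt(sigmaG2 / v0)
  }
  center <- mean(as.numeric(X %*% eff))
  new("TraitArchitecture", qtlEffects = eff, mu = as.numeric(mu),
      sigmaP2 = as.numeric(sigmaP2), h2 = as.numeric(h2),
      sigmaG2 = sigmaG2, sigmaE2 = sigmaP2 - sigmaG2, sigmaA2 = sigmaG2,
      gammaShape = shape, center = center)
}

#' True breeding values from QTL genotypes
#'
#' Direct QTL dosage sum \eqn{g_i = \sum_j a_j x_{ij}}, centered so the
#' founder cohort used at rescaling time averages zero. This is the
#' "genomic" TBV mode; the default pipeline mode is the pedigree-recursive
#' one (\code{\link{trueBVRecursive}}), and the two agree in expectation.
#'
#' @param pop a \linkS4class{Population} with QTL genotypes.
#' @param arch a \linkS4class{TraitArchitecture}.
#' @return numeric vector of TBVs, named by individual id.
#' @export
trueBVGenomic <- function(pop, arch) {
  X <- dosage(pop)[, qtlIndex(pop@map), drop = FALSE]
  setNames(as.numeric(X %*% arch@qtlEffects) - arch@center,
           as.character(pop@id))
}

#' Pedigree-recursive true breeding values
#'
#' \eqn{g_i = \frac{1}{2} g_s + \frac{1}{2} g_d + w_i} with the Mendelian
#' sampling term drawn fresh per offspring,
#' \eqn{w_i \sim N(0, \sigma_w^2)},
#' \eqn{\sigma_w^2 = \frac{1}{4}(1-f_s)\sigma_a^2 +
#' \frac{1}{4}(1-f_d)\sigma_a^2}, where \eqn{f_s, f_d} are the parents'
#' pedigree inbreeding coefficients and \eqn{\sigma_a^2} the base-generation
#' additive variance. Vectorized over offspring.
#'
#' @param gSire,gDam parental true breeding values.
#' @param fSire,fDam parental pedigree inbreeding coefficients in [0, 1].
#' @param sigmaA2 base-generation additive genetic variance.
#' @return list with components \code{g} and \code{w}.
#' @export
trueBVRecursive <- function(gSire, gDam, fSire, fDam, sigmaA2) {
  stopifnot(length(gSire) == length(gDam), all(fSire >= 0), all(fSire <= 1),
            all(fDam >= 0), all(fDam <= 1), sigmaA2 >= 0)
  sw2 <- 0.25 * (1 - fSire) * sigmaA2 + 0.25 * (1 - fDam) * sigmaA2
  w <- rnorm(length(gSire), 0, sqrt(sw2))
  list(g = 0.5 * gSire + 0.5 * gDam + w, w = w)
}

#' Phenotypes from true breeding values
#'
#' \eqn{y_i = \mu + g_i + e_i} with \eqn{e_i \sim N(0, \sigma_e^2)} drawn
#' fresh for every cohort.
#'
#' @param g true breeding values.
#' @param arch a \linkS4class{TraitArchitecture}.
#' @return list with components \code{y} and \code{e}.
#' @export
phenotype <- function(g, arch) {
  e <- rnorm(length(g), 0, sqrt(arch@sigmaE2))
  list(y = arch@mu + g + e, e = e)
}

# internal: attach trait state (g, w, y) to a population
attachTraits <- function(pop, g, w, y) {
  pop@traits <- data.frame(g = as.numeric(g), w = as.numeric(w),
                           y = as.numeric(y))
  pop
}
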