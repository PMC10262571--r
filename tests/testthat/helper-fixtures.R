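# Shared fixtures, built once per test session.

.fixtures <- new.env()

# small drifted population: 2 chromosomes x 50 cM, 200 markers + 10 QTL
# each, short mutation-drift history, 5 male / 50 female founders
tinyFounderSet <- function() {
  if (!is.null(.fixtures$founders)) return(.fixtures$founders)
  map <- buildGenomeMap(2, 50, 200, 10, seed = 101)
  hist <- simulateHistorical(map, nPhase1 = 120L, gensPhase1 = 60L,
                             nPhase2 = 120L, gensPhase2 = 60L,
                             mutationRate = 2.5e-5, seed = 102)
  founders <- sampleModernFounders(hist, 5, 50, seed = 103)
  .fixtures$founders <- list(map = map, founders = founders,
                             model = recombinationModel(map))
  .fixtures$founders
}

# hand-built population over an explicit map; haplotype rows supplied
manualPopulation <- function(hap1, hap2, map, sex = NULL) {
  n <- nrow(hap1)
  if (is.null(sex)) sex <- rep(c("M", "F"), length.out = n)
  new("Population", id = seq_len(n), sex = sex,
      sire = rep(NA_integer_, n), dam = rep(NA_integer_, n),
      generation = rep(0L, n), hap1 = hap1, hap2 = hap2, map = map,
      traits = data.frame())
}

# uniform map: nLoci equally spaced marker loci on one chromosome
uniformMap <- function(nLociPerChr, nChr = 1, lengthCM = 100,
                       qtl = integer(0)) {
  pos <- rep(seq(1, lengthCM - 1, length.out = nLociPerChr), nChr)
  chr <- rep(seq_len(nChr), each = nLociPerChr)
  role <- rep("marker", length(pos))
  role[qtl] <- "qtl"
  new("GenomeMap", chr = as.integer(chr), pos = pos, role = role,
      nChr = as.integer(nChr), lengthCM = as.numeric(lengthCM))
}

# random HWE genotype/haplotype pair at given allele frequencies
hweHaplotypes <- function(n, p) {
  L <- length(p)
  h1 <- matrix(as.integer(runif(n * L) < rep(p, each = n)), n, L)
  h2 <- matrix(as.integer(runif(n * L) < rep(p, each = n)), n, L)
  list(h1 = h1, h2 = h2)
}

# synthetic marker/QTL cohort for prediction tests: returns dosage matrix,
# true breeding values scaled to varG, phenotypes at heritability h2
predictionCohort <- function(n, m, nQtlLoci, h2, sigmaP2 = 1000) {
  p <- runif(m, 0.1, 0.9)
  M <- vapply(p, function(q) rbinom(n, 2, q), numeric(n))
  qtl <- sample(m, nQtlLoci)
  a <- rnorm(nQtlLoci)
  g <- as.numeric(M[, qtl] %*% a)
  varG <- h2 * sigmaP2
  g <- (g - mean(g)) * sqrt(varG / var(g))
  y <- g + rnorm(n, 0, sqrt(sigmaP2 - varG))
  list(M = M, g = g, y = y, qtl = qtl)
}
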