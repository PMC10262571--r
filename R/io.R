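#' Write a population in PLINK text format
#'
#' \code{.map} columns: chromosome, locus id (\code{chr_pos_role}), genetic
#' position in cM, bp position = \code{round(cM * 1e6)}. \code{.ped} holds
#' the phased alleles exported in 1/2 coding (0 -> 1, 1 -> 2), two columns
#' per locus (paternal then maternal strand), after the six standard
#' columns (family = 0, id, sire, dam, sex 1/2, phenotype from attached
#' traits or -9).
#'
#' @param pop a \linkS4class{Population}.
#' @param prefix output path prefix (writes \code{prefix.ped},
#'   \code{prefix.map}).
#' @return invisibly, the two file paths.
#' @export
writePlink <- function(pop, prefix) {
  map <- pop@map
  mapDf <- data.frame(chr = map@chr,
                      id = sprintf("%d_%s_%s", map@chr,
                                   format(map@pos, trim = TRUE), map@role),
                      cM = map@pos, bp = round(map@pos * 1e6))
  write.table(mapDf, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  n <- nInd(pop); L <- nLoci(pop)
  alleles <- matrix(0L, n, 2L * L)
  alleles[, seq(1, 2 * L, 2)] <- pop@hap1 + 1L
  alleles[, seq(2, 2 * L, 2)] <- pop@hap2 + 1L
  phe <- if (nrow(pop@traits)) pop@traits$y else rep(-9, n)
  ped <- cbind(0L, pop@id,
               ifelse(is.na(pop@sire), 0L, pop@sire),
               ifelse(is.na(pop@dam), 0L, pop@dam),
               ifelse(pop@sex == "M", 1L, 2L), phe, alleles)
  write.table(ped, paste0(prefix, ".ped"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(c(paste0(prefix, ".ped"), paste0(prefix, ".map")))
}

#' Read a phased population from PLINK text files
#'
#' Inverse of \code{\link{writePlink}} (the package's own PLINK-text
#' convention: phased 1/2 alleles, first strand paternal). Locus roles are
#' recovered from the locus ids when they follow the writer's naming,
#' otherwise all loci are treated as markers.
#'
#' @param prefix path prefix of the \code{.ped}/\code{.map} pair.
#' @param lengthCM chromosome length of the recovered map; defaults to the
#'   maximum observed position rounded up.
#' @return a \linkS4class{Population}.
#' @export
readPlink <- function(prefix, lengthCM = NULL) {
  mapDf <- read.table(paste0(prefix, ".map"), sep = "\t",
                      col.names = c("chr", "id", "cM", "bp"))
  role <- ifelse(grepl("_qtl$", mapDf$id), "qtl", "marker")
  if (is.null(lengthCM)) lengthCM <- ceiling(max(mapDf$cM))
  map <- new("GenomeMap", chr = as.integer(mapDf$chr), pos = mapDf$cM,
             role = role, nChr = length(unique(mapDf$chr)),
             lengthCM = as.numeric(lengthCM))
  ped <- as.matrix(read.table(paste0(prefix, ".ped"), sep = " "))
  n <- nrow(ped); L <- nrow(mapDf)
  alleles <- ped[, -(1:6), drop = FALSE]
  hap1 <- matrix(as.integer(alleles[, seq(1, 2 * L, 2)]) - 1L, n, L)
  hap2 <- matrix(as.integer(alleles[, seq(2, 2 * L, 2)]) - 1L, n, L)
  newPopulation(ped[, 2], ifelse(ped[, 5] == 1, "M", "F"),
                ifelse(ped[, 3] == 0, NA_integer_, ped[, 3]),
                ifelse(ped[, 4] == 0, NA_integer_, ped[, 4]),
                rep(0L, n), hap1, hap2, map)
}

#' Read a phased population from a VCF
#'
#' Requires phased GT fields (\code{|} separator) and biallelic sites.
#' Genetic positions are taken as bp / 1e6 (1 cM per Mb). Needs the
#' \pkg{vcfR} package.
#'
#' @param path VCF file path (may be gzipped).
#' @return a \linkS4class{Population} of unrelated, unsexed (alternating
#'   M/F) individuals; intended as a real-data entry point for the
#'   relationship and prediction modules.
#' @export
readPhasedVcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("readPhasedVcf requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  if (any(grepl("/", gt, fixed = TRUE)))
    stop("unphased genotypes: phased GT ('|') required")
  chrNames <- vcfR::getCHROM(v)
  chr <- as.integer(factor(chrNames, levels = unique(chrNames)))
  pos <- vcfR::getPOS(v) / 1e6
  o <- order(chr, pos)
  gt <- gt[o, , drop = FALSE]; chr <- chr[o]; pos <- pos[o]
  hap1 <- t(matrix(as.integer(substr(gt, 1, 1)), nrow(gt), ncol(gt)))
  hap2 <- t(matrix(as.integer(substr(gt, 3, 3)), nrow(gt), ncol(gt)))
  map <- new("GenomeMap", chr = chr, pos = pos,
             role = rep("marker", length(pos)),
             nChr = length(unique(chr)), lengthCM = max(pos) + 1e-6)
  n <- ncol(gt)
  newPopulation(seq_len(n), rep(c("M", "F"), length.out = n),
                rep(NA_integer_, n), rep(NA_integer_, n), rep(0L, n),
                hap1, hap2, map)
}

#' Write a mating plan as CSV
#'
#' Columns: mating_index, sire, dam, n_offspring.
#'
#' @param plan a \linkS4class{MatingPlan}.
#' @param path output CSV path.
#' @export
writeMatingPlan <- function(plan, path) {
  df <- cbind(mating_index = seq_along(plan@sire), planTable(plan))
  names(df)[4] <- "n_offspring"
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a mating plan written by \code{\link{writeMatingPlan}}
#'
#' @param path CSV path.
#' @param capacity capacity to record on the plan (default: max observed
#'   sire usage).
#' @return a \linkS4class{MatingPlan}.
#' @export
readMatingPlan <- function(path, capacity = NULL) {
  df <- read.csv(path)
  if (is.null(capacity)) capacity <- max(table(df$sire))
  new("MatingPlan", sire = as.integer(df$sire), dam = as.integer(df$dam),
      nOffspring = as.integer(df$n_offspring),
      capacity = as.integer(capacity))
}

#' Write estimated marker effects as CSV
#'
#' Columns: marker id, chromosome, position (cM), effect, inclusion
#' probability - the table behind SNP-effect profile plots.
#'
#' @param effects a \linkS4class{MarkerEffects}.
#' @param map the \linkS4class{GenomeMap} the markers belong to.
#' @param path output CSV path.
#' @export
writeMarkerEffects <- function(effects, map, path) {
  mi <- markerIndex(map)
  df <- data.frame(marker = sprintf("%d_%s", map@chr[mi],
                                    format(map@pos[mi], trim = TRUE)),
                   chr = map@chr[mi], cM = map@pos[mi],
                   a = effects@a, inclusion_prob = effects@inclusionProb)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a relationship matrix as CSV
#'
#' @param rel a \linkS4class{RelationshipMatrix}.
#' @param path output CSV path.
#' @param long write long format (i, j, value) instead of a square matrix
#'   with id header.
#' @export
writeRelationshipMatrix <- function(rel, path, long = FALSE) {
  G <- relMatrix(rel)
  if (long) {
    idx <- which(upper.tri(G, diag = TRUE), arr.ind = TRUE)
    df <- data.frame(i = rownames(G)[idx[, 1]], j = colnames(G)[idx[, 2]],
                     value = G[idx])
    write.csv(df, path, row.names = FALSE)
  } else {
    write.csv(as.data.frame(G), path, row.names = TRUE)
  }
  invisible(path)
}
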