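#' Random mating of selected parents
#'
#' Dams are shuffled uniformly and dealt to sires in balanced blocks of
#' \code{capacity}, with no restriction on mating among siblings.
#'
#' @param sires,dams integer parent id vectors.
#' @param capacity maximum dams per sire (default 30).
#' @param nOffspring litter size per mating (default 10).
#' @return a \linkS4class{MatingPlan}.
#' @export
randomMating <- function(sires, dams, capacity = 30L, nOffspring = 10L) {
  if (length(dams) > length(sires) * capacity)
    stop("capacity infeasible: too many dams")
  d <- sample(dams)
  s <- rep(sires, each = capacity, length.out = length(d))
  new("MatingPlan", sire = as.integer(s), dam = as.integer(d),
      nOffspring = rep(as.integer(nOffspring), length(d)),
      capacity = as.integer(capacity))
}

# internal: blockwise pairing of ranked sires and dams
blockPlan <- function(sires, dams, capacity, nOffspring) {
  if (length(dams) > length(sires) * capacity)
    stop("capacity infeasible: too many dams")
  s <- rep(sires, each = capacity, length.out = length(dams))
  new("MatingPlan", sire = as.integer(s), dam = as.integer(dams),
      nOffspring = rep(as.integer(nOffspring), length(dams)),
      capacity = as.integer(capacity))
}

#' Positive assortative mating
#'
#' Sires and dams are both ranked by GEBV (descending, ties broken by id);
#' the rank-1 sire receives the top \code{capacity} dams, the rank-2 sire
#' the next block, and so on (rank-30 sire gets dams 871-900 at full
#' scale).
#'
#' @param sires,dams integer parent id vectors.
#' @param gebvs named numeric vector of GEBVs covering all parents.
#' @param capacity dams per sire (default 30).
#' @param nOffspring litter size per mating (default 10).
#' @return a \linkS4class{MatingPlan}.
#' @export
positiveAssortative <- function(sires, dams, gebvs, capacity = 30L,
                                nOffspring = 10L) {
  gs <- gebvs[as.character(sires)]; gd <- gebvs[as.character(dams)]
  if (anyNA(gs) || anyNA(gd)) stop("GEBV missing for some parents")
  blockPlan(sires[order(-gs, sires)], dams[order(-gd, dams)],
            capacity, nOffspring)
}

#' Negative assortative mating
#'
#' Sires ranked by GEBV ascending, dams descending: the best sire is mated
#' to the \code{capacity} lowest-ranking dams and the worst sire to the
#' \code{capacity} best dams.
#'
#' @inheritParams positiveAssortative
#' @return a \linkS4class{MatingPlan}.
#' @export
negativeAssortative <- function(sires, dams, gebvs, capacity = 30L,
                                nOffspring = 10L) {
  gs <- gebvs[as.character(sires)]; gd <- gebvs[as.character(dams)]
  if (anyNA(gs) || anyNA(gd)) stop("GEBV missing for some parents")
  blockPlan(sires[order(gs, sires)], dams[order(-gd, dams)],
            capacity, nOffspring)
}

#' Incidence matrix of a mating plan
#'
#' Rows are matings; each row holds 1/2 on its sire column and 1/2 on its
#' dam column, so row sums are 1 and \code{P \%*\% merit} gives midparent
#' merit per mating.
#'
#' @param plan a \linkS4class{MatingPlan}.
#' @param parentIds column order of the parents.
#' @return numeric matrix of dimension (matings x parents).
#' @export
incidenceMatrix <- function(plan, parentIds) {
  k <- length(plan@sire)
  P <- matrix(0, k, length(parentIds))
  si <- match(plan@sire, parentIds); di <- match(plan@dam, parentIds)
  if (anyNA(si) || anyNA(di)) stop("plan parent missing from parentIds")
  P[cbind(seq_len(k), si)] <- P[cbind(seq_len(k), si)] + 0.5
  P[cbind(seq_len(k), di)] <- P[cbind(seq_len(k), di)] + 0.5
  colnames(P) <- as.character(parentIds)
  P
}

#' Per-mating Mendelian sampling dispersion
#'
#' Linkage-free within-cross segregation variance of progeny merit:
#' \eqn{D_{kk} = \sum_j a_j^2 [het_s(j) + het_d(j)] / 4} over markers, where
#' \eqn{het_p(j)} indicates heterozygosity of parent p at marker j. A
#' parent's contribution separates, so the term is precomputed per parent.
#'
#' @param plan a \linkS4class{MatingPlan}.
#' @param pop phased \linkS4class{Population} holding the parents.
#' @param effects a \linkS4class{MarkerEffects} fit.
#' @return numeric vector \code{D_kk}, one entry per mating.
#' @export
mendelianDispersion <- function(plan, pop, effects) {
  load <- heterozygosityLoad(pop, effects)
  (load[as.character(plan@sire)] + load[as.character(plan@dam)]) / 4
}

# internal: per-parent sum of a_j^2 over heterozygous markers
heterozygosityLoad <- function(pop, effects) {
  mi <- markerIndex(pop@map)
  het <- (pop@hap1[, mi, drop = FALSE] != pop@hap2[, mi, drop = FALSE])
  setNames(as.numeric(het %*% effects@a[seq_along(mi)]^2),
           as.character(pop@id))
}

#' Evaluate the genomic-mating objectives of a plan
#'
#' \eqn{Gain(P) = 1' P G m} and
#' \eqn{Inbreeding(P) = 1'(P G P' + D) 1}, with \eqn{m = M a} the parents'
#' genomic merit vector and D the per-mating Mendelian sampling dispersion.
#'
#' @param plan a \linkS4class{MatingPlan}.
#' @param G a \linkS4class{RelationshipMatrix} (or plain symmetric matrix
#'   with ids as dimnames) over the parents.
#' @param merit named numeric vector of parent merits (\code{Ma}).
#' @param D per-mating dispersion vector (default all zero).
#' @return list with numeric scalars \code{gain} and \code{inbreeding}.
#' @export
evaluatePlan <- function(plan, G, merit, D = NULL) {
  Gm <- if (is(G, "RelationshipMatrix")) relMatrix(G) else G
  if (max(abs(Gm - t(Gm))) > 1e-8) stop("G must be symmetric")
  ids <- colnames(Gm)
  if (is.null(ids)) stop("G must carry parent ids as dimnames")
  P <- incidenceMatrix(plan, as.integer(ids))
  mv <- merit[ids]
  if (anyNA(mv)) stop("merit missing for some parents")
  if (is.null(D)) D <- rep(0, length(plan@sire))
  gm <- as.numeric(Gm %*% mv)
  gain <- sum(P %*% gm)
  u <- colSums(P)
  inbreeding <- as.numeric(t(u) %*% Gm %*% u) + sum(D)
  list(gain = gain, inbreeding = inbreeding)
}

# fast objective kernel used by the optimizer: everything is expressed
# through per-sire usage counts plus dam-side constants, because every dam
# occurs exactly once and P rows are (1/2, 1/2).
# assign: integer vector over dams, values 1..nSires
planObjectives <- function(assign, env) {
  cnt <- tabulate(assign, env$nS)
  u <- c(cnt, rep(1, env$nD)) / 2
  gain <- env$damGainConst + 0.5 * sum(cnt * env$gmS)
  inb <- as.numeric(t(u) %*% env$Gpar %*% u) +
    env$damLoadConst + sum(cnt * env$loadS) / 4
  c(gain, inb)
}

#' Optimize mate allocation over the gain/inbreeding frontier
#'
#' Hybrid genetic-algorithm / simulated-annealing search over feasible
#' dam-to-sire assignment vectors under a per-sire capacity constraint.
#' Each member of the GA population carries its own scalarization weight
#' \eqn{\lambda} (spread over [0, 1]), optimizing
#' \eqn{\lambda\,gain^* - (1-\lambda)\,inbreeding^*} on range-normalized
#' objectives; tournament selection (size 2), uniform crossover with
#' capacity repair, per-dam reassignment mutation at rate 1/nDams, and
#' simulated-annealing acceptance of non-improving mutants (geometric
#' temperature decay, T0 = 1, ratio 0.995). An elitist archive keeps every
#' nondominated (gain, inbreeding) plan found; its extremes are the
#' max-gain and min-inbreeding endpoint schemes.
#'
#' @param sires,dams integer parent ids.
#' @param G parent \linkS4class{RelationshipMatrix} (or matrix with id
#'   dimnames) covering all sires and dams.
#' @param merit named parent merit vector (\code{Ma}).
#' @param capacity maximum dams per sire.
#' @param hetLoad optional named per-parent Mendelian dispersion load (from
#'   \code{\link{heterozygosityLoad}}); \code{NULL} disables the D term.
#' @param gaPopSize GA population size (default 200).
#' @param nIter GA iterations (default 800).
#' @param nOffspring litter size recorded in returned plans (default 10).
#' @return a \linkS4class{MatingFrontier}.
#' @export
optimizeMating <- function(sires, dams, G, merit, capacity = 30L,
                           hetLoad = NULL, gaPopSize = 200L, nIter = 800L,
                           nOffspring = 10L) {
  nS <- length(sires); nD <- length(dams)
  if (gaPopSize < 2) stop("gaPopSize must be at least 2")
  if (nD > nS * capacity) stop("capacity infeasible: too many dams")
  Gm <- if (is(G, "RelationshipMatrix")) relMatrix(G) else G
  ids <- as.integer(colnames(Gm))
  ord <- match(c(sires, dams), ids)
  if (anyNA(ord)) stop("G must cover all parents")
  Gpar <- Gm[ord, ord]
  mv <- merit[as.character(c(sires, dams))]
  if (anyNA(mv)) stop("merit missing for some parents")
  gmAll <- as.numeric(Gpar %*% mv)
  if (is.null(hetLoad)) hetLoad <- setNames(rep(0, nS + nD),
                                            as.character(c(sires, dams)))
  loadAll <- hetLoad[as.character(c(sires, dams))]
  env <- list2env(list(
    nS = nS, nD = nD, Gpar = Gpar,
    gmS = gmAll[seq_len(nS)],
    damGainConst = 0.5 * sum(gmAll[nS + seq_len(nD)]),
    loadS = as.numeric(loadAll[seq_len(nS)]),
    damLoadConst = sum(loadAll[nS + seq_len(nD)]) / 4))

  randomAssign <- function() {
    pool <- sample(rep(seq_len(nS), capacity))
    pool[seq_len(nD)]
  }
  repair <- function(a) {
    cnt <- tabulate(a, nS)
    over <- which(cnt > capacity)
    for (s in over) {
      idx <- which(a == s)
      excess <- sample(idx, cnt[s] - capacity)
      for (i in excess) {
        free <- which(tabulate(a, nS) < capacity)
        a[i] <- if (length(free) > 1) sample(free, 1) else free
      }
    }
    a
  }
  mutate <- function(a) {
    flip <- which(runif(nD) < 1 / nD)
    for (i in flip) {
      cnt <- tabulate(a, nS)
      cnt[a[i]] <- cnt[a[i]] - 1L
      free <- which(cnt < capacity)
      a[i] <- if (length(free) > 1) sample(free, 1) else free
    }
    a
  }

  popA <- replicate(gaPopSize, randomAssign(), simplify = FALSE)
  obj <- t(vapply(popA, planObjectives, numeric(2), env = env))
  lambda <- seq(0, 1, length.out = gaPopSize)

  # nondominated archive (gain max, inbreeding min)
  archA <- list(); archObj <- matrix(numeric(0), 0, 2)
  pushArchive <- function(a, o) {
    if (nrow(archObj)) {
      dominated <- any(archObj[, 1] >= o[1] - 1e-12 &
                       archObj[, 2] <= o[2] + 1e-12 &
                       (archObj[, 1] > o[1] + 1e-12 |
                        archObj[, 2] < o[2] - 1e-12))
      if (dominated) return(invisible())
      dup <- any(abs(archObj[, 1] - o[1]) <= 1e-12 &
                 abs(archObj[, 2] - o[2]) <= 1e-12)
      if (dup) return(invisible())
      keep <- !(o[1] >= archObj[, 1] - 1e-12 & o[2] <= archObj[, 2] + 1e-12 &
                (o[1] > archObj[, 1] + 1e-12 | o[2] < archObj[, 2] - 1e-12))
      archA <<- archA[keep]; archObj <<- archObj[keep, , drop = FALSE]
    }
    archA[[length(archA) + 1L]] <<- a
    archObj <<- rbind(archObj, o)
    invisible()
  }
  for (i in seq_len(gaPopSize)) pushArchive(popA[[i]], obj[i, ])

  scal <- function(o, lam, rg) {
    gn <- (o[1] - rg[1]) / max(rg[2] - rg[1], 1e-12)
    ib <- (o[2] - rg[3]) / max(rg[4] - rg[3], 1e-12)
    lam * gn - (1 - lam) * ib
  }

  temp <- 1
  for (it in seq_len(nIter)) {
    rg <- c(min(obj[, 1]), max(obj[, 1]), min(obj[, 2]), max(obj[, 2]))
    newPop <- vector("list", gaPopSize)
    newObj <- matrix(0, gaPopSize, 2)
    for (i in seq_len(gaPopSize)) {
      lam <- lambda[i]
      pickParent <- function() {
        c2 <- sample.int(gaPopSize, 2)
        sc <- c(scal(obj[c2[1], ], lam, rg), scal(obj[c2[2], ], lam, rg))
        c2[which.max(sc)]
      }
      p1 <- popA[[pickParent()]]; p2 <- popA[[pickParent()]]
      mask <- runif(nD) < 0.5
      child <- ifelse(mask, p1, p2)
      child <- repair(child)
      child <- mutate(child)
      co <- planObjectives(child, env)
      pushArchive(child, co)
      # SA acceptance against the current slot holder
      cur <- scal(obj[i, ], lam, rg); cand <- scal(co, lam, rg)
      if (cand >= cur || runif(1) < exp((cand - cur) / temp)) {
        newPop[[i]] <- child; newObj[i, ] <- co
      } else {
        newPop[[i]] <- popA[[i]]; newObj[i, ] <- obj[i, ]
      }
    }
    popA <- newPop; obj <- newObj
    temp <- temp * 0.995
  }

  toPlan <- function(a) new("MatingPlan", sire = as.integer(sires[a]),
                            dam = as.integer(dams),
                            nOffspring = rep(as.integer(nOffspring), nD),
                            capacity = as.integer(capacity))
  dimnames(archObj) <- NULL
  o <- order(archObj[, 1])
  plans <- lapply(archA[o], toPlan)
  gain <- archObj[o, 1]; inb <- archObj[o, 2]
  new("MatingFrontier", gain = gain, inbreeding = inb, plans = plans,
      maxGain = which.max(gain), minInbreeding = which.min(inb))
}
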