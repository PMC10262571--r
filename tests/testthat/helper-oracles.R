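# Independent oracles used against the package implementations.

# Wright path-counting inbreeding for small pedigrees.
# ped: data.frame(id, sire, dam), NA for unknown parents.
pathCountingF <- function(ped) {
  getPar <- function(id) {
    r <- ped[ped$id == id, ]
    c(sire = r$sire, dam = r$dam)
  }
  # all ascending paths from x (vectors of ids, starting at x)
  allPaths <- function(x) {
    out <- list(c(x))
    for (p in getPar(x)) {
      if (!is.na(p)) for (pp in allPaths(p)) out <- c(out, list(c(x, pp)))
    }
    out
  }
  Fmemo <- new.env()
  Fof <- function(id) {
    key <- as.character(id)
    if (!is.null(Fmemo[[key]])) return(Fmemo[[key]])
    par <- getPar(id)
    if (anyNA(par)) { Fmemo[[key]] <- 0; return(0) }
    ps <- allPaths(par[["sire"]]); pd <- allPaths(par[["dam"]])
    tot <- 0
    for (P1 in ps) for (P2 in pd) {
      A1 <- P1[length(P1)]; A2 <- P2[length(P2)]
      if (A1 != A2) next
      # the two path legs may share only the common ancestor
      if (length(intersect(P1[-length(P1)], P2[-length(P2)])) > 0) next
      n <- length(P1) + length(P2) - 1  # individuals in the chain
      tot <- tot + 0.5^n * (1 + Fof(A1))
    }
    Fmemo[[key]] <- tot
    tot
  }
  setNames(vapply(ped$id, Fof, numeric(1)), as.character(ped$id))
}

# Exhaustive enumeration of all capacity-feasible dam-to-sire assignments;
# returns the attainable objective extremes.
enumeratePlans <- function(sires, dams, G, merit, capacity, hetLoad = NULL) {
  nS <- length(sires); nD <- length(dams)
  grid <- as.matrix(expand.grid(rep(list(seq_len(nS)), nD)))
  gains <- c(); inbs <- c()
  for (r in seq_len(nrow(grid))) {
    a <- grid[r, ]
    if (max(tabulate(a, nS)) > capacity) next
    plan <- new("MatingPlan", sire = as.integer(sires[a]),
                dam = as.integer(dams),
                nOffspring = rep(1L, nD), capacity = as.integer(capacity))
    D <- if (is.null(hetLoad)) NULL else
      (hetLoad[as.character(sires[a])] + hetLoad[as.character(dams)]) / 4
    o <- evaluatePlan(plan, G, merit, D)
    gains <- c(gains, o$gain); inbs <- c(inbs, o$inbreeding)
  }
  list(maxGain = max(gains), minInbreeding = min(inbs))
}

# random positive-definite relationship-like matrix with id dimnames
randomGLike <- function(n, ids = seq_len(n)) {
  A <- matrix(rnorm(n * 5), n)
  G <- tcrossprod(A) / 5 + diag(n)
  dimnames(G) <- list(ids, ids)
  G
}
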