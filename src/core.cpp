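#include <Rcpp.h>
using namespace Rcpp;

// Gamete sampling under the Haldane map: locus 1 of each chromosome starts
// from a random parental haplotype (u < 0.5 -> paternal), every later locus
// switches source iff an independent uniform draw falls below the adjacent
// recombination fraction r[j]. Uses R's RNG so results follow set.seed().
//
// hap1/hap2: nParents x nLoci 0/1 matrices (paternal / maternal strand).
// r:        per-locus adjacent recombination fraction (ignored at chrFirst).
// chrFirst: TRUE where a locus is the first of its chromosome.
// parents:  0-based row index into hap1/hap2, one per requested gamete.
// [[Rcpp::export]]
IntegerMatrix cpp_sample_gametes(const IntegerMatrix& hap1,
                                 const IntegerMatrix& hap2,
                                 const NumericVector& r,
                                 const LogicalVector& chrFirst,
                                 const IntegerVector& parents) {
  const int L = hap1.ncol(), nG = parents.size();
  if (hap2.ncol() != L || r.size() != L || chrFirst.size() != L)
    stop("haplotype/map length mismatch");
  IntegerMatrix out(nG, L);
  for (int g = 0; g < nG; ++g) {
    const int p = parents[g];
    if (p < 0 || p >= hap1.nrow()) stop("parent index out of range");
    int src = 0;
    for (int j = 0; j < L; ++j) {
      if (chrFirst[j]) {
        src = (unif_rand() < 0.5) ? 0 : 1;
      } else if (unif_rand() < r[j]) {
        src = 1 - src;
      }
      out(g, j) = (src == 0) ? hap1(p, j) : hap2(p, j);
    }
  }
  return out;
}

// BayesB Gibbs sampler with a per-marker mixture prior: with probability pi0
// the effect is exactly zero, otherwise it carries its own variance with a
// scaled-inverse-chi-square prior (nu, S2). Marker variances are kept in the
// chain state (sampled from the prior while the marker is excluded) so the
// inclusion indicator has a proper full conditional. Residual variance gets
// a scaled-inv-chi-square (nuE, Se2) prior.
// [[Rcpp::export]]
List cpp_bayesb(const NumericMatrix& X, const NumericVector& y,
                int nIter, int burnIn, int thin,
                double pi0, double nu, double S2,
                double nuE, double Se2) {
  const int n = X.nrow(), m = X.ncol();
  if (y.size() != n) stop("dim mismatch");
  if (nIter <= burnIn) stop("nIter must exceed burnIn");

  std::vector<double> xtx(m), a(m, 0.0), sumA(m, 0.0), sumIn(m, 0.0);
  const double* Xp = X.begin();  // column-major
  for (int j = 0; j < m; ++j) {
    const double* xj = Xp + (size_t)j * n;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
    xtx[j] = s;
  }

  double mu = mean(y);
  double varE = var(y);
  if (varE <= 0) varE = Se2 > 0 ? Se2 : 1.0;
  std::vector<double> ycorr(n);
  for (int i = 0; i < n; ++i) ycorr[i] = y[i] - mu;

  double sumMu = 0.0, sumVarE = 0.0;
  int nKept = 0;
  const double logPriorOdds = std::log((1.0 - pi0) / pi0);

  for (int it = 1; it <= nIter; ++it) {
    // intercept
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += ycorr[i];
    double muNew = mu + s / n + norm_rand() * std::sqrt(varE / n);
    double dmu = muNew - mu;
    for (int i = 0; i < n; ++i) ycorr[i] -= dmu;
    mu = muNew;

    for (int j = 0; j < m; ++j) {
      if (xtx[j] <= 0.0) continue;  // monomorphic: effect pinned at 0
      const double* xj = Xp + (size_t)j * n;
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += xj[i] * ycorr[i];
      rhs += xtx[j] * a[j];
      // marker variance: posterior if currently in the model, prior if not
      double sj2;
      if (a[j] != 0.0)
        sj2 = (S2 * nu + a[j] * a[j]) / R::rchisq(nu + 1.0);
      else
        sj2 = S2 * nu / R::rchisq(nu);
      const double v0 = xtx[j] * varE;
      const double v1 = xtx[j] * xtx[j] * sj2 + xtx[j] * varE;
      const double logOdds = logPriorOdds +
        0.5 * (std::log(v0 / v1) + rhs * rhs * (1.0 / v0 - 1.0 / v1));
      const double pIn = 1.0 / (1.0 + std::exp(-logOdds));
      const bool in = (unif_rand() < pIn);
      double aNew = 0.0;
      if (in) {
        const double C = xtx[j] + varE / sj2;
        aNew = rhs / C + norm_rand() * std::sqrt(varE / C);
      }
      if (aNew != a[j]) {
        const double d = a[j] - aNew;
        for (int i = 0; i < n; ++i) ycorr[i] += xj[i] * d;
        a[j] = aNew;
      }
      if (it > burnIn && ((it - burnIn) % thin == 0) && in) sumIn[j] += 1.0;
    }

    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += ycorr[i] * ycorr[i];
    varE = (sse + nuE * Se2) / R::rchisq((double)n + nuE);

    if (it > burnIn && ((it - burnIn) % thin == 0)) {
      ++nKept;
      for (int j = 0; j < m; ++j) sumA[j] += a[j];
      sumMu += mu;
      sumVarE += varE;
    }
  }

  NumericVector postA(m), postIn(m);
  for (int j = 0; j < m; ++j) {
    postA[j] = sumA[j] / nKept;
    postIn[j] = sumIn[j] / nKept;
  }
  return List::create(_["a"] = postA, _["inclusionProb"] = postIn,
                      _["intercept"] = sumMu / nKept,
                      _["varE"] = sumVarE / nKept, _["nKept"] = nKept);
}

// Shared-segment (ROH/IBD) kinship from phased haplotypes. H holds two rows
// per individual (2i, 2i+1). For each ordered haplotype pair the genetic
// length of maximal identical stretches passing both thresholds is summed;
// kinship is the mean over the four pairs divided by the assayable map
// length (sum over chromosomes of last - first locus position). Diagonals
// use an individual's own two haplotypes, so full autozygosity gives f = 1.
// [[Rcpp::export]]
NumericMatrix cpp_segment_kinship(const IntegerMatrix& H,
                                  const NumericVector& pos,
                                  const IntegerVector& chr,
                                  double minLen, int minMarkers) {
  const int L = H.ncol(), nInd = H.nrow() / 2;
  if (H.nrow() % 2 != 0) stop("H must have two rows per individual");
  if (pos.size() != L || chr.size() != L) stop("map length mismatch");

  // chromosome boundaries (loci assumed grouped by chromosome)
  std::vector<int> starts, ends;
  double totLen = 0.0;
  for (int j = 0; j < L; ++j) {
    if (j == 0 || chr[j] != chr[j - 1]) starts.push_back(j);
    if (j == L - 1 || chr[j + 1] != chr[j]) ends.push_back(j);
  }
  for (size_t c = 0; c < starts.size(); ++c)
    totLen += pos[ends[c]] - pos[starts[c]];
  if (totLen <= 0) stop("map has no extent");

  // shared qualified length between two haplotype rows
  auto sharedLen = [&](int ra, int rb) -> double {
    double tot = 0.0;
    for (size_t c = 0; c < starts.size(); ++c) {
      int j = starts[c];
      const int e = ends[c];
      while (j <= e) {
        if (H(ra, j) != H(rb, j)) { ++j; continue; }
        int k = j;
        while (k < e && H(ra, k + 1) == H(rb, k + 1)) ++k;
        const double len = pos[k] - pos[j];
        if ((k - j + 1) >= minMarkers && len >= minLen) tot += len;
        j = k + 1;
      }
    }
    return tot;
  };

  NumericMatrix f(nInd, nInd);
  for (int i = 0; i < nInd; ++i) {
    for (int j2 = i; j2 < nInd; ++j2) {
      double s;
      if (i == j2) {
        // (h1,h1) and (h2,h2) are self pairs spanning the whole map
        s = 2.0 * totLen + 2.0 * sharedLen(2 * i, 2 * i + 1);
      } else {
        s = sharedLen(2 * i, 2 * j2) + sharedLen(2 * i, 2 * j2 + 1) +
            sharedLen(2 * i + 1, 2 * j2) + sharedLen(2 * i + 1, 2 * j2 + 1);
      }
      const double v = 0.25 * s / totLen;
      f(i, j2) = v;
      f(j2, i) = v;
    }
  }
  return f;
}

// Pedigree inbreeding by the tabular (recursive additive relationship)
// method. sire/dam are 1-based indices into the individual vector, 0 for
// unknown; individuals must be ordered parents-before-offspring.
// [[Rcpp::export]]
NumericVector cpp_fped(const IntegerVector& sire, const IntegerVector& dam) {
  const int n = sire.size();
  if (dam.size() != n) stop("sire/dam length mismatch");
  std::vector<double> A((size_t)n * n, 0.0);
  NumericVector F(n);
  for (int i = 0; i < n; ++i) {
    const int s = sire[i] - 1, d = dam[i] - 1;
    if (s >= i || d >= i) stop("individual listed before its parents");
    for (int j = 0; j < i; ++j) {
      double v = 0.0;
      if (s >= 0) v += 0.5 * A[(size_t)j * n + s];
      if (d >= 0) v += 0.5 * A[(size_t)j * n + d];
      A[(size_t)j * n + i] = v;
      A[(size_t)i * n + j] = v;
    }
    double aii = 1.0;
    if (s >= 0 && d >= 0) aii += 0.5 * A[(size_t)s * n + d];
    A[(size_t)i * n + i] = aii;
    F[i] = aii - 1.0;
  }
  return F;
}
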