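// Network-free stochastic simulation of the holoenzyme model.
//
// Discrete agents: CaM molecules (lobe Ca counts, Ng flag, subunit bond),
// CaMKII subunits arranged as two independent hexameric rings per
// holoenzyme (kinase at ring position i targets position i+1 mod 6),
// free Ng, free PP1 and an integer free-Ca pool.  Exact SSA over aggregated
// channels; the time-inhomogeneous pulse-influx channel is simulated by
// thinning against a rigorous envelope bound.  All randomness comes from
// R's RNG so set.seed() makes runs reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct ClassList {
  std::vector<int> ids;
  void add(int id, std::vector<int>& pos) {
    pos[id] = (int)ids.size();
    ids.push_back(id);
  }
  void remove(int id, std::vector<int>& pos) {
    int p = pos[id];
    int last = ids.back();
    ids[p] = last;
    pos[last] = p;
    ids.pop_back();
    pos[id] = -1;
  }
  int size() const { return (int)ids.size(); }
  int pick(double u) const {
    int k = (int)(u * ids.size());
    if (k >= (int)ids.size()) k = (int)ids.size() - 1;
    return ids[k];
  }
};

inline double rexp_unit() {
  double u = unif_rand();
  if (u <= 0.0) u = 1e-300;
  return -std::log(u);
}

inline int ipick(double u, int n) {
  int k = (int)(u * n);
  return (k >= n) ? n - 1 : k;
}

} // namespace

// [[Rcpp::export(name = ".ssaRunCpp")]]
List ssaRunCpp(IntegerVector camC0, IntegerVector camN0, IntegerVector camNg0,
               IntegerVector camSub0, IntegerVector subP0,
               IntegerVector subCam0, IntegerVector subPP10,
               int freeNg0, int freePP10, int nCa0,
               NumericVector rates, double molPerUM,
               double ke, double baselineCa,
               NumericVector onsets, double A_uM, double tauR, double tauF,
               double influxBound_uM,
               double tStart, double tEnd, double recordStart,
               double recordDt, bool clampCa, bool audit) {

  const int nCaM = camC0.size();
  const int nSub = subP0.size();
  if (nSub % 12 != 0) stop("subunit count must be a multiple of 12");

  // --- rate constants (bimolecular ones converted to per-pair rates) ---
  auto R = [&](const char* nm) -> double {
    if (!rates.containsElementNamed(nm)) stop("missing rate: %s", nm);
    return as<double>(rates[nm]);
  };
  const double om = molPerUM;
  double konC[2]  = { R("kon1C") / om, R("kon2C") / om };
  double koffC[2] = { R("koff1C"), R("koff2C") };
  double konN[2]  = { R("kon1N") / om, R("kon2N") / om };
  double koffN[2] = { R("koff1N"), R("koff2N") };
  double konKC[2]  = { R("konK1C") / om, R("konK2C") / om };
  double koffKC[2] = { R("koffK1C"), R("koffK2C") };
  double konKN[2]  = { R("konK1N") / om, R("konK2N") / om };
  double koffKN[2] = { R("koffK1N"), R("koffK2N") };
  const char* suff[3][3] = { {"0",  "1N", "2N"},
                             {"1C", "1C1N", "1C2N"},
                             {"2C", "2C1N", "4"} };
  double konCaM[3][3], koffCaM[3][3], kponCaM[3][3], kp[3][3];
  for (int c = 0; c < 3; ++c)
    for (int n = 0; n < 3; ++n) {
      std::string s(suff[c][n]);
      konCaM[c][n]  = R(("konCaM" + s).c_str()) / om;
      koffCaM[c][n] = R(("koffCaM" + s).c_str());
      kponCaM[c][n] = R(("kponCaM" + s).c_str()) / om;
      kp[c][n] = (c + n >= 1) ? R(("kpCaM" + s).c_str()) : 0.0;
    }
  const double kpoffCaM = R("kpoffCaM");
  const double konNg = R("konNg") / om, koffNg = R("koffNg");
  const double konPP1 = R("konPP1") / om;
  const double koffPP1 = R("konPP1") * R("Km") - R("kcat");
  const double kcat = R("kcat");
  if (koffPP1 <= 0) stop("konPP1 too small for Km/kcat");

  // --- mutable agent state ---
  std::vector<int> camC(camC0.begin(), camC0.end());
  std::vector<int> camN(camN0.begin(), camN0.end());
  std::vector<int> camNg(camNg0.begin(), camNg0.end());
  std::vector<int> camSub(camSub0.begin(), camSub0.end());
  std::vector<int> subP(subP0.begin(), subP0.end());
  std::vector<int> subCam(subCam0.begin(), subCam0.end());
  std::vector<int> subPP1(subPP10.begin(), subPP10.end());
  int freeNg = freeNg0, freePP1 = freePP10, nCa = nCa0;

  // --- class lists ---
  ClassList freeCam[3][3], boundU[3][3], boundP[3][3], ngCams;
  std::vector<int> camPos(nCaM, -1);
  ClassList freeU, freeP, elig, pp1b;
  std::vector<int> subPosFree(nSub, -1), subPosElig(nSub, -1),
      subPosPP1(nSub, -1);

  auto camClassAdd = [&](int i) {
    if (camNg[i]) ngCams.add(i, camPos);
    else if (camSub[i] < 0) freeCam[camC[i]][camN[i]].add(i, camPos);
    else if (subP[camSub[i]]) boundP[camC[i]][camN[i]].add(i, camPos);
    else boundU[camC[i]][camN[i]].add(i, camPos);
  };
  auto camClassRemove = [&](int i) {
    if (camNg[i]) ngCams.remove(i, camPos);
    else if (camSub[i] < 0) freeCam[camC[i]][camN[i]].remove(i, camPos);
    else if (subP[camSub[i]]) boundP[camC[i]][camN[i]].remove(i, camPos);
    else boundU[camC[i]][camN[i]].remove(i, camPos);
  };
  for (int i = 0; i < nCaM; ++i) camClassAdd(i);

  int nPsub = 0, nBoundSub = 0, nBoundUSub = 0;
  for (int j = 0; j < nSub; ++j) {
    if (subP[j]) ++nPsub;
    if (subCam[j] >= 0) {
      ++nBoundSub;
      if (!subP[j]) ++nBoundUSub;
    } else {
      if (subP[j]) freeP.add(j, subPosFree);
      else freeU.add(j, subPosFree);
    }
    if (subP[j] && !subPP1[j]) elig.add(j, subPosElig);
    if (subPP1[j]) pp1b.add(j, subPosPP1);
  }

  // --- neighbour map: kinase at (ring, i) targets (ring, i+1 mod 6) ---
  auto kinaseOf = [](int j) {
    int h = j / 12, r = (j % 12) / 6, p = j % 6;
    return h * 12 + r * 6 + (p + 5) % 6;
  };
  auto succOf = [](int j) {
    int h = j / 12, r = (j % 12) / 6, p = j % 6;
    return h * 12 + r * 6 + (p + 1) % 6;
  };

  // --- per-subunit phosphorylation propensity ---
  std::vector<double> phosProp(nSub, 0.0);
  double phosTotal = 0.0;
  auto recomputeSub = [&](int j) {
    double nw = 0.0;
    if (!subP[j] && subCam[j] >= 0) {
      int cm = subCam[j];
      if (camC[cm] + camN[cm] >= 1) {
        int k = kinaseOf(j);
        if (subP[k] || subCam[k] >= 0) nw = kp[camC[cm]][camN[cm]];
      }
    }
    phosTotal += nw - phosProp[j];
    phosProp[j] = nw;
  };
  for (int j = 0; j < nSub; ++j) recomputeSub(j);

  // --- influx ---
  const double j0 = clampCa ? 0.0 : ke * baselineCa * om;      // molecules/s
  const double A_mol = A_uM * om;
  const double pulseBound = influxBound_uM * om;
  const int nPulse = onsets.size();
  auto pulseRate = [&](double t) {
    double s = 0.0;
    for (int k = nPulse - 1; k >= 0; --k) {
      double dt = t - onsets[k];
      if (dt < 0) continue;
      s += A_mol * (dt / tauR) * std::exp(-dt / tauF);
      if (dt > 60.0 * tauF) break;  // onsets increasing: older ones negligible
    }
    return s;
  };
  // Piecewise-constant thinning bound: near a pulse onset (age < 2 tauF) the
  // single-pulse peak plus decayed-tail bound applies; past 2 tauF the
  // envelope is decreasing, so its value at the segment start bounds the
  // segment.  validUntil marks where the bound changes (segment end or next
  // onset), and the main loop jumps there without an event if tau overshoots.
  int pulseIdx = 0;
  auto pulseBoundAt = [&](double t, double& validUntil) {
    if (nPulse == 0 || clampCa) { validUntil = R_PosInf; return 0.0; }
    if (t < onsets[0]) { validUntil = onsets[0]; return 0.0; }
    while (pulseIdx + 1 < nPulse && onsets[pulseIdx + 1] <= t) ++pulseIdx;
    double dt = t - onsets[pulseIdx];
    double nextOn = (pulseIdx + 1 < nPulse) ? onsets[pulseIdx + 1] : R_PosInf;
    double b, vu;
    if (dt < 2.0 * tauF) {
      b = pulseBound;
      vu = onsets[pulseIdx] + 2.0 * tauF;
    } else {
      double segStart = onsets[pulseIdx] + std::floor(dt / tauF) * tauF;
      b = pulseRate(segStart);
      vu = segStart + tauF;
    }
    if (b < 1e-9) { b = 0.0; vu = nextOn; }
    validUntil = std::min(vu, nextOn);
    // guard against landing exactly on a segment boundary (float rounding):
    // the envelope is decreasing there, so extending the segment keeps the
    // bound valid
    if (validUntil <= t) validUntil = std::min(t + tauF, nextOn);
    if (validUntil <= t) validUntil = t + tauF;
    return b;
  };

  // --- recording ---
  int nRec = (int)std::floor((tEnd - recordStart) / recordDt + 1e-9) + 1;
  NumericVector recTime(nRec);
  NumericMatrix obs(nRec, 7);
  colnames(obs) = CharacterVector::create("pSub", "camBound", "camBoundU",
                                          "freeCa", "camNg", "freeCaM",
                                          "pp1Bound");
  int iRec = 0;
  auto record = [&](double tr) {
    if (iRec >= nRec) return;
    recTime[iRec] = tr;
    int nFreeCam = 0;
    for (int c = 0; c < 3; ++c)
      for (int n = 0; n < 3; ++n) nFreeCam += freeCam[c][n].size();
    obs(iRec, 0) = nPsub / om;
    obs(iRec, 1) = nBoundSub / om;
    obs(iRec, 2) = nBoundUSub / om;
    obs(iRec, 3) = nCa / om;
    obs(iRec, 4) = ngCams.size() / om;
    obs(iRec, 5) = nFreeCam / om;
    obs(iRec, 6) = pp1b.size() / om;
    ++iRec;
  };

  int totNg0 = freeNg0, totPP10 = freePP10;
  for (int i = 0; i < nCaM; ++i) totNg0 += camNg0[i];
  for (int j = 0; j < nSub; ++j) totPP10 += subPP10[j];
  auto auditCheck = [&](double t) {
    int tot = ngCams.size();
    for (int c = 0; c < 3; ++c)
      for (int n = 0; n < 3; ++n)
        tot += freeCam[c][n].size() + boundU[c][n].size() + boundP[c][n].size();
    if (tot != nCaM) stop("audit: CaM count drifted at t=%g", t);
    int np = 0, nb = 0, nbu = 0;
    for (int j = 0; j < nSub; ++j) {
      if (subP[j]) ++np;
      if (subCam[j] >= 0) { ++nb; if (!subP[j]) ++nbu; }
      if (subPP1[j] && !subP[j]) stop("audit: PP1 bound to U subunit");
      if (subCam[j] >= 0 && camSub[subCam[j]] != j)
        stop("audit: subunit/CaM bond inconsistent");
    }
    if (np != nPsub || nb != nBoundSub || nbu != nBoundUSub)
      stop("audit: subunit counters drifted at t=%g", t);
    if (freePP1 + (int)pp1b.size() != totPP10)
      stop("audit: PP1 count drifted at t=%g", t);
    if (freeNg + ngCams.size() != totNg0)
      stop("audit: Ng count drifted at t=%g", t);
  };

  double t = tStart;
  double nextRec = recordStart;
  double peakCa = 0.0;
  long long nEvents = 0, phosEvents = 0;
  std::vector<double> evCount(16, 0.0); // per-family event tally

  const int NCH = 85;
  std::vector<double> a(NCH);

  while (true) {
    // ---- propensities ----
    int ch = 0;
    for (int c = 0; c < 2; ++c)            // Ca on free CaM, C lobe
      for (int n = 0; n < 3; ++n)
        a[ch++] = konC[c] * nCa * freeCam[c][n].size();
    for (int n = 0; n < 2; ++n)            // Ca on free CaM, N lobe
      for (int c = 0; c < 3; ++c)
        a[ch++] = konN[n] * nCa * freeCam[c][n].size();
    for (int c = 1; c < 3; ++c)            // Ca off free CaM, C lobe
      for (int n = 0; n < 3; ++n)
        a[ch++] = koffC[c - 1] * freeCam[c][n].size();
    for (int n = 1; n < 3; ++n)
      for (int c = 0; c < 3; ++c)
        a[ch++] = koffN[n - 1] * freeCam[c][n].size();
    for (int c = 0; c < 2; ++c)            // Ca on subunit-bound CaM
      for (int n = 0; n < 3; ++n)
        a[ch++] = konKC[c] * nCa * (boundU[c][n].size() + boundP[c][n].size());
    for (int n = 0; n < 2; ++n)
      for (int c = 0; c < 3; ++c)
        a[ch++] = konKN[n] * nCa * (boundU[c][n].size() + boundP[c][n].size());
    for (int c = 1; c < 3; ++c)            // Ca off subunit-bound CaM
      for (int n = 0; n < 3; ++n)
        a[ch++] = koffKC[c - 1] * (boundU[c][n].size() + boundP[c][n].size());
    for (int n = 1; n < 3; ++n)
      for (int c = 0; c < 3; ++c)
        a[ch++] = koffKN[n - 1] * (boundU[c][n].size() + boundP[c][n].size());
    a[ch++] = konNg * freeNg * freeCam[0][0].size();      // 48
    a[ch++] = koffNg * ngCams.size();                     // 49
    for (int c = 0; c < 3; ++c)            // CaM binding to U subunits
      for (int n = 0; n < 3; ++n)
        a[ch++] = konCaM[c][n] * freeCam[c][n].size() * freeU.size();
    for (int c = 0; c < 3; ++c)            // CaM binding to P subunits
      for (int n = 0; n < 3; ++n)
        a[ch++] = kponCaM[c][n] * freeCam[c][n].size() * freeP.size();
    for (int c = 0; c < 3; ++c)            // CaM unbinding from U subunits
      for (int n = 0; n < 3; ++n)
        a[ch++] = koffCaM[c][n] * boundU[c][n].size();
    {
      int nbp = 0;
      for (int c = 0; c < 3; ++c)
        for (int n = 0; n < 3; ++n) nbp += boundP[c][n].size();
      a[ch++] = kpoffCaM * nbp;                           // 77
    }
    a[ch++] = konPP1 * freePP1 * elig.size();             // 78
    a[ch++] = koffPP1 * pp1b.size();                      // 79
    a[ch++] = kcat * pp1b.size();                         // 80
    a[ch++] = phosTotal > 0 ? phosTotal : 0.0;            // 81
    a[ch++] = clampCa ? 0.0 : ke * nCa;                   // 82
    a[ch++] = j0;                                         // 83
    double validUntil;
    double curBound = pulseBoundAt(t, validUntil);
    a[ch++] = curBound;                                   // 84

    double total = 0.0;
    for (int i = 0; i < NCH; ++i) total += a[i];
    double tau = (total > 0) ? rexp_unit() / total : R_PosInf;
    double tNew = t + tau;

    if (tNew > validUntil && validUntil < tEnd) {
      // thinning bound changes before the tentative event: jump, no event
      while (nextRec <= validUntil + 1e-12 && iRec < nRec) {
        record(nextRec);
        nextRec += recordDt;
      }
      t = validUntil;
      continue;
    }
    while (nextRec <= tNew + 1e-12 && iRec < nRec) {
      record(nextRec);
      nextRec += recordDt;
    }
    if (tNew >= tEnd || !R_FINITE(tNew)) break;
    t = tNew;

    // ---- select channel ----
    double r = unif_rand() * total;
    int sel = 0;
    for (; sel < NCH - 1; ++sel) {
      if (r < a[sel]) break;
      r -= a[sel];
    }

    ++nEvents;
    if ((nEvents & 0xFFFF) == 0) {  // refresh against float drift
      phosTotal = 0.0;
      for (int j = 0; j < nSub; ++j) phosTotal += phosProp[j];
      if (audit) auditCheck(t);
    }

    if (sel < 6) {                       // Ca + free CaM (C lobe)
      int c = sel / 3, n = sel % 3;
      int i = freeCam[c][n].pick(unif_rand());
      camClassRemove(i); camC[i] = c + 1; camClassAdd(i);
      if (!clampCa) --nCa;
      evCount[0] += 1;
    } else if (sel < 12) {               // Ca + free CaM (N lobe)
      int k = sel - 6, n = k / 3, c = k % 3;
      int i = freeCam[c][n].pick(unif_rand());
      camClassRemove(i); camN[i] = n + 1; camClassAdd(i);
      if (!clampCa) --nCa;
      evCount[0] += 1;
    } else if (sel < 18) {               // Ca off free CaM (C lobe)
      int k = sel - 12, c = k / 3 + 1, n = k % 3;
      int i = freeCam[c][n].pick(unif_rand());
      camClassRemove(i); camC[i] = c - 1; camClassAdd(i);
      if (!clampCa) ++nCa;
      evCount[1] += 1;
    } else if (sel < 24) {
      int k = sel - 18, n = k / 3 + 1, c = k % 3;
      int i = freeCam[c][n].pick(unif_rand());
      camClassRemove(i); camN[i] = n - 1; camClassAdd(i);
      if (!clampCa) ++nCa;
      evCount[1] += 1;
    } else if (sel < 48) {               // Ca on/off subunit-bound CaM
      int k = sel - 24;
      int c, n, dc = 0, dn = 0;
      if (k < 6) { c = k / 3; n = k % 3; dc = 1; }
      else if (k < 12) { k -= 6; n = k / 3; c = k % 3; dn = 1; }
      else if (k < 18) { k -= 12; c = k / 3 + 1; n = k % 3; dc = -1; }
      else { k -= 18; n = k / 3 + 1; c = k % 3; dn = -1; }
      int szU = boundU[c][n].size(), szP = boundP[c][n].size();
      int pickIdx = ipick(unif_rand(), szU + szP);
      int i = (pickIdx < szU) ? boundU[c][n].ids[pickIdx]
                              : boundP[c][n].ids[pickIdx - szU];
      camClassRemove(i); camC[i] += dc; camN[i] += dn; camClassAdd(i);
      if (!clampCa) nCa -= (dc + dn);
      recomputeSub(camSub[i]);
      evCount[dc + dn > 0 ? 2 : 3] += 1;
    } else if (sel == 48) {              // Ng binds Ca-free CaM
      int i = freeCam[0][0].pick(unif_rand());
      camClassRemove(i); camNg[i] = 1; camClassAdd(i);
      --freeNg;
      evCount[4] += 1;
    } else if (sel == 49) {              // Ng unbinds
      int i = ngCams.pick(unif_rand());
      camClassRemove(i); camNg[i] = 0; camClassAdd(i);
      ++freeNg;
      evCount[5] += 1;
    } else if (sel < 68) {               // CaM binds a subunit
      int k = sel - 50;
      bool toP = k >= 9; if (toP) k -= 9;
      int c = k / 3, n = k % 3;
      int i = freeCam[c][n].pick(unif_rand());
      int j = (toP ? freeP : freeU).pick(unif_rand());
      (toP ? freeP : freeU).remove(j, subPosFree);
      camClassRemove(i);
      camSub[i] = j; subCam[j] = i;
      camClassAdd(i);
      ++nBoundSub; if (!toP) ++nBoundUSub;
      recomputeSub(j); recomputeSub(succOf(j));
      evCount[6] += 1;
    } else if (sel < 77) {               // CaM unbinds from U subunit
      int k = sel - 68, c = k / 3, n = k % 3;
      int i = boundU[c][n].pick(unif_rand());
      int j = camSub[i];
      camClassRemove(i);
      camSub[i] = -1; subCam[j] = -1;
      camClassAdd(i);
      freeU.add(j, subPosFree);
      --nBoundSub; --nBoundUSub;
      recomputeSub(j); recomputeSub(succOf(j));
      evCount[7] += 1;
    } else if (sel == 77) {              // CaM unbinds from P subunit
      int nbp = 0;
      for (int c = 0; c < 3; ++c)
        for (int n = 0; n < 3; ++n) nbp += boundP[c][n].size();
      int pickIdx = ipick(unif_rand(), nbp), i = -1;
      for (int c = 0; c < 3 && i < 0; ++c)
        for (int n = 0; n < 3 && i < 0; ++n) {
          int sz = boundP[c][n].size();
          if (pickIdx < sz) i = boundP[c][n].ids[pickIdx];
          else pickIdx -= sz;
        }
      int j = camSub[i];
      camClassRemove(i);
      camSub[i] = -1; subCam[j] = -1;
      camClassAdd(i);
      freeP.add(j, subPosFree);
      --nBoundSub;
      recomputeSub(j); recomputeSub(succOf(j));
      evCount[7] += 1;
    } else if (sel == 78) {              // PP1 binds
      int j = elig.pick(unif_rand());
      elig.remove(j, subPosElig);
      subPP1[j] = 1; --freePP1;
      pp1b.add(j, subPosPP1);
      evCount[8] += 1;
    } else if (sel == 79) {              // PP1 unbinds
      int j = pp1b.pick(unif_rand());
      pp1b.remove(j, subPosPP1);
      subPP1[j] = 0; ++freePP1;
      elig.add(j, subPosElig);
      evCount[9] += 1;
    } else if (sel == 80) {              // PP1 catalysis: P -> U
      int j = pp1b.pick(unif_rand());
      pp1b.remove(j, subPosPP1);
      subPP1[j] = 0; ++freePP1;
      int i = subCam[j];
      if (i >= 0) camClassRemove(i);
      subP[j] = 0; --nPsub;
      if (i >= 0) { camClassAdd(i); ++nBoundUSub; }
      else {
        freeP.remove(j, subPosFree);
        freeU.add(j, subPosFree);
      }
      recomputeSub(j); recomputeSub(succOf(j));
      evCount[10] += 1;
    } else if (sel == 81) {              // neighbour phosphorylation
      double rr = unif_rand() * phosTotal;
      int j = -1;
      for (int s = 0; s < nSub; ++s) {
        if (phosProp[s] > 0) {
          if (rr < phosProp[s]) { j = s; break; }
          rr -= phosProp[s];
        }
      }
      if (j < 0) {  // float roundoff: take last eligible
        for (int s = nSub - 1; s >= 0; --s)
          if (phosProp[s] > 0) { j = s; break; }
      }
      if (j < 0) stop("phosphorylation channel fired with no eligible substrate");
      int i = subCam[j];
      camClassRemove(i);
      subP[j] = 1; ++nPsub; --nBoundUSub;
      camClassAdd(i);
      elig.add(j, subPosElig);
      recomputeSub(j); recomputeSub(succOf(j));
      if (t >= 0) ++phosEvents;
      evCount[11] += 1;
    } else if (sel == 82) {              // Ca efflux
      if (nCa > 0) --nCa;
      evCount[12] += 1;
    } else if (sel == 83) {              // baseline influx
      ++nCa;
      evCount[13] += 1;
    } else {                             // pulse influx candidate (thinning)
      double lam = pulseRate(t);
      if (unif_rand() * curBound <= lam) {
        ++nCa;
        evCount[14] += 1;
      } else evCount[15] += 1;           // null event
    }
    if (t >= 0 && nCa > peakCa) peakCa = nCa;
  }

  while (iRec < nRec) { record(nextRec); nextRec += recordDt; }

  return List::create(
    _["time"] = recTime, _["obs"] = obs,
    _["peakCa"] = peakCa / om,
    _["phosphoEvents"] = (double)phosEvents,
    _["nEvents"] = (double)nEvents,
    _["eventCounts"] = NumericVector(evCount.begin(), evCount.end()),
    _["final"] = List::create(
      _["camC"] = IntegerVector(camC.begin(), camC.end()),
      _["camN"] = IntegerVector(camN.begin(), camN.end()),
      _["camNg"] = IntegerVector(camNg.begin(), camNg.end()),
      _["camSub"] = IntegerVector(camSub.begin(), camSub.end()),
      _["subP"] = IntegerVector(subP.begin(), subP.end()),
      _["subCam"] = IntegerVector(subCam.begin(), subCam.end()),
      _["subPP1"] = IntegerVector(subPP1.begin(), subPP1.end()),
      _["freeNg"] = freeNg, _["freePP1"] = freePP1, _["nCa"] = nCa));
}
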