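#include <Rcpp.h>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// 8 lattice (Moore) directions
static const int DX[8] = { 1, 1, 0, -1, -1, -1, 0, 1 };
static const int DY[8] = { 0, 1, 1,  1,  0, -1, -1, -1 };

// subset codes
enum { NAIVE = 0, EFFECTOR = 1, MEMORY = 2 };

static inline int runifInt(int n) {
  // uniform integer in [0, n-1] from R's RNG
  int k = (int)(unif_rand() * n);
  if (k >= n) k = n - 1;
  if (k < 0) k = 0;
  return k;
}

struct Params {
  double killProb;
  int conjDuration;
  int maxConjugates;
  double memoryDiffProb;
  int memoryDiffGeneration;
  int divisionCycleTime;
  int persMin, persMax;
  double lifespan[3];     // naive, effector, memory (minutes)
  double regenRate;       // fraction per day
  double influxRate;      // fraction per day
  bool motility;          // fixture switch: disable all movement/efflux
};

struct Sim {
  int W, H;
  int nIslets;
  std::vector<double> mem;        // membrane minutes remaining; -1 outside ring
  std::vector<int> memIslet;      // islet id of ring site, 0 elsewhere
  std::vector<int> beta;          // islet id of resident Beta cell, 0 = none
  std::vector<int> interior;      // original islet footprint id, 0 elsewhere
  std::vector<int> occ;           // T-cell index + 1, 0 = free
  std::vector<uint8_t> trig;      // per-islet attack flag (1-based index)
  std::vector<int> betaList;      // site indices holding Beta cells (lazy-cleaned)
  std::vector<uint8_t> inList;    // site in betaList?
  // incrementally maintained neighbourhood counts (fast-path filters)
  std::vector<int> nearBeta;      // Beta cells among the 8 neighbours
  std::vector<int> nearMemIntact; // intact ring sites in the 3x3 block
  std::vector<int> nearOpen;      // opened ring sites in the 3x3 block

  // agents (structure of arrays)
  std::vector<int> cx, cy, sub, gen, dir, pers, cycT, c1, c2;
  std::vector<double> age;
  std::vector<uint8_t> cyc, alive;

  Params P;
  long betaCount = 0, aliveCount = 0, deadSlots = 0;
  // cumulative event counters
  double kills = 0, conjForms = 0, divisions = 0, memDiffs = 0, recalls = 0,
         openings = 0, nInflux = 0, nEfflux = 0, deaths = 0, regenBirths = 0;

  std::vector<int> order;            // per-tick randomised agent order
  std::vector<int> dividersScratch;  // regeneration scratch

  inline int sidx(int x, int y) const { return x + y * W; }
  inline bool inGrid(int x, int y) const { return x >= 0 && x < W && y >= 0 && y < H; }

  // bump the 8-neighbour count of `v` around site s
  inline void bump8(std::vector<int>& v, int s, int delta) {
    int x = s % W, y = s / W;
    for (int d = 0; d < 8; ++d) {
      int nx = x + DX[d], ny = y + DY[d];
      if (inGrid(nx, ny)) v[sidx(nx, ny)] += delta;
    }
  }
  // bump the 3x3-block count of `v` around site s (own site included)
  inline void bump9(std::vector<int>& v, int s, int delta) {
    int x = s % W, y = s / W;
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int nx = x + dx, ny = y + dy;
        if (inGrid(nx, ny)) v[sidx(nx, ny)] += delta;
      }
  }
  inline void placeBeta(int s, int id) {
    beta[s] = id;
    bump8(nearBeta, s, +1);
    ++betaCount;
    if (!inList[s]) { inList[s] = 1; betaList.push_back(s); }
  }
  inline void killBeta(int s) {
    beta[s] = 0;
    bump8(nearBeta, s, -1);
    --betaCount;
  }
  inline void openSite(int s) {
    mem[s] = 0;
    bump9(nearMemIntact, s, -1);
    bump9(nearOpen, s, +1);
    openings += 1;
  }

  inline bool betaAdjacent(int x, int y) const {
    for (int d = 0; d < 8; ++d) {
      int nx = x + DX[d], ny = y + DY[d];
      if (inGrid(nx, ny) && beta[sidx(nx, ny)] > 0) return true;
    }
    return false;
  }

  // antigen contact: a Moore-adjacent Beta cell that is physically
  // accessible (not separated by intact basement membrane). Drives
  // activation, cycling, recall and conjugation alike.
  inline bool antigenContact(int x, int y) const {
    int e = sidx(x, y);
    if (nearBeta[e] == 0) return false;
    for (int d = 0; d < 8; ++d) {
      int nx = x + DX[d], ny = y + DY[d];
      if (!inGrid(nx, ny)) continue;
      int s = sidx(nx, ny);
      if (beta[s] > 0 && conjugable(e, s)) return true;
    }
    return false;
  }

  // effector engagement with intact basement membrane (own site included):
  // engaged effectors arrest in place and erode the adjacent ring sites
  inline bool membraneEngaged(int x, int y) const {
    return nearMemIntact[sidx(x, y)] > 0;
  }

  // an opened ring site in the Moore neighbourhood (own site included)
  // offers a way forward: engaged effectors beside an opening resume moving
  inline bool openingAdjacent(int x, int y) const {
    return nearOpen[sidx(x, y)] > 0;
  }

  // May an agent standing at `from` occupy site (tx, ty)?
  // Free sites only; an intact basement membrane blocks crossings between the
  // islet interior and its perimeter ring (in both directions), but ring sites
  // themselves are ordinary walkable tissue.
  inline bool canOccupy(int from, int tx, int ty) const {
    int s = sidx(tx, ty);
    if (occ[s] != 0 || beta[s] != 0) return false;
    bool fromIn = interior[from] > 0, toIn = interior[s] > 0;
    if (!fromIn && toIn && memIslet[from] > 0 && mem[from] > 0) return false;
    if (fromIn && !toIn && mem[s] > 0) return false;
    if (!fromIn && toIn && memIslet[from] == 0) return false;  // cannot enter except via ring
    return true;
  }

  // Is the Beta cell at site b conjugable by an effector at site e?
  // Beta cells on the original islet footprint are protected until the effector
  // is inside the islet or standing on an opened (strength 0) ring site;
  // regrowth outside the footprint is unprotected.
  inline bool conjugable(int e, int b) const {
    if (interior[b] == 0) return true;
    if (interior[e] > 0) return true;
    if (memIslet[e] > 0 && mem[e] <= 0) return true;
    return false;
  }

  void removeCell(int i) {
    occ[sidx(cx[i], cy[i])] = 0;
    alive[i] = 0;
    --aliveCount;
    ++deadSlots;
  }

  int addCell(int x, int y, int subset, int generation) {
    cx.push_back(x); cy.push_back(y); sub.push_back(subset);
    gen.push_back(generation); dir.push_back(runifInt(8)); pers.push_back(0);
    cycT.push_back(0); c1.push_back(0); c2.push_back(0);
    age.push_back(0.0); cyc.push_back(0); alive.push_back(1);
    int i = (int)cx.size() - 1;
    occ[sidx(x, y)] = i + 1;
    ++aliveCount;
    return i;
  }

  void compact() {
    size_t n = cx.size(), j = 0;
    for (size_t i = 0; i < n; ++i) {
      if (!alive[i]) continue;
      if (i != j) {
        cx[j] = cx[i]; cy[j] = cy[i]; sub[j] = sub[i]; gen[j] = gen[i];
        dir[j] = dir[i]; pers[j] = pers[i]; cycT[j] = cycT[i];
        c1[j] = c1[i]; c2[j] = c2[i]; age[j] = age[i];
        cyc[j] = cyc[i]; alive[j] = 1;
      }
      occ[sidx(cx[j], cy[j])] = (int)j + 1;
      ++j;
    }
    cx.resize(j); cy.resize(j); sub.resize(j); gen.resize(j); dir.resize(j);
    pers.resize(j); cycT.resize(j); c1.resize(j); c2.resize(j); age.resize(j);
    cyc.resize(j); alive.resize(j);
    deadSlots = 0;
  }

  void shuffledAlive(std::vector<int>& out, int subsetOnly = -1) {
    out.clear();
    for (size_t i = 0; i < cx.size(); ++i)
      if (alive[i] && (subsetOnly < 0 || sub[i] == subsetOnly)) out.push_back((int)i);
    for (int i = (int)out.size() - 1; i > 0; --i) {
      int j = runifInt(i + 1);
      std::swap(out[i], out[j]);
    }
  }

  // (1) ageing and lifespan culling. Effectors engaged at the basement
  // membrane hold their position under target-adhesion survival signals and
  // do not accumulate age while engaged.
  void stepCull() {
    for (size_t i = 0; i < cx.size(); ++i) {
      if (!alive[i]) continue;
      if (sub[i] == EFFECTOR && membraneEngaged(cx[i], cy[i])) continue;
      age[i] += 1.0;
      if (age[i] >= P.lifespan[sub[i]]) {
        removeCell((int)i);
        deaths += 1;
      }
    }
  }

  // (2) conjugate countdown
  void stepConjCountdown() {
    for (size_t i = 0; i < cx.size(); ++i) {
      if (!alive[i]) continue;
      if (c1[i] > 0) --c1[i];
      if (c2[i] > 0) --c2[i];
    }
  }

  // (3) persistent random-walk movement with boundary efflux.
  // Conjugated cells and cycling cells in antigen contact are arrested.
  void stepMove() {
    if (!P.motility) return;
    for (int i : order) {
      if (!alive[i]) continue;
      if (c1[i] > 0 || c2[i] > 0) continue;
      if (cyc[i] && antigenContact(cx[i], cy[i])) continue;
      if (sub[i] == EFFECTOR && membraneEngaged(cx[i], cy[i]) &&
          !openingAdjacent(cx[i], cy[i]) && !antigenContact(cx[i], cy[i]))
        continue;
      int from = sidx(cx[i], cy[i]);
      // invasion: a cell at a breach steps through the opening into the
      // islet rather than diffusing away (local, not chemotactic)
      if (interior[from] == 0) {
        int inv[8], ninv = 0;
        for (int d = 0; d < 8; ++d) {
          int nx = cx[i] + DX[d], ny = cy[i] + DY[d];
          if (!inGrid(nx, ny)) continue;
          int t = sidx(nx, ny);
          if (interior[t] > 0 && canOccupy(from, nx, ny)) inv[ninv++] = t;
        }
        if (ninv == 0 && memIslet[from] == 0) {
          for (int d = 0; d < 8; ++d) {
            int nx = cx[i] + DX[d], ny = cy[i] + DY[d];
            if (!inGrid(nx, ny)) continue;
            int t = sidx(nx, ny);
            if (memIslet[t] > 0 && mem[t] <= 0 && canOccupy(from, nx, ny))
              inv[ninv++] = t;
          }
        }
        if (ninv > 0) {
          int t = inv[runifInt(ninv)];
          occ[from] = 0;
          cx[i] = t % W; cy[i] = t / W;
          occ[t] = i + 1;
          continue;
        }
      }
      if (pers[i] <= 0) {
        dir[i] = runifInt(8);
        pers[i] = P.persMin + runifInt(P.persMax - P.persMin + 1);
      }
      int nx = cx[i] + DX[dir[i]], ny = cy[i] + DY[dir[i]];
      if (!inGrid(nx, ny)) {
        removeCell(i);
        nEfflux += 1;
        continue;
      }
      if (canOccupy(from, nx, ny)) {
        occ[from] = 0;
        cx[i] = nx; cy[i] = ny;
        occ[sidx(nx, ny)] = i + 1;
      }
      --pers[i];
    }
  }

  // (4) membrane degradation: each ring site with remaining strength loses one
  // minute per effector in its Moore neighbourhood (or standing on it)
  void stepDegrade() {
    for (size_t i = 0; i < cx.size(); ++i) {
      if (!alive[i] || sub[i] != EFFECTOR) continue;
      if (nearMemIntact[sidx(cx[i], cy[i])] == 0) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        for (int dx = -1; dx <= 1; ++dx) {
          int nx = cx[i] + dx, ny = cy[i] + dy;
          if (!inGrid(nx, ny)) continue;
          int s = sidx(nx, ny);
          if (memIslet[s] > 0 && mem[s] > 0) {
            mem[s] -= 1.0;
            if (mem[s] <= 0) openSite(s);
          }
        }
      }
    }
  }

  // (5) memory recall: contact with a Beta cell restores effector function
  void stepRecall() {
    for (size_t i = 0; i < cx.size(); ++i) {
      if (!alive[i] || sub[i] != MEMORY) continue;
      if (antigenContact(cx[i], cy[i])) {
        sub[i] = EFFECTOR;
        age[i] = 0.0;
        recalls += 1;
      }
    }
  }

  // (6) conjugate formation and killing (kill decided at formation)
  void stepConjugate() {
    int cand[8];
    for (int i : order) {
      if (!alive[i]) continue;
      if (sub[i] != EFFECTOR) continue;
      int capacity = P.maxConjugates - (c1[i] > 0 ? 1 : 0) - (c2[i] > 0 ? 1 : 0);
      if (capacity <= 0) continue;
      int e = sidx(cx[i], cy[i]);
      if (nearBeta[e] == 0) continue;
      int ncand = 0;
      for (int d = 0; d < 8; ++d) {
        int nx = cx[i] + DX[d], ny = cy[i] + DY[d];
        if (!inGrid(nx, ny)) continue;
        int s = sidx(nx, ny);
        if (beta[s] > 0 && conjugable(e, s)) cand[ncand++] = s;
      }
      if (ncand == 0) continue;
      // uniform random choice of up to `capacity` distinct targets
      for (int k = ncand - 1; k > 0; --k) {
        int j = runifInt(k + 1);
        std::swap(cand[k], cand[j]);
      }
      int take = capacity < ncand ? capacity : ncand;
      for (int k = 0; k < take; ++k) {
        int s = cand[k];
        conjForms += 1;
        trig[beta[s]] = 1;  // a conjugated Beta cell marks its islet as attacked
        if (unif_rand() < P.killProb) {
          killBeta(s);
          kills += 1;
        }
        if (c1[i] == 0) c1[i] = P.conjDuration; else c2[i] = P.conjDuration;
      }
    }
  }

  // subset of a division product: memory with probability memoryDiffProb from
  // generation memoryDiffGeneration on, effector otherwise
  int productSubset(int g) {
    if (g >= P.memoryDiffGeneration && unif_rand() < P.memoryDiffProb) {
      memDiffs += 1;
      return MEMORY;
    }
    return EFFECTOR;
  }

  // (7) cell-cycle progression, division and activation. Antigen contact
  // commits a cell to one programmed division: the started cycle runs to
  // completion autonomously (conjugated or not); products need fresh contact
  // to enter the next cycle.
  void stepProliferate() {
    // phase A: progress cycling cells; division when the timer expires,
    // deferred while no free site exists
    for (int i : order) {
      if (!alive[i] || !cyc[i]) continue;
      if (cycT[i] > 0) --cycT[i];
      if (cycT[i] > 0) continue;
      int from = sidx(cx[i], cy[i]);
      int nfree = 0, fx[8], fy[8];
      for (int d = 0; d < 8; ++d) {
        int nx = cx[i] + DX[d], ny = cy[i] + DY[d];
        if (inGrid(nx, ny) && canOccupy(from, nx, ny)) { fx[nfree] = nx; fy[nfree] = ny; ++nfree; }
      }
      if (nfree == 0) continue;  // deferred one tick
      int pick = runifInt(nfree);
      int g = gen[i] + 1;
      // symmetric division: parent and daughter are both fresh products.
      // One antigen encounter commits the lineage to the programmed burst:
      // below the memory-eligible generation products re-enter the cycle
      // autonomously; later generations need renewed contact.
      bool burst = g < P.memoryDiffGeneration;
      gen[i] = g;
      age[i] = 0.0;
      sub[i] = productSubset(g);
      cyc[i] = (burst && sub[i] == EFFECTOR) ? 1 : 0;
      cycT[i] = cyc[i] ? P.divisionCycleTime : 0;
      int j = addCell(fx[pick], fy[pick], productSubset(g), g);
      if (burst && sub[j] == EFFECTOR) { cyc[j] = 1; cycT[j] = P.divisionCycleTime; }
      divisions += 1;
    }
    // phase B: antigen contact starts the fast cycle in naive cells and in
    // unengaged effector cells (new products included)
    for (size_t i = 0; i < cx.size(); ++i) {
      if (!alive[i] || cyc[i]) continue;
      if (sub[i] == MEMORY) continue;
      bool engaged = sub[i] == EFFECTOR && (c1[i] > 0 || c2[i] > 0);
      if (engaged || antigenContact(cx[i], cy[i])) {
        cyc[i] = 1;
        cycT[i] = P.divisionCycleTime;
      }
    }
  }

  // (8) attack triggering and Beta-cell regeneration
  void stepRegen() {
    for (size_t i = 0; i < cx.size(); ++i) {
      if (!alive[i]) continue;
      // a T cell on a membrane or interior site, or an effector engaged in
      // eroding the ring, marks the islet as under attack (conjugation of a
      // Beta cell triggers during conjugate formation)
      int s = sidx(cx[i], cy[i]);
      int id = memIslet[s] > 0 ? memIslet[s] : interior[s];
      if (id > 0) trig[id] = 1;
      if (sub[i] == EFFECTOR && nearMemIntact[s] > 0) {
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int nx = cx[i] + dx, ny = cy[i] + dy;
            if (!inGrid(nx, ny)) continue;
            int t = sidx(nx, ny);
            if (memIslet[t] > 0 && mem[t] > 0) trig[memIslet[t]] = 1;
          }
      }
    }
    if (P.regenRate <= 0) return;
    double p = P.regenRate / 1440.0;
    // collect the triggered living Beta cells (lazily cleaning the list),
    // then draw the number of dividers binomially and pick them uniformly
    // without replacement -- distributionally identical to an independent
    // per-cell Bernoulli draw
    dividersScratch.clear();
    for (int k = (int)betaList.size() - 1; k >= 0; --k) {
      int s = betaList[k];
      if (beta[s] == 0) {
        inList[s] = 0;
        betaList[k] = betaList.back();
        betaList.pop_back();
        continue;
      }
      if (trig[beta[s]]) dividersScratch.push_back(s);
    }
    int pool = (int)dividersScratch.size();
    if (pool == 0) return;
    int nDiv = (int)R::rbinom((double)pool, p);
    for (int m = 0; m < nDiv; ++m) {
      int j = m + runifInt(pool - m);
      std::swap(dividersScratch[m], dividersScratch[j]);
      int s = dividersScratch[m];
      if (beta[s] == 0) continue;  // displaced or killed earlier this step
      int id = beta[s];
      int x = s % W, y = s / W;
      int nfree = 0, fs[8];
      for (int d = 0; d < 8; ++d) {
        int nx = x + DX[d], ny = y + DY[d];
        if (!inGrid(nx, ny)) continue;
        int t = sidx(nx, ny);
        if (beta[t] == 0 && occ[t] == 0) fs[nfree++] = t;
      }
      if (nfree > 0) {
        placeBeta(fs[runifInt(nfree)], id);
        regenBirths += 1;
        continue;
      }
      // crowded: growth pressure pushes the newborn along a straight line
      // of Beta cells to the nearest free site (it emerges at the islet
      // surface); no resident cell moves, so the protected core stays
      // protected. Division is skipped only when no such path exists.
      int d = runifInt(8);
      int L = -1;
      for (int step = 1; step <= 24; ++step) {
        int nx = x + DX[d] * step, ny = y + DY[d] * step;
        if (!inGrid(nx, ny)) break;
        int t = sidx(nx, ny);
        if (occ[t] != 0) break;            // a T cell blocks the path
        if (beta[t] == 0) { L = step; break; }
      }
      if (L < 0) continue;
      placeBeta(sidx(x + DX[d] * L, y + DY[d] * L), id);
      regenBirths += 1;
    }
  }

  // (9) influx of naive cells at the tissue boundary
  void stepInflux() {
    if (P.influxRate <= 0 || aliveCount == 0) return;
    double lambda = P.influxRate * (double)aliveCount / 1440.0;
    int n = (int)R::rpois(lambda);
    int perim = 2 * W + 2 * H - 4;
    for (int k = 0; k < n; ++k) {
      for (int attempt = 0; attempt < 100; ++attempt) {
        int r = runifInt(perim);
        int x, y;
        if (r < W) { x = r; y = 0; }
        else if (r < 2 * W) { x = r - W; y = H - 1; }
        else if (r < 2 * W + H - 2) { x = 0; y = r - 2 * W + 1; }
        else { x = W - 1; y = r - 2 * W - (H - 2) + 1; }
        int s = sidx(x, y);
        if (occ[s] == 0 && beta[s] == 0) {
          addCell(x, y, NAIVE, 0);
          nInflux += 1;
          break;
        }
      }
    }
  }

  void tick() {
    shuffledAlive(order);   // one randomised agent order per tick
    stepCull();
    stepConjCountdown();
    stepMove();
    stepDegrade();
    stepRecall();
    stepConjugate();
    stepProliferate();
    stepRegen();
    stepInflux();
    if (deadSlots > 4096 && deadSlots * 2 > (long)cx.size()) compact();
  }

  void census(long cnt[3]) const {
    cnt[0] = cnt[1] = cnt[2] = 0;
    for (size_t i = 0; i < cx.size(); ++i)
      if (alive[i]) ++cnt[sub[i]];
  }

  void audit() const {
    long nOcc = 0;
    for (int s = 0; s < W * H; ++s) {
      if (occ[s] != 0) {
        ++nOcc;
        int i = occ[s] - 1;
        if (i < 0 || i >= (int)cx.size() || !alive[i] || sidx(cx[i], cy[i]) != s)
          stop("corrupted state: occupancy grid out of sync with agents");
      }
      if (occ[s] != 0 && beta[s] != 0)
        stop("corrupted state: T cell and Beta cell share a site");
    }
    if (nOcc != aliveCount)
      stop("corrupted state: occupancy count does not match live agents");
    long nb = 0;
    for (int s = 0; s < W * H; ++s) if (beta[s] != 0) ++nb;
    if (nb != betaCount)
      stop("corrupted state: Beta census out of sync with grid");
    // the incremental neighbourhood counts must match a recount
    for (int y = 0; y < H; ++y)
      for (int x = 0; x < W; ++x) {
        int s = sidx(x, y);
        int nb8 = 0;
        for (int d = 0; d < 8; ++d) {
          int nx = x + DX[d], ny = y + DY[d];
          if (inGrid(nx, ny) && beta[sidx(nx, ny)] > 0) ++nb8;
        }
        if (nb8 != nearBeta[s])
          stop("corrupted state: nearBeta count out of sync");
      }
  }
};

static void loadState(Sim& S, const List& state) {
  // matrices arrive as R matrices indexed [x, y] (nrow = grid width)
  IntegerMatrix betaM = state["beta"];
  IntegerMatrix interiorM = state["interior"];
  IntegerMatrix memIsletM = state["memIslet"];
  NumericMatrix memM = state["mem"];
  S.W = betaM.nrow();
  S.H = betaM.ncol();
  int W = S.W, H = S.H;
  S.mem.assign(W * H, -1.0);
  S.memIslet.assign(W * H, 0);
  S.beta.assign(W * H, 0);
  S.interior.assign(W * H, 0);
  S.occ.assign(W * H, 0);
  S.inList.assign(W * H, 0);
  S.betaList.clear();
  S.betaCount = 0;
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      int s = x + y * W;
      S.beta[s] = betaM(x, y);
      S.interior[s] = interiorM(x, y);
      S.memIslet[s] = memIsletM(x, y);
      double m = memM(x, y);
      S.mem[s] = ISNAN(m) ? -1.0 : m;
      if (S.beta[s] > 0) {
        ++S.betaCount;
        S.inList[s] = 1;
        S.betaList.push_back(s);
      }
    }
  }
  S.nearBeta.assign(W * H, 0);
  S.nearMemIntact.assign(W * H, 0);
  S.nearOpen.assign(W * H, 0);
  for (int s = 0; s < W * H; ++s) {
    if (S.beta[s] > 0) S.bump8(S.nearBeta, s, +1);
    if (S.memIslet[s] > 0) {
      if (S.mem[s] > 0) S.bump9(S.nearMemIntact, s, +1);
      else S.bump9(S.nearOpen, s, +1);
    }
  }
  IntegerVector trigV = state["triggered"];
  S.nIslets = trigV.size();
  S.trig.assign(S.nIslets + 1, 0);
  for (int i = 0; i < S.nIslets; ++i) S.trig[i + 1] = trigV[i] != 0;

  List cells = state["cells"];
  IntegerVector x = cells["x"], y = cells["y"], subset = cells["subset"],
                generation = cells["generation"], direction = cells["direction"],
                persistence = cells["persistence"], cycleTimer = cells["cycleTimer"],
                conj1 = cells["conj1"], conj2 = cells["conj2"];
  NumericVector cage = cells["age"];
  LogicalVector cycling = cells["cycling"];
  int n = x.size();
  S.cx.clear(); S.cy.clear(); S.sub.clear(); S.gen.clear(); S.dir.clear();
  S.pers.clear(); S.cycT.clear(); S.c1.clear(); S.c2.clear();
  S.age.clear(); S.cyc.clear(); S.alive.clear();
  S.aliveCount = 0; S.deadSlots = 0;
  for (int i = 0; i < n; ++i) {
    int xi = x[i] - 1, yi = y[i] - 1;  // R coordinates are 1-based
    if (xi < 0 || xi >= W || yi < 0 || yi >= H)
      stop("cell %d is outside the grid", i + 1);
    int s = xi + yi * W;
    if (S.occ[s] != 0) stop("two T cells share a site at initialisation");
    if (S.beta[s] != 0) stop("T cell placed on a Beta-cell site");
    S.cx.push_back(xi); S.cy.push_back(yi); S.sub.push_back(subset[i]);
    S.gen.push_back(generation[i]); S.dir.push_back(direction[i]);
    S.pers.push_back(persistence[i]); S.cycT.push_back(cycleTimer[i]);
    S.c1.push_back(conj1[i]); S.c2.push_back(conj2[i]);
    S.age.push_back(cage[i]); S.cyc.push_back(cycling[i] ? 1 : 0);
    S.alive.push_back(1);
    S.occ[s] = i + 1;
    ++S.aliveCount;
  }
}

static Params loadParams(const List& params) {
  Params P;
  P.killProb = as<double>(params["killProb"]);
  P.conjDuration = as<int>(params["conjDuration"]);
  P.maxConjugates = as<int>(params["maxConjugates"]);
  P.memoryDiffProb = as<double>(params["memoryDiffProb"]);
  P.memoryDiffGeneration = as<int>(params["memoryDiffGeneration"]);
  P.divisionCycleTime = as<int>(params["divisionCycleTime"]);
  P.persMin = as<int>(params["persMin"]);
  P.persMax = as<int>(params["persMax"]);
  P.lifespan[0] = as<double>(params["naiveLifespan"]);
  P.lifespan[1] = as<double>(params["effectorLifespan"]);
  P.lifespan[2] = as<double>(params["memoryLifespan"]);
  P.regenRate = as<double>(params["betaRegenRate"]);
  P.influxRate = as<double>(params["influxRate"]);
  P.motility = as<bool>(params["motility"]);
  return P;
}

static List dumpState(const Sim& S) {
  int W = S.W, H = S.H;
  NumericMatrix memM(W, H);
  IntegerMatrix memIsletM(W, H), betaM(W, H), interiorM(W, H);
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      int s = x + y * W;
      memM(x, y) = S.mem[s] < 0 ? NA_REAL : S.mem[s];
      memIsletM(x, y) = S.memIslet[s];
      betaM(x, y) = S.beta[s];
      interiorM(x, y) = S.interior[s];
    }
  }
  IntegerVector trigV(S.nIslets);
  for (int i = 0; i < S.nIslets; ++i) trigV[i] = S.trig[i + 1];
  long n = 0;
  for (size_t i = 0; i < S.cx.size(); ++i) if (S.alive[i]) ++n;
  IntegerVector x(n), y(n), subset(n), generation(n), direction(n),
      persistence(n), cycleTimer(n), conj1(n), conj2(n);
  NumericVector cage(n);
  LogicalVector cycling(n);
  long j = 0;
  for (size_t i = 0; i < S.cx.size(); ++i) {
    if (!S.alive[i]) continue;
    x[j] = S.cx[i] + 1; y[j] = S.cy[i] + 1; subset[j] = S.sub[i];
    generation[j] = S.gen[i]; direction[j] = S.dir[i]; persistence[j] = S.pers[i];
    cycleTimer[j] = S.cycT[i]; conj1[j] = S.c1[i]; conj2[j] = S.c2[i];
    cage[j] = S.age[i]; cycling[j] = S.cyc[i] != 0;
    ++j;
  }
  List cells = List::create(
      _["x"] = x, _["y"] = y, _["subset"] = subset, _["age"] = cage,
      _["generation"] = generation, _["direction"] = direction,
      _["persistence"] = persistence, _["cycling"] = cycling,
      _["cycleTimer"] = cycleTimer, _["conj1"] = conj1, _["conj2"] = conj2);
  return List::create(
      _["mem"] = memM, _["memIslet"] = memIsletM, _["beta"] = betaM,
      _["interior"] = interiorM, _["triggered"] = trigV, _["cells"] = cells);
}

// [[Rcpp::export(name = ".cpp_run")]]
List cpp_run(List state, List params, int nTicks, int recordEvery = 1440,
             bool checkInvariants = false, bool returnState = false,
             bool earlyStop = true, bool stopWhenBetaExtinct = false) {
  Sim S;
  loadState(S, state);
  S.P = loadParams(params);

  int nRec = nTicks / recordEvery + 1;
  NumericVector recTick(nRec), recBeta(nRec), recNaive(nRec), recEff(nRec),
      recMem(nRec), recKills(nRec), recDiv(nRec), recInflux(nRec),
      recEfflux(nRec), recDeaths(nRec), recRegen(nRec), recOpen(nRec);
  long cnt[3];
  int r = 0;
  S.census(cnt);
  recTick[r] = 0; recBeta[r] = S.betaCount;
  recNaive[r] = cnt[0]; recEff[r] = cnt[1]; recMem[r] = cnt[2];
  recKills[r] = 0; recDiv[r] = 0; recInflux[r] = 0; recEfflux[r] = 0;
  recDeaths[r] = 0; recRegen[r] = 0; recOpen[r] = 0;
  ++r;

  bool stopped = false;
  for (int t = 1; t <= nTicks; ++t) {
    if (!stopped) {
      S.tick();
      if (checkInvariants && t % 720 == 0) S.audit();
      if (earlyStop && S.betaCount == 0 &&
          (S.aliveCount == 0 || stopWhenBetaExtinct)) stopped = true;
    }
    if (t % recordEvery == 0) {
      S.census(cnt);
      recTick[r] = t; recBeta[r] = S.betaCount;
      recNaive[r] = cnt[0]; recEff[r] = cnt[1]; recMem[r] = cnt[2];
      recKills[r] = S.kills; recDiv[r] = S.divisions; recInflux[r] = S.nInflux;
      recEfflux[r] = S.nEfflux; recDeaths[r] = S.deaths; recRegen[r] = S.regenBirths;
      recOpen[r] = S.openings;
      ++r;
    }
    if (t % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  if (checkInvariants) S.audit();

  DataFrame series = DataFrame::create(
      _["tick"] = recTick, _["beta"] = recBeta, _["naive"] = recNaive,
      _["effector"] = recEff, _["memory"] = recMem, _["kills"] = recKills,
      _["divisions"] = recDiv, _["influx"] = recInflux, _["efflux"] = recEfflux,
      _["deaths"] = recDeaths, _["regenBirths"] = recRegen,
      _["openings"] = recOpen);
  NumericVector events = NumericVector::create(
      _["kills"] = S.kills, _["conjugates"] = S.conjForms,
      _["divisions"] = S.divisions, _["memoryDiff"] = S.memDiffs,
      _["recalls"] = S.recalls, _["openings"] = S.openings,
      _["influx"] = S.nInflux, _["efflux"] = S.nEfflux,
      _["deaths"] = S.deaths, _["regenBirths"] = S.regenBirths);
  List out = List::create(_["series"] = series, _["events"] = events,
                          _["earlyStopped"] = stopped);
  if (returnState) out["state"] = dumpState(S);
  return out;
}
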