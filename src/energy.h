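#ifndef SRNABUD_ENERGY_H
#define SRNABUD_ENERGY_H

// Reduced nearest-neighbor energy model for RNA secondary structure.
// All energies in centi-kcal/mol (integers) so that the dynamic program and
// the exhaustive-enumeration oracle can be compared exactly.
//
// Bases: A=0, C=1, G=2, U=3.
// Pair types: 0=AU 1=UA 2=CG 3=GC 4=GU 5=UG, -1 = not pairable.

#include <vector>

namespace srnabud {

const int INF_E = 1000000000;
const int MIN_HAIRPIN = 3;   // minimum unpaired bases in a hairpin loop
const int MAX_INTERIOR = 30; // cap on interior/bulge loop size in the DP

inline int pair_type(int a, int b, bool allow_gu) {
  if (a == 0 && b == 3) return 0; // AU
  if (a == 3 && b == 0) return 1; // UA
  if (a == 1 && b == 2) return 2; // CG
  if (a == 2 && b == 1) return 3; // GC
  if (allow_gu && a == 2 && b == 3) return 4; // GU
  if (allow_gu && a == 3 && b == 2) return 5; // UG
  return -1;
}

// stack[outer][inner]: outer pair (i,j) stacked on inner pair (i+1,j-1)
const int STACK[6][6] = {
  //            AU    UA    CG    GC    GU    UG
  /* AU */ {  -90, -110, -220, -210,  -60, -140 },
  /* UA */ { -130,  -90, -240, -210, -100, -130 },
  /* CG */ { -210, -210, -330, -240, -140, -210 },
  /* GC */ { -240, -220, -340, -330, -150, -250 },
  /* GU */ { -130, -140, -250, -210,  -50,  -50 },
  /* UG */ { -100,  -60, -150, -140,  -50,  -50 }
};

inline int hairpin_energy(int size) {          // size = unpaired bases, >= 3
  return 500 + 15 * (size - MIN_HAIRPIN);
}

inline int interior_energy(int size) {         // bulge + internal, size >= 1
  return 200 + 35 * size;
}

// multiloop: ML_A + ML_B * (branches incl. closing pair) + ML_C * unpaired
const int ML_A = 340;
const int ML_B = 40;
const int ML_C = 10;

// Loop-decomposition energy of a complete structure given partner vector
// (partner[i] = j if (i,j) paired, -1 otherwise).  Shared scoring used by
// the oracle; the DP never calls this.
inline int structure_energy(const std::vector<int>& s,
                            const std::vector<int>& partner,
                            bool allow_gu) {
  int n = (int)s.size();
  int e = 0;
  for (int i = 0; i < n; ++i) {
    int j = partner[i];
    if (j <= i) continue;
    // loop closed by (i,j)
    int branches = 0, unpaired = 0;
    int child_i = -1, child_j = -1;
    int p = i + 1;
    while (p < j) {
      if (partner[p] > p) {
        ++branches;
        if (branches == 1) { child_i = p; child_j = partner[p]; }
        p = partner[p] + 1;
      } else {
        ++unpaired;
        ++p;
      }
    }
    if (branches == 0) {
      e += hairpin_energy(j - i - 1);
    } else if (branches == 1) {
      int s1 = child_i - i - 1, s2 = j - child_j - 1;
      if (s1 == 0 && s2 == 0) {
        e += STACK[pair_type(s[i], s[j], allow_gu)]
                  [pair_type(s[child_i], s[child_j], allow_gu)];
      } else {
        e += interior_energy(s1 + s2);
      }
    } else {
      e += ML_A + ML_B * (branches + 1) + ML_C * unpaired;
    }
  }
  return e;
}

} // namespace srnabud

#endif
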