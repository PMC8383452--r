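#include <Rcpp.h>
using namespace Rcpp;

// Replicate-wide maximum scan LLR per direction. counts: areas x reps
// multinomial replicates; zones given as flattened member indices
// (0-based) with offsets; Ein: expected count inside each zone.

// [[Rcpp::export(name = ".scanRefMax")]]
List scanRefMax(IntegerMatrix counts, IntegerVector zoneStart,
                IntegerVector zoneMembers, NumericVector Ein,
                double total) {
  const int nReps = counts.ncol();
  const int nZones = zoneStart.size() - 1;
  NumericVector hi(nReps, 0.0), lo(nReps, 0.0);
  for (int r = 0; r < nReps; ++r) {
    double mh = 0.0, ml = 0.0;
    for (int z = 0; z < nZones; ++z) {
      double O = 0.0;
      for (int k = zoneStart[z]; k < zoneStart[z + 1]; ++k)
        O += counts(zoneMembers[k], r);
      const double E = Ein[z];
      if (O == E) continue;
      double llr = 0.0;
      if (O > 0) llr += O * std::log(O / E);
      const double rem = total - O;
      if (rem > 0) llr += rem * std::log(rem / (total - E));
      if (O > E) { if (llr > mh) mh = llr; }
      else       { if (llr > ml) ml = llr; }
    }
    hi[r] = mh; lo[r] = ml;
  }
  return List::create(_["high"] = hi, _["low"] = lo);
}
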