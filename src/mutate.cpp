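#include <Rcpp.h>
#include <string>
using namespace Rcpp;

static const char BASES[4] = {'A', 'C', 'G', 'T'};

static inline char random_base() {
  int b = (int) std::floor(unif_rand() * 4.0);
  if (b > 3) b = 3;
  return BASES[b];
}

static inline char random_other_base(char c) {
  char b = random_base();
  while (b == c) b = random_base();
  return b;
}

// Per-position error process for simulated amplicon reads: each template
// position independently suffers an error with probability `error_rate`;
// the error is a substitution / insertion (after the position) / deletion
// with probabilities p_sub / p_ins / p_del (normalised).  Uses the R RNG,
// so results are reproducible under set.seed().
// [[Rcpp::export]]
std::string cpp_mutate_read(std::string tmpl, double error_rate,
                            double p_sub, double p_ins, double p_del) {
  const double tot = p_sub + p_ins + p_del;
  const double c1 = p_sub / tot, c2 = (p_sub + p_ins) / tot;
  std::string out;
  out.reserve(tmpl.size() + 16);
  for (size_t i = 0; i < tmpl.size(); ++i) {
    const char c = tmpl[i];
    if (unif_rand() >= error_rate) { out.push_back(c); continue; }
    const double u = unif_rand();
    if (u < c1) out.push_back(random_other_base(c));       // substitution
    else if (u < c2) { out.push_back(c); out.push_back(random_base()); } // insertion
    // else deletion: emit nothing
  }
  return out;
}
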