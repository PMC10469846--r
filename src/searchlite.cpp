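#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Monoisotopic residue masses for the 20 standard amino acids.
// Indexed by (letter - 'A'); non-residue letters hold -1.
static double AA_MASS[26];
static bool aa_init = false;

static void init_aa() {
  if (aa_init) return;
  for (int i = 0; i < 26; ++i) AA_MASS[i] = -1.0;
  AA_MASS['G' - 'A'] = 57.02146;
  AA_MASS['A' - 'A'] = 71.03711;
  AA_MASS['S' - 'A'] = 87.03203;
  AA_MASS['P' - 'A'] = 97.05276;
  AA_MASS['V' - 'A'] = 99.06841;
  AA_MASS['T' - 'A'] = 101.04768;
  AA_MASS['C' - 'A'] = 103.00919;
  AA_MASS['L' - 'A'] = 113.08406;
  AA_MASS['I' - 'A'] = 113.08406;
  AA_MASS['N' - 'A'] = 114.04293;
  AA_MASS['D' - 'A'] = 115.02694;
  AA_MASS['Q' - 'A'] = 128.05858;
  AA_MASS['K' - 'A'] = 128.09496;
  AA_MASS['E' - 'A'] = 129.04259;
  AA_MASS['M' - 'A'] = 131.04049;
  AA_MASS['H' - 'A'] = 137.05891;
  AA_MASS['F' - 'A'] = 147.06841;
  AA_MASS['R' - 'A'] = 156.10111;
  AA_MASS['Y' - 'A'] = 163.06333;
  AA_MASS['W' - 'A'] = 186.07931;
  aa_init = true;
}

static const double WATER = 18.010565;
static const double PROTON = 1.007276;

// Neutral monoisotopic peptide mass (residues + water). NA for bad letters.
// [[Rcpp::export]]
NumericVector peptide_mass_cpp(CharacterVector peptides) {
  init_aa();
  int n = peptides.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(peptides, i));
    double m = WATER;
    bool ok = true;
    for (const char *p = s; *p; ++p) {
      int idx = *p - 'A';
      if (idx < 0 || idx >= 26 || AA_MASS[idx] < 0) { ok = false; break; }
      m += AA_MASS[idx];
    }
    out[i] = ok ? m : NA_REAL;
  }
  return out;
}

// Singly charged b/y fragment masses of one peptide, sorted ascending.
// b_i = prefix + proton; y_i = suffix + water + proton (i = 1..L-1).
// [[Rcpp::export]]
NumericVector by_fragments_cpp(std::string peptide) {
  init_aa();
  int L = (int)peptide.size();
  if (L < 2) return NumericVector(0);
  std::vector<double> res(L);
  for (int i = 0; i < L; ++i) {
    int idx = peptide[i] - 'A';
    if (idx < 0 || idx >= 26 || AA_MASS[idx] < 0)
      stop("invalid residue in peptide");
    res[i] = AA_MASS[idx];
  }
  NumericVector out(2 * (L - 1));
  double acc = 0.0;
  for (int i = 0; i < L - 1; ++i) { acc += res[i]; out[i] = acc + PROTON; }
  acc = 0.0;
  for (int i = 0; i < L - 1; ++i) {
    acc += res[L - 1 - i];
    out[L - 1 + i] = acc + WATER + PROTON;
  }
  std::sort(out.begin(), out.end());
  return out;
}

// Maximum matching between sorted theoretical and sorted observed masses
// where a pair may match iff |t - o| <= tol and each observed peak is used
// at most once. Greedy two-pointer on sorted inputs is optimal here because
// the compatibility intervals all have equal width.
static int match_count(const std::vector<double> &theo,
                       const double *obs, int n_obs, double tol) {
  int i = 0, j = 0, cnt = 0;
  int n_theo = (int)theo.size();
  while (i < n_theo && j < n_obs) {
    if (obs[j] < theo[i] - tol) { ++j; }
    else if (obs[j] > theo[i] + tol) { ++i; }
    else { ++cnt; ++i; ++j; }
  }
  return cnt;
}

// [[Rcpp::export]]
int match_count_cpp(NumericVector theo_sorted, NumericVector obs_sorted,
                    double tol) {
  std::vector<double> t(theo_sorted.begin(), theo_sorted.end());
  return match_count(t, obs_sorted.begin(), obs_sorted.size(), tol);
}

// Score a set of candidate peptides against one spectrum: for each peptide
// compute b/y fragments and count matches against the sorted observed peaks.
// [[Rcpp::export]]
IntegerVector score_candidates_cpp(CharacterVector peptides,
                                   NumericVector obs_sorted, double tol) {
  init_aa();
  int n = peptides.size();
  IntegerVector out(n);
  std::vector<double> theo;
  for (int k = 0; k < n; ++k) {
    const char *s = CHAR(STRING_ELT(peptides, k));
    int L = (int)std::strlen(s);
    if (L < 2) { out[k] = 0; continue; }
    theo.assign(2 * (L - 1), 0.0);
    double acc = 0.0;
    for (int i = 0; i < L - 1; ++i) {
      int idx = s[i] - 'A';
      acc += AA_MASS[idx];
      theo[i] = acc + PROTON;
    }
    acc = 0.0;
    for (int i = 0; i < L - 1; ++i) {
      int idx = s[L - 1 - i] - 'A';
      acc += AA_MASS[idx];
      theo[L - 1 + i] = acc + WATER + PROTON;
    }
    std::sort(theo.begin(), theo.end());
    out[k] = match_count(theo, obs_sorted.begin(), obs_sorted.size(), tol);
  }
  return out;
}

// Score many (spectrum, peptide) candidate pairs in one call. obs_list is a
// list of sorted observed-mass vectors; spec_idx (1-based) selects the
// spectrum for each peptide.
// [[Rcpp::export]]
IntegerVector score_pairs_cpp(CharacterVector peptides,
                              IntegerVector spec_idx, List obs_list,
                              double tol) {
  init_aa();
  int n = peptides.size();
  IntegerVector out(n);
  std::vector<double> theo;
  for (int k = 0; k < n; ++k) {
    const char *s = CHAR(STRING_ELT(peptides, k));
    int L = (int)std::strlen(s);
    NumericVector obs = obs_list[spec_idx[k] - 1];
    if (L < 2) { out[k] = 0; continue; }
    theo.assign(2 * (L - 1), 0.0);
    double acc = 0.0;
    for (int i = 0; i < L - 1; ++i) {
      acc += AA_MASS[s[i] - 'A'];
      theo[i] = acc + PROTON;
    }
    acc = 0.0;
    for (int i = 0; i < L - 1; ++i) {
      acc += AA_MASS[s[L - 1 - i] - 'A'];
      theo[L - 1 + i] = acc + WATER + PROTON;
    }
    std::sort(theo.begin(), theo.end());
    out[k] = match_count(theo, obs.begin(), obs.size(), tol);
  }
  return out;
}

// Semi-tryptic expansion: for each fully tryptic peptide emit all prefixes
// and suffixes with length in [min_len, len], keyed back to the parent row.
// Returns a list(peptide = character, parent = integer 1-based).
// [[Rcpp::export]]
List semi_tryptic_cpp(CharacterVector peptides, int min_len) {
  int n = peptides.size();
  std::vector<std::string> out;
  std::vector<int> parent;
  for (int k = 0; k < n; ++k) {
    std::string s = as<std::string>(peptides[k]);
    int L = (int)s.size();
    if (L < min_len) continue;
    out.push_back(s); parent.push_back(k + 1);
    for (int l = min_len; l < L; ++l) {
      out.push_back(s.substr(0, l)); parent.push_back(k + 1);
      out.push_back(s.substr(L - l, l)); parent.push_back(k + 1);
    }
  }
  return List::create(_["peptide"] = wrap(out), _["parent"] = wrap(parent));
}
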