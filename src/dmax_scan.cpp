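#include <Rcpp.h>
using namespace Rcpp;

// Total log-likelihood of labeled gene expression for each candidate dmax.
//
// For each grid value d: W = max(0, 1 - dist/d) (0 when blocked), per gene
// and class p = R * (1 - prod_links(1 - A*W)), and the likelihood sums
// log(p) over active labels and log(1-p) over inactive ones, with p
// clamped to [eps, 1-eps].
//
// link_gene / link_crm are 1-based indices into the label/A matrices;
// labels has NA for unlabeled entries.
// [[Rcpp::export]]
NumericVector cpp_dmax_scan(NumericVector grid,
                            IntegerVector link_gene,
                            IntegerVector link_crm,
                            NumericVector link_dist,
                            LogicalVector link_blocked,
                            NumericMatrix A,
                            NumericMatrix R,
                            NumericMatrix labels,
                            double eps) {
  const int nlink = link_gene.size();
  const int ngene = labels.nrow();
  const int nclass = labels.ncol();
  NumericVector out(grid.size());
  std::vector<double> logq(ngene);
  for (int g = 0; g < grid.size(); ++g) {
    const double d = grid[g];
    double total = 0.0;
    for (int c = 0; c < nclass; ++c) {
      std::fill(logq.begin(), logq.end(), 0.0);
      for (int l = 0; l < nlink; ++l) {
        if (link_blocked[l] || link_dist[l] >= d) continue;
        const double w = 1.0 - link_dist[l] / d;
        const double aw = A(link_crm[l] - 1, c) * w;
        logq[link_gene[l] - 1] += std::log1p(-std::min(aw, 1.0));
      }
      for (int j = 0; j < ngene; ++j) {
        const double y = labels(j, c);
        if (ISNAN(y)) continue;
        double p = R(j, c) * (-std::expm1(logq[j]));
        if (p < eps) p = eps;
        if (p > 1.0 - eps) p = 1.0 - eps;
        total += (y >= 0.5) ? std::log(p) : std::log1p(-p);
      }
    }
    out[g] = total;
  }
  return out;
}
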