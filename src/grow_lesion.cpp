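#include <Rcpp.h>
using namespace Rcpp;

// Stochastic region growing for synthetic lesions: starting from a seed
// voxel, repeatedly add one uniformly chosen frontier voxel (6-connectivity)
// that lies inside `allowed`, until `target` voxels are reached or the
// frontier empties. The result is always a single 6-connected component.
// Uses R's RNG, so set.seed() in R governs the draw. Indices are 1-based.
// [[Rcpp::export]]
IntegerVector grow_lesion_cpp(LogicalVector allowed, IntegerVector dims,
                              int seed_voxel, int target) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int V = nx * ny * nz;
  if (allowed.size() != V) stop("allowed mask does not match dims");
  std::vector<char> in_lesion(V, 0), in_frontier(V, 0);
  std::vector<int> lesion, frontier;
  lesion.reserve(target);

  const int dx[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, -1, 1};

  int s = seed_voxel - 1;
  if (s < 0 || s >= V || !allowed[s]) stop("seed voxel outside the allowed mask");

  auto expand = [&](int v) {
    const int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
    for (int t = 0; t < 6; ++t) {
      const int xx = x + dx[t], yy = y + dy[t], zz = z + dz[t];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
      const int u = xx + nx * (yy + ny * zz);
      if (!allowed[u] || in_lesion[u] || in_frontier[u]) continue;
      in_frontier[u] = 1;
      frontier.push_back(u);
    }
  };

  in_lesion[s] = 1;
  lesion.push_back(s);
  expand(s);

  while ((int)lesion.size() < target && !frontier.empty()) {
    int pick = (int)(unif_rand() * frontier.size());
    if (pick >= (int)frontier.size()) pick = frontier.size() - 1;
    const int v = frontier[pick];
    frontier[pick] = frontier.back();
    frontier.pop_back();
    in_lesion[v] = 1;
    lesion.push_back(v);
    expand(v);
  }

  return IntegerVector(lesion.begin(), lesion.end()) + 1;
}
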