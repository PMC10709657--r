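#include <Rcpp.h>
#include <cstdint>
#include <vector>

// Incremental prefix-intersection cursor over two ranked lists.
//
// Each of the n aligned features has a fixed global index 0..n-1. A ranked
// list is a permutation of these indexes (most extreme feature first). The
// cursor keeps one bitset per list: bit k is set iff feature k lies inside
// the current prefix of that list. Moving the cursor from (i, j) to
// (i', j') toggles exactly |i - i'| + |j - j'| bits, and the running
// intersection count is maintained by checking the companion mask at each
// toggle, so a move is O(|di| + |dj|) with 64 features per machine word.

namespace {

class OverlapCursor {
public:
  OverlapCursor(const std::vector<int> &a_order,
                const std::vector<int> &b_order, int n)
      : a_order_(a_order), b_order_(b_order), n_(n), i_(0), j_(0), count_(0) {
    size_t words = (static_cast<size_t>(n) + 63) / 64;
    mask_a_.assign(words, 0ULL);
    mask_b_.assign(words, 0ULL);
  }

  int n() const { return n_; }
  int i() const { return i_; }
  int j() const { return j_; }
  long long count() const { return count_; }

  // Move to prefix lengths (ti, tj); returns the intersection count.
  long long move(int ti, int tj) {
    while (i_ < ti) { add(mask_a_, mask_b_, a_order_[i_]); ++i_; }
    while (i_ > ti) { --i_; drop(mask_a_, mask_b_, a_order_[i_]); }
    while (j_ < tj) { add(mask_b_, mask_a_, b_order_[j_]); ++j_; }
    while (j_ > tj) { --j_; drop(mask_b_, mask_a_, b_order_[j_]); }
    return count_;
  }

  // Popcount of the intersection recomputed from scratch (invariant check).
  long long recount() const {
    long long c = 0;
    for (size_t w = 0; w < mask_a_.size(); ++w) {
#if defined(__GNUC__) || defined(__clang__)
      c += __builtin_popcountll(mask_a_[w] & mask_b_[w]);
#else
      uint64_t x = mask_a_[w] & mask_b_[w];
      while (x) { x &= x - 1; ++c; }
#endif
    }
    return c;
  }

private:
  void add(std::vector<uint64_t> &mine, const std::vector<uint64_t> &other,
           int k) {
    uint64_t bit = 1ULL << (k & 63);
    mine[k >> 6] |= bit;
    if (other[k >> 6] & bit) ++count_;
  }
  void drop(std::vector<uint64_t> &mine, const std::vector<uint64_t> &other,
            int k) {
    uint64_t bit = 1ULL << (k & 63);
    mine[k >> 6] &= ~bit;
    if (other[k >> 6] & bit) --count_;
  }

  std::vector<int> a_order_, b_order_;
  int n_, i_, j_;
  long long count_;
  std::vector<uint64_t> mask_a_, mask_b_;
};

OverlapCursor *get(SEXP xp) {
  Rcpp::XPtr<OverlapCursor> p(xp);
  return p.get();
}

} // namespace

// [[Rcpp::export(name = ".cursor_new")]]
SEXP cursor_new(Rcpp::IntegerVector a_order, Rcpp::IntegerVector b_order) {
  int n = a_order.size();
  if (b_order.size() != n)
    Rcpp::stop("rank orders have different lengths (%d vs %d)", n,
               (int)b_order.size());
  std::vector<char> seen_a(n, 0), seen_b(n, 0);
  std::vector<int> a(n), b(n);
  for (int k = 0; k < n; ++k) {
    int fa = a_order[k] - 1, fb = b_order[k] - 1; // R is 1-based
    if (fa < 0 || fa >= n || fb < 0 || fb >= n)
      Rcpp::stop("rank orders must be permutations of 1..n");
    if (seen_a[fa]++ || seen_b[fb]++)
      Rcpp::stop("rank orders must be permutations of 1..n (duplicate index)");
    a[k] = fa;
    b[k] = fb;
  }
  Rcpp::XPtr<OverlapCursor> ptr(new OverlapCursor(a, b, n), true);
  return ptr;
}

// [[Rcpp::export(name = ".cursor_move")]]
double cursor_move(SEXP xp, int i, int j) {
  OverlapCursor *c = get(xp);
  if (i < 0 || j < 0 || i > c->n() || j > c->n())
    Rcpp::stop("coordinate (%d, %d) out of range [0, %d]", i, j, c->n());
  return static_cast<double>(c->move(i, j));
}

// [[Rcpp::export(name = ".cursor_state")]]
Rcpp::NumericVector cursor_state(SEXP xp) {
  OverlapCursor *c = get(xp);
  return Rcpp::NumericVector::create(
      Rcpp::Named("i") = c->i(), Rcpp::Named("j") = c->j(),
      Rcpp::Named("count") = static_cast<double>(c->count()),
      Rcpp::Named("popcount") = static_cast<double>(c->recount()));
}

// Batch evaluation: visits the coordinates in the order given (callers sort
// by (i, j) to bound bit updates) and returns the intersection count at each.
// [[Rcpp::export(name = ".cursor_counts")]]
Rcpp::NumericVector cursor_counts(SEXP xp, Rcpp::IntegerVector i,
                                  Rcpp::IntegerVector j) {
  OverlapCursor *c = get(xp);
  int m = i.size();
  if (j.size() != m) Rcpp::stop("i and j must have the same length");
  Rcpp::NumericVector out(m);
  for (int k = 0; k < m; ++k) {
    if (i[k] < 0 || j[k] < 0 || i[k] > c->n() || j[k] > c->n())
      Rcpp::stop("coordinate (%d, %d) out of range [0, %d]", i[k], j[k],
                 c->n());
    out[k] = static_cast<double>(c->move(i[k], j[k]));
  }
  return out;
}
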