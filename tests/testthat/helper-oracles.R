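# Brute-force frontier oracle: a point is on the upper-left frontier iff
# no single point or pair-interpolation attains strictly more QALYs at no
# more colonoscopies (flat extension beyond the last point).  O(n^3),
# independent of the hull construction it checks.
oracle_on_hull <- function(x, y, eps = 1e-9) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    best <- -Inf
    for (j in seq_len(n)) {
      if (j != i && x[j] <= x[i]) best <- max(best, y[j])
      for (k in seq_len(n)) {
        if (x[j] <= x[i] && x[i] <= x[k] && x[j] < x[k]) {
          v <- y[j] + (y[k] - y[j]) * (x[i] - x[j]) / (x[k] - x[j])
          best <- max(best, v)
        }
      }
    }
    y[i] >= best - eps
  }, logical(1))
}
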