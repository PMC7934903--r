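# fixtures and independent oracles used across the suite

make_disc <- function(r, n = 2 * r + 10) {
  c0 <- ceiling(n / 2)
  m <- matrix(0L, n, n)
  for (y in seq_len(n)) {
    for (x in seq_len(n)) {
      if ((x - c0)^2 + (y - c0)^2 <= r^2) m[y, x] <- 1L
    }
  }
  m
}

make_square_mask <- function(side, n = 64, x0 = 20, y0 = 20) {
  m <- matrix(0L, n, n)
  m[y0:(y0 + side - 1), x0:(x0 + side - 1)] <- 1L
  m
}

# exact null distribution of the Wilcoxon signed-rank statistic by
# enumeration of all 2^n sign patterns (ranks doubled so ties stay integer)
exact_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 16)
  r <- rank(abs(d)) * 2
  obs <- sum(r[d > 0])
  total <- sum(r)
  counts <- numeric(total + 1)
  counts[1] <- 1
  for (ri in r) {
    shifted <- c(rep(0, ri), counts[seq_len(length(counts) - ri)])
    counts <- counts + shifted
  }
  probs <- counts / 2^n
  mu <- total / 2
  dev <- abs(obs - mu)
  sum(probs[abs(seq(0, total) - mu) >= dev - 1e-9])
}

# exact two-group Kruskal-Wallis p by enumeration of group assignments
exact_kw_p <- function(g1, g2) {
  x <- c(g1, g2)
  n1 <- length(g1)
  N <- length(x)
  stopifnot(choose(N, n1) <= 2000)
  h_obs <- kruskal_wallis(list(g1, g2))$statistic
  cmb <- utils::combn(N, n1)
  hs <- apply(cmb, 2, function(idx) {
    kruskal_wallis(list(x[idx], x[-idx]))$statistic
  })
  mean(hs >= h_obs - 1e-9)
}

# naive Spearman: Pearson product-moment formula applied to ranks
spearman_naive <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# count connected components with an independent implementation (EBImage)
count_components <- function(m) {
  max(EBImage::bwlabel(m))
}

# one small mixed-shape constant-area library, built once per test run
shared_test_library <- local({
  lib <- NULL
  function() {
    if (is.null(lib)) {
      lib <<- build_stimulus_library(
        counts = 1:6, shapes = c("square", "diamond", "circle"),
        n_per_cell = 3, seed = 424242
      )
    }
    lib
  }
})
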