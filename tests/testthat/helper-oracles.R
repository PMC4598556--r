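# Independent oracles used to cross-check the package implementation.
# Each takes a deliberately different route from the code under test.

# Brute-force Brownian covariance: per-pair MRCA depth via ape::mrca and
# root-to-node path lengths (O(n^2), no call to ape::vcv).
bf_vcv <- function(tree) {
  n <- ape::Ntip(tree)
  depths <- ape::node.depth.edgelength(tree)
  m <- ape::mrca(tree)
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n))
    for (j in seq_len(n))
      C[i, j] <- if (i == j) depths[i] else depths[m[i, j]]
  C
}

# Exhaustive sign-test P: enumerate all 2^n equiprobable win/loss outcomes
# and count those with at least k wins. Feasible up to n ~ 21.
enum_sign_p <- function(k, n) {
  outcomes <- 0:(2^n - 1)
  wins <- integer(length(outcomes))
  for (b in 0:(n - 1))
    wins <- wins + bitwAnd(bitwShiftR(outcomes, b), 1L)
  sum(wins >= k) / length(outcomes)
}

# Direct-algebra GLS: explicit matrix inverses, no Cholesky whitening.
gls_direct <- function(y, X, V) {
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  res <- y - X %*% beta
  rss <- drop(t(res) %*% Vi %*% res)
  n <- length(y); k <- ncol(X)
  s2 <- rss / (n - k)
  se <- sqrt(s2 * diag(solve(t(X) %*% Vi %*% X)))
  list(beta = drop(beta), se = se, rss = rss)
}

# Random ultrametric test tree with safe tip labels.
rand_tree <- function(n, depth = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n, birth = log(n) / depth, death = 0)
  tr$edge.length <- tr$edge.length * depth /
    max(ape::node.depth.edgelength(tr)[seq_len(n)])
  tr$tip.label <- sprintf("t%03d", seq_len(n))
  tr
}

tree3 <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

tree6 <- function()
  ape::read.tree(text = "(((A:1,B:1):1,(C:1,D:1):1):1,(E:2,F:2):1);")
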