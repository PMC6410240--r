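# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity with the most naive possible code path so that the
# package implementation is checked against something it shares nothing with.

# All-offsets, both-strands ungapped alignment score by direct double loop.
brute_align_score <- function(read, ref, penalty = 1) {
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  best <- -Inf
  for (r in c(read, rc(read))) {
    rv <- strsplit(r, "")[[1]]
    fv <- strsplit(ref, "")[[1]]
    L <- length(rv); R <- length(fv)
    for (off in (-(L - 1)):(R - 1)) {
      s <- max(0, off); e <- min(R, off + L)
      idx <- (s + 1):e
      m <- sum(fv[idx] == rv[idx - off])
      mm <- length(idx) - m
      best <- max(best, m - penalty * mm)
    }
  }
  best
}

# Levene-Haldane exact p by enumeration over unnormalized weights
# w(h) = 2^h / (n_AA! h! n_BB!), normalized over feasible h.
brute_hwe_exact <- function(ndd, ndn, nnn) {
  n <- ndd + ndn + nnn
  nA <- 2 * ndd + ndn
  minor <- min(nA, 2 * n - nA)
  hs <- seq(minor %% 2, minor, by = 2)
  w <- vapply(hs, function(h) {
    exp(h * log(2) - lfactorial((nA - h) / 2) - lfactorial(h) -
          lfactorial((2 * n - nA - h) / 2))
  }, numeric(1))
  p <- w / sum(w)
  obs <- p[match(ndn, hs)]
  sum(p[p <= obs * (1 + 1e-7)])
}

# Two-sided Fisher p by enumeration of all tables with fixed margins.
brute_fisher_p <- function(x1, n1, x2, n2) {
  k <- x1 + x2
  lo <- max(0, k - n2); hi <- min(k, n1)
  probs <- dhyper(lo:hi, n1, n2, k)
  obs <- probs[x1 - lo + 1]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Cox partial log-likelihood for a single covariate, no tied event times.
brute_cox_loglik <- function(beta, time, status, x) {
  eta <- beta * x
  ll <- 0
  for (i in which(status == 1)) {
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

# Exact expected p-distance between two sequences derived from a common
# source by independent substitution passes (each pass: per-site prob r of
# switching to a uniformly chosen different base). `path1`, `path2` are
# vectors of per-pass substitution probabilities.
expected_p_distance <- function(path1, path2) {
  Mr <- function(r) {
    m <- matrix(r / 3, 4, 4); diag(m) <- 1 - r; m
  }
  chain <- function(path) Reduce(`%*%`, lapply(path, Mr), accumulate = FALSE)
  M1 <- chain(path1); M2 <- chain(path2)
  1 - sum(M1 * M2) / 4
}

# Random additive distance matrix from a random binary tree with positive
# branch lengths; returns the matrix and the generating tree.
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE,
                   br = function(k) runif(k, 0.05, 1))
  d <- ape::cophenetic.phylo(tr)
  d <- d[order(rownames(d)), order(colnames(d))]
  list(d = d, tree = tr)
}

# Orientation-free bipartition keys of a phylo tree over a fixed label order.
tree_split_keys <- function(tree, labels = sort(tree$tip.label)) {
  pp <- ape::prop.part(tree)
  n <- length(labels)
  keys <- vapply(pp, function(side) {
    idx <- sort(match(attr(pp, "labels")[side], labels))
    if (1 %in% idx) idx <- setdiff(seq_len(n), idx)
    paste(idx, collapse = ",")
  }, character(1))
  setdiff(unique(keys), c("", paste(seq_len(n), collapse = ",")))
}

# Balanced two-way cell-means ANOVA decomposition (classical closed form).
brute_anova_ss <- function(y, f1, f2) {
  gm <- mean(y)
  m1 <- tapply(y, f1, mean); m2 <- tapply(y, f2, mean)
  mc <- tapply(y, interaction(f1, f2), mean)
  n1 <- table(f1); n2 <- table(f2); nc <- table(interaction(f1, f2))
  ss1 <- sum(n1 * (m1 - gm)^2)
  ss2 <- sum(n2 * (m2 - gm)^2)
  cellf <- interaction(f1, f2)
  ssc <- sum(nc * (mc - gm)^2)
  list(ss1 = ss1, ss2 = ss2, ss_int = ssc - ss1 - ss2,
       ss_res = sum((y - mc[cellf])^2))
}
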