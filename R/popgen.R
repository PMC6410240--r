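#' Genotype count table constructor
#'
#' @param n_deldel,n_delnon,n_nonnon non-negative genotype counts
#'   (deletion homozygote, heterozygote, non-deletion homozygote).
#' @param stratum,sex stratum labels (collection and sex, or `"All"`).
#' @return data.frame of class `genotype_counts`.
#' @examples
#' genotype_counts(510, 96, 8, stratum = "All")
#' @export
genotype_counts <- function(n_deldel, n_delnon, n_nonnon,
                            stratum = "All", sex = "All") {
  stopifnot(all(c(n_deldel, n_delnon, n_nonnon) >= 0))
  out <- data.frame(stratum = stratum, sex = sex,
                    n_deldel = as.integer(n_deldel),
                    n_delnon = as.integer(n_delnon),
                    n_nonnon = as.integer(n_nonnon))
  class(out) <- c("genotype_counts", "data.frame")
  out
}

#' Deletion-allele frequency with binomial confidence interval
#'
#' Computes the allele frequency either from diploid genotype counts
#' (`counts`; the chromosome-level success count is `2 n_DelDel + n_DelNon`
#' out of `2n`) or directly from haploid calls (`x` deletion chromosomes out
#' of `n_chromosomes`, as for one-allele-per-line haploid-embryo data).
#' The confidence interval is Clopper-Pearson (exact, beta quantiles) by
#' default, or the Wilson score interval.
#'
#' @param counts a [genotype_counts()] row (rows are summed if several).
#' @param x,n_chromosomes haploid alternative to `counts`.
#' @param ci_method `"clopper_pearson"` or `"wilson"`.
#' @param level confidence level.
#' @return list (`frequency_estimate`) with `p_hat`, `n_chromosomes`,
#'   `ci_low`, `ci_high`, `ci_method`, `level`.
#' @examples
#' allele_frequency(genotype_counts(510, 96, 8))$p_hat       # 0.9088
#' allele_frequency(x = 5, n_chromosomes = 192)$ci_low       # ~0.0085
#' @export
allele_frequency <- function(counts = NULL, x = NULL, n_chromosomes = NULL,
                             ci_method = c("clopper_pearson", "wilson"),
                             level = 0.95) {
  ci_method <- match.arg(ci_method)
  if (!is.null(counts)) {
    stopifnot(is.data.frame(counts))
    x <- 2L * sum(counts$n_deldel) + sum(counts$n_delnon)
    n_chromosomes <- 2L * (sum(counts$n_deldel) + sum(counts$n_delnon) +
                             sum(counts$n_nonnon))
  }
  stopifnot(!is.null(x), !is.null(n_chromosomes))
  if (n_chromosomes < 1) stop("no chromosomes sampled")
  stopifnot(x >= 0, x <= n_chromosomes)
  ci <- binom_ci(x, n_chromosomes, level, ci_method)
  out <- list(p_hat = x / n_chromosomes, n_chromosomes = n_chromosomes,
              ci_low = ci[1], ci_high = ci[2],
              ci_method = ci_method, level = level)
  class(out) <- "frequency_estimate"
  out
}

binom_ci <- function(x, n, level, method) {
  a <- (1 - level) / 2
  if (method == "clopper_pearson") {
    lo <- if (x == 0) 0 else qbeta(a, x, n - x + 1)
    hi <- if (x == n) 1 else qbeta(1 - a, x + 1, n - x)
  } else { # wilson score
    z <- qnorm(1 - a)
    p <- x / n
    mid <- p + z^2 / (2 * n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
    den <- 1 + z^2 / n
    lo <- max(0, (mid - half) / den)
    hi <- min(1, (mid + half) / den)
  }
  c(lo, hi)
}

#' Hardy-Weinberg chi-squared test
#'
#' Compares observed genotype counts with the Hardy-Weinberg expectations
#' `n p^2, 2 n p q, n q^2` computed at the sample allele frequency. The
#' statistic has 1 degree of freedom (three categories, one estimated
#' parameter). Undefined for monomorphic samples.
#'
#' @param counts a [genotype_counts()] row.
#' @param yates apply Yates' continuity correction.
#' @return list (`hwe_result`) with `expected` (length-3), `chi2`, `df`,
#'   `p_chi2`.
#' @examples
#' hwe_chisq(genotype_counts(120, 22, 1))$p_chi2
#' @export
hwe_chisq <- function(counts, yates = FALSE) {
  o <- c(sum(counts$n_deldel), sum(counts$n_delnon), sum(counts$n_nonnon))
  n <- sum(o)
  if (n < 1) stop("empty sample")
  p <- (2 * o[1] + o[2]) / (2 * n)
  if (p == 0 || p == 1) stop("monomorphic sample: HWE test undefined")
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  dev <- abs(o - e)
  if (yates) dev <- pmax(0, dev - 0.5)
  chi2 <- sum(dev^2 / e)
  out <- list(expected = e, chi2 = chi2, df = 1L,
              p_chi2 = pchisq(chi2, df = 1, lower.tail = FALSE))
  class(out) <- "hwe_result"
  out
}

#' Hardy-Weinberg exact test (Levene-Haldane)
#'
#' Exact test conditioning on the sample size and the minor-allele count:
#' the heterozygote count under HWE follows the Levene-Haldane distribution
#' \deqn{P(h \mid n, n_A) = \frac{n!\, n_A!\, n_B!\, 2^h}
#'       {(2n)!\, n_{AA}!\, h!\, n_{BB}!}}
#' and the p-value sums the probabilities of all feasible heterozygote
#' counts whose conditional probability does not exceed that of the
#' observed count (with a small relative tolerance for ties).
#'
#' @param counts a [genotype_counts()] row.
#' @return list with `p_exact`, `observed_het`, `het_probs` (named vector of
#'   conditional probabilities over feasible heterozygote counts).
#' @examples
#' hwe_exact(genotype_counts(1, 0, 1))$p_exact  # 1/3
#' @export
hwe_exact <- function(counts) {
  o <- c(sum(counts$n_deldel), sum(counts$n_delnon), sum(counts$n_nonnon))
  n <- sum(o)
  nA <- 2 * o[1] + o[2]
  nB <- 2 * o[3] + o[2]
  if (nA == 0 || nB == 0) stop("monomorphic sample: HWE test undefined")
  minor <- min(nA, nB)
  hs <- seq(minor %% 2, minor, by = 2)
  logp <- lfactorial(n) + lfactorial(nA) + lfactorial(nB) + hs * log(2) -
    lfactorial(2 * n) - lfactorial((nA - hs) / 2) - lfactorial(hs) -
    lfactorial((nB - hs) / 2)
  probs <- exp(logp)
  obs <- probs[match(o[2], hs)]
  p <- sum(probs[probs <= obs * (1 + 1e-7)])
  list(p_exact = min(1, p), observed_het = o[2],
       het_probs = setNames(probs, hs))
}

#' Fisher exact test for two binomial samples
#'
#' Two-sided exact test on the 2x2 table of deletion/non-deletion
#' chromosome counts in two samples; the p-value sums hypergeometric
#' probabilities of all tables (fixed margins) no more likely than the
#' observed one. The unconditioned sample odds ratio is reported.
#'
#' @param x1,n1 deletion chromosomes and total chromosomes, sample 1.
#' @param x2,n2 same for sample 2.
#' @return list with `odds_ratio` (sample OR), `p_value`, `table`.
#' @examples
#' fisher_2x2(10, 20, 10, 20)$p_value  # 1
#' @export
fisher_2x2 <- function(x1, n1, x2, n2) {
  stopifnot(x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  if (n1 == 0 || n2 == 0) stop("empty sample")
  tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2, byrow = TRUE,
                dimnames = list(sample = c("s1", "s2"),
                                allele = c("del", "non")))
  p <- fisher.test(tab)$p.value
  or <- (x1 * (n2 - x2)) / ((n1 - x1) * x2)
  list(odds_ratio = or, p_value = min(1, p), table = tab)
}

#' Stratified frequency and Hardy-Weinberg report
#'
#' Reproduces the published table layout from a stratified genotype count
#' table: per-stratum allele frequency with confidence interval, both HWE
#' tests (chi-squared and exact) per stratum and pooled, an `"All"` row
#' (element-wise sum), and pairwise Fisher exact tests between strata and,
#' when a `sex` column distinguishes sexes, between sexes within stratum.
#'
#' @param counts a [genotype_counts()] data.frame (one row per stratum, or
#'   per stratum x sex).
#' @param ci_method,level passed to [allele_frequency()].
#' @return list with data.frames `frequencies`, `hwe`, `pairwise_strata`,
#'   `pairwise_sex`.
#' @examples
#' tab <- rbind(genotype_counts(160, 31, 3, "June 2016"),
#'              genotype_counts(120, 22, 1, "Sept 2016"))
#' seasonal_report(tab)$frequencies
#' @export
seasonal_report <- function(counts, ci_method = "clopper_pearson",
                            level = 0.95) {
  stopifnot(is.data.frame(counts), nrow(counts) >= 1)
  if (is.null(counts$sex)) counts$sex <- "All"
  strata <- unique(counts$stratum)

  by_stratum <- lapply(strata, function(s) {
    rows <- counts[counts$stratum == s, , drop = FALSE]
    genotype_counts(sum(rows$n_deldel), sum(rows$n_delnon), sum(rows$n_nonnon),
                    stratum = s)
  })
  all_row <- genotype_counts(sum(counts$n_deldel), sum(counts$n_delnon),
                             sum(counts$n_nonnon), stratum = "All")
  per <- c(by_stratum, list(all_row))

  freqs <- do.call(rbind, lapply(per, function(g) {
    fe <- allele_frequency(g, ci_method = ci_method, level = level)
    data.frame(stratum = g$stratum, n = g$n_deldel + g$n_delnon + g$n_nonnon,
               n_deldel = g$n_deldel, n_delnon = g$n_delnon,
               n_nonnon = g$n_nonnon, n_chromosomes = fe$n_chromosomes,
               p_hat = fe$p_hat, ci_low = fe$ci_low, ci_high = fe$ci_high)
  }))

  hwe <- do.call(rbind, lapply(per, function(g) {
    poly <- (2 * g$n_deldel + g$n_delnon) > 0 && (2 * g$n_nonnon + g$n_delnon) > 0
    data.frame(stratum = g$stratum,
               chi2 = if (poly) hwe_chisq(g)$chi2 else NA_real_,
               p_chi2 = if (poly) hwe_chisq(g)$p_chi2 else NA_real_,
               p_exact = if (poly) hwe_exact(g)$p_exact else NA_real_)
  }))

  chrom <- function(g) {
    x <- 2 * sum(g$n_deldel) + sum(g$n_delnon)
    n <- 2 * (sum(g$n_deldel) + sum(g$n_delnon) + sum(g$n_nonnon))
    c(x, n)
  }
  pairwise_strata <- NULL
  if (length(strata) >= 2) {
    cmb <- combn(seq_along(strata), 2)
    pairwise_strata <- do.call(rbind, apply(cmb, 2, function(ij) {
      a <- chrom(by_stratum[[ij[1]]]); b <- chrom(by_stratum[[ij[2]]])
      ft <- fisher_2x2(a[1], a[2], b[1], b[2])
      data.frame(stratum1 = strata[ij[1]], stratum2 = strata[ij[2]],
                 odds_ratio = ft$odds_ratio, p_value = ft$p_value)
    }, simplify = FALSE))
  }

  pairwise_sex <- NULL
  sexes <- setdiff(unique(counts$sex), "All")
  if (length(sexes) == 2) {
    pairwise_sex <- do.call(rbind, lapply(strata, function(s) {
      a <- counts[counts$stratum == s & counts$sex == sexes[1], , drop = FALSE]
      b <- counts[counts$stratum == s & counts$sex == sexes[2], , drop = FALSE]
      if (!nrow(a) || !nrow(b)) return(NULL)
      ca <- chrom(a); cb <- chrom(b)
      ft <- fisher_2x2(ca[1], ca[2], cb[1], cb[2])
      data.frame(stratum = s, sex1 = sexes[1], sex2 = sexes[2],
                 odds_ratio = ft$odds_ratio, p_value = ft$p_value)
    }))
  }

  list(frequencies = freqs, hwe = hwe,
       pairwise_strata = pairwise_strata, pairwise_sex = pairwise_sex)
}
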