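#' Average technical replicates of a Ct table
#'
#' Collapses technical replicates to one Ct pair per biological replicate by
#' the arithmetic mean, per gene. Replicates with a missing target or
#' reference Ct are dropped with a warning.
#'
#' @param ct a `ct_table` data.frame (columns `background`, `genotype`,
#'   `bio_rep`, `tech_rep`, `ct_target`, `ct_ref`).
#' @return data.frame with one row per (background, genotype, bio_rep) and
#'   columns `ct_target`, `ct_ref`.
#' @examples
#' ct <- simulate_qpcr(sim_config(seed = 1))
#' nrow(collapse_technical(ct))  # one row per biological replicate
#' @export
collapse_technical <- function(ct) {
  stopifnot(all(c("background", "genotype", "bio_rep",
                  "ct_target", "ct_ref") %in% names(ct)))
  bad <- !is.finite(ct$ct_target) | !is.finite(ct$ct_ref)
  if (any(bad)) {
    warning(sum(bad), " technical measurement(s) with missing Ct dropped")
    ct <- ct[!bad, , drop = FALSE]
  }
  out <- aggregate(cbind(ct_target, ct_ref) ~ background + genotype + bio_rep,
                   data = ct, FUN = mean)
  out[order(out$background, out$genotype, out$bio_rep), , drop = FALSE]
}

#' Per-replicate relative expression by the delta-delta-Ct method
#'
#' For each biological replicate, `delta_ct = ct_target - ct_ref`
#' (normalization by the reference gene), then
#' `delta_delta_ct = delta_ct - mean(delta_ct)` of the calibrator group
#' within the same background, and `fold = 2^(-delta_delta_ct)` (classic
#' assumption of amplification efficiency 2). With the non-deletion group as
#' calibrator, the calibrator group's geometric-mean fold is exactly 1.
#'
#' @param ct_collapsed output of [collapse_technical()].
#' @param calibrator genotype level used as calibrator within background.
#' @return the input with added columns `delta_ct`, `delta_delta_ct`,
#'   `fold`.
#' @examples
#' ct <- collapse_technical(simulate_qpcr(sim_config(seed = 1)))
#' rel <- relative_expression(ct)
#' @export
relative_expression <- function(ct_collapsed, calibrator = "non_deletion") {
  stopifnot(calibrator %in% ct_collapsed$genotype)
  out <- ct_collapsed
  out$delta_ct <- out$ct_target - out$ct_ref
  out$delta_delta_ct <- NA_real_
  for (bg in unique(out$background)) {
    sel <- out$background == bg
    cal <- sel & out$genotype == calibrator
    if (!any(cal)) stop("no calibrator replicates in background ", bg)
    out$delta_delta_ct[sel] <- out$delta_ct[sel] - mean(out$delta_ct[cal])
  }
  out$fold <- 2^(-out$delta_delta_ct)
  out
}

#' Fold change of the deletion genotype per background
#'
#' Group-level delta-delta-Ct estimate:
#' `fold = 2^(mean delta_ct[non-deletion] - mean delta_ct[deletion])` within
#' each background.
#'
#' @param ct_collapsed output of [collapse_technical()].
#' @return data.frame with `background`, `fold`, `n_del`, `n_non`.
#' @examples
#' ct <- collapse_technical(simulate_qpcr(sim_config(seed = 1)))
#' ddct_fold(ct)
#' @export
ddct_fold <- function(ct_collapsed) {
  dct <- ct_collapsed$ct_target - ct_collapsed$ct_ref
  do.call(rbind, lapply(unique(ct_collapsed$background), function(bg) {
    sel <- ct_collapsed$background == bg
    del <- sel & ct_collapsed$genotype == "deletion"
    non <- sel & ct_collapsed$genotype == "non_deletion"
    if (!any(del) || !any(non)) stop("empty genotype group in background ", bg)
    data.frame(background = bg,
               fold = 2^(mean(dct[non]) - mean(dct[del])),
               n_del = sum(del), n_non = sum(non))
  }))
}

#' Two-factor ANOVA of relative expression
#'
#' Least-squares two-way ANOVA of per-replicate relative expression on
#' genetic background and genotype with their interaction, using Type II
#' sums of squares (robust to the mild unbalance of 25-28 replicates per
#' cell; equal to the classical decomposition on balanced data). The
#' response is the per-replicate fold change by default, or its log2.
#'
#' @param relexp output of [relative_expression()].
#' @param response `"fold"` or `"log2"`.
#' @return data.frame (`anova_table`) with one row per term (background,
#'   genotype, interaction, residual): `sum_sq`, `df`, `F`, `p`, `eta_sq`
#'   (share of the total sum of squares).
#' @examples
#' rel <- relative_expression(collapse_technical(simulate_qpcr(sim_config(seed = 1))))
#' two_factor_anova(rel)
#' @export
two_factor_anova <- function(relexp, response = c("fold", "log2")) {
  response <- match.arg(response)
  y <- if (response == "log2") log2(relexp$fold) else relexp$fold
  d <- data.frame(y = y, background = factor(relexp$background),
                  genotype = factor(relexp$genotype))
  stopifnot(nlevels(d$background) >= 2 || nlevels(d$genotype) >= 2)
  cells <- table(d$background, d$genotype)
  form <- if (any(cells == 0)) {
    warning("empty cell(s): interaction term dropped")
    y ~ background + genotype
  } else {
    y ~ background * genotype
  }
  fit <- lm(form, data = d)
  a2 <- car::Anova(fit, type = 2)
  ss_total <- sum((y - mean(y))^2)
  nm <- rownames(a2)
  nm[nm == "background:genotype"] <- "interaction"
  nm[nm == "Residuals"] <- "residual"
  out <- data.frame(term = nm, sum_sq = a2[["Sum Sq"]], df = a2[["Df"]],
                    F = a2[["F value"]], p = a2[["Pr(>F)"]],
                    eta_sq = a2[["Sum Sq"]] / ss_total)
  rownames(out) <- NULL
  out
}

#' Share of expression variance explained by genotype
#'
#' One-way decomposition: `SS_between / SS_total` for a two-group genotype
#' factor, equal to the squared point-biserial correlation.
#'
#' @param values numeric expression values.
#' @param genotype group labels (two non-empty groups).
#' @return eta-squared in `[0, 1]`.
#' @examples
#' variance_explained(c(1, 2, 3, 7, 8, 9), rep(c("a", "b"), each = 3))
#' @export
variance_explained <- function(values, genotype) {
  stopifnot(length(values) == length(genotype))
  keep <- is.finite(values) & !is.na(genotype)
  values <- values[keep]; genotype <- genotype[keep]
  g <- unique(genotype)
  stopifnot(length(g) == 2)
  ss_total <- sum((values - mean(values))^2)
  if (ss_total == 0) stop("zero total variance")
  ss_between <- sum(tapply(values, genotype, function(v)
    length(v) * (mean(v) - mean(values))^2))
  ss_between / ss_total
}
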