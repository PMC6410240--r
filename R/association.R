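#' Collapse expression replicates and apply the exclusion rule
#'
#' Averages the two per-line expression replicates within sex and excludes
#' lines with only one reported replicate in either sex (the published
#' exclusion rule for the array data).
#'
#' @param panel data.frame as from [simulate_stress_panel()] (columns
#'   `line_id`, `genotype`, `sex`, `expression_rep1`, `expression_rep2`, and
#'   optionally survival columns).
#' @return the panel with a single `expression` column (mean of the two
#'   replicates); lines failing the rule are removed with a message.
#' @examples
#' panel <- simulate_stress_panel(sim_config(seed = 1))
#' ph <- collapse_expression(panel)
#' @export
collapse_expression <- function(panel) {
  ok_row <- is.finite(panel$expression_rep1) & is.finite(panel$expression_rep2)
  bad_lines <- unique(panel$line_id[!ok_row])
  if (length(bad_lines)) {
    message("excluding ", length(bad_lines),
            " line(s) with a single expression replicate")
    panel <- panel[!panel$line_id %in% bad_lines, , drop = FALSE]
  }
  panel$expression <- (panel$expression_rep1 + panel$expression_rep2) / 2
  panel
}

#' t test of expression between genotypes, per sex
#'
#' Pooled-variance Student's t test (Welch optional) of log2 expression
#' between deletion and non-deletion lines, with the fold change computed as
#' `2^(mean_del - mean_non)` since expression is on the log2 scale.
#'
#' @param expression numeric log2 expression values (one per line).
#' @param genotype `"deletion"` / `"non_deletion"` per line.
#' @param sex optional sex labels; when given, one test per sex.
#' @param welch use Welch's unequal-variance t test.
#' @return data.frame with one row per sex (or a single `"all"` row):
#'   `sex`, `n_del`, `n_non`, `fold`, `t`, `df`, `p`.
#' @examples
#' set.seed(1)
#' g <- rep(c("deletion", "non_deletion"), each = 20)
#' e <- rnorm(40) + 0.5 * (g == "deletion")
#' expression_ttest(e, g)
#' @export
expression_ttest <- function(expression, genotype, sex = NULL, welch = FALSE) {
  if (is.null(sex)) sex <- rep("all", length(expression))
  stopifnot(length(expression) == length(genotype),
            length(sex) == length(expression))
  do.call(rbind, lapply(unique(sex), function(s) {
    e <- expression[sex == s]; g <- genotype[sex == s]
    del <- e[g == "deletion"]; non <- e[g == "non_deletion"]
    if (length(del) < 2 || length(non) < 2)
      stop("need >= 2 lines per genotype group")
    tt <- t.test(del, non, var.equal = !welch)
    data.frame(sex = s, n_del = length(del), n_non = length(non),
               fold = 2^(mean(del) - mean(non)),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  }))
}

#' Spearman rank correlation of expression and survival
#'
#' Mid-rank (average ranks for ties) Spearman correlation with the
#' t-approximation p-value on `n - 2` degrees of freedom.
#'
#' @param expression,survival paired numeric vectors (n >= 4).
#' @return list with `rho`, `p_value`, `n`.
#' @examples
#' spearman_cor(1:10, (1:10)^2)$rho  # 1
#' @export
spearman_cor <- function(expression, survival) {
  keep <- is.finite(expression) & is.finite(survival)
  expression <- expression[keep]; survival <- survival[keep]
  n <- length(expression)
  stopifnot(n >= 4)
  if (length(unique(expression)) < 2 || length(unique(survival)) < 2)
    stop("constant vector: Spearman correlation undefined")
  ct <- suppressWarnings(
    cor.test(expression, survival, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Cox proportional-hazards association of genotype with survival
#'
#' Fits a Cox model of survival time on sex and genotype, optionally with
#' line entered as treatment-coded indicator terms or as strata. Ties are
#' handled by the Efron method by default (Breslow available). Note that in
#' an inbred-line panel the genotype is constant within line, so genotype
#' and a full set of line indicators are collinear; the fitter's singularity
#' handling then drops aliased line terms, and the stratified form is the
#' cleaner way to adjust for line while keeping genotype estimable only
#' through between-line contrasts (see the package vignette). The default
#' is therefore `line_effect = "none"`.
#'
#' @param records data.frame with columns `survival_hours`, `event`, `sex`,
#'   `genotype`, and `line_id` when a line effect is requested.
#' @param line_effect `"none"`, `"factor"`, or `"strata"`.
#' @param ties `"efron"` or `"breslow"`.
#' @return list (`cox_fit`) with `coefficients` (data.frame: `term`,
#'   `coef`, `se`, `hazard_ratio`, `z`, `p`), `loglik` (log partial
#'   likelihood at the estimate), `ties`, `converged`, and the underlying
#'   `survival::coxph` fit as `fit`.
#' @examples
#' panel <- simulate_stress_panel(sim_config(seed = 1))
#' msb <- panel[panel$agent == "MSB", ]
#' cox_ph(msb)$coefficients
#' @export
cox_ph <- function(records, line_effect = c("none", "factor", "strata"),
                   ties = c("efron", "breslow")) {
  line_effect <- match.arg(line_effect)
  ties <- match.arg(ties)
  stopifnot(all(c("survival_hours", "event", "sex", "genotype") %in%
                  names(records)))
  if (sum(records$event) < 2) stop("need >= 2 observed event times")
  d <- records
  d$sex <- factor(d$sex)
  d$genotype <- factor(d$genotype, levels = c("non_deletion", "deletion"))
  d$genotype <- droplevels(d$genotype)
  if (nlevels(d$genotype) < 2) stop("genotype is constant: nothing to test")
  rhs <- if (nlevels(d$sex) >= 2) "sex + genotype" else "genotype"
  if (line_effect == "factor") rhs <- paste(rhs, "+ factor(line_id)")
  if (line_effect == "strata") rhs <- paste(rhs, "+ strata(line_id)")
  form <- stats::as.formula(paste("survival::Surv(survival_hours, event) ~", rhs))
  fit <- survival::coxph(form, data = d, ties = ties)
  cf <- summary(fit)$coefficients
  converged <- is.finite(fit$loglik[2]) && all(is.finite(coef(fit)) | is.na(coef(fit)))
  if (any(!is.finite(cf[, "se(coef)"])))
    warning("infinite standard error: possible monotone likelihood / separation")
  coefs <- data.frame(term = rownames(cf), coef = cf[, "coef"],
                      se = cf[, "se(coef)"],
                      hazard_ratio = cf[, "exp(coef)"],
                      z = cf[, "z"], p = cf[, "Pr(>|z|)"])
  rownames(coefs) <- NULL
  out <- list(coefficients = coefs, loglik = fit$loglik[2], ties = ties,
              converged = converged, fit = fit)
  class(out) <- "cox_fit"
  out
}

#' Per-agent association summary
#'
#' Tabulates, for each oxidative-stress agent, the Spearman correlation of
#' expression with survival and the Cox genotype effect, declaring for which
#' agent each association is significant at `alpha`. Computes no new
#' statistics beyond [spearman_cor()] and [cox_ph()].
#'
#' @param panel data.frame as from [simulate_stress_panel()] after
#'   [collapse_expression()] (needs `expression`; one row per line x sex x
#'   agent).
#' @param agents agents expected in the panel; a missing agent yields a
#'   partial report with a warning.
#' @param alpha significance level for the verdict columns.
#' @param line_effect,ties passed to [cox_ph()].
#' @return data.frame with one row per agent: `agent`, `rho`, `rho_p`,
#'   `genotype_hr`, `genotype_p`, `expression_significant`,
#'   `genotype_significant`.
#' @examples
#' panel <- collapse_expression(simulate_stress_panel(sim_config(seed = 1)))
#' agent_contrast(panel)
#' @export
agent_contrast <- function(panel, agents = c("MSB", "paraquat"), alpha = 0.05,
                           line_effect = "none", ties = "efron") {
  if (is.null(panel$expression))
    panel <- collapse_expression(panel)
  present <- intersect(agents, unique(panel$agent))
  missing <- setdiff(agents, present)
  if (length(missing))
    warning("agent(s) missing from panel: ", paste(missing, collapse = ", "))
  do.call(rbind, lapply(present, function(a) {
    d <- panel[panel$agent == a, , drop = FALSE]
    sp <- spearman_cor(d$expression, d$survival_hours)
    cx <- cox_ph(d, line_effect = line_effect, ties = ties)
    gr <- cx$coefficients[cx$coefficients$term == "genotypedeletion", ]
    data.frame(agent = a, rho = sp$rho, rho_p = sp$p_value,
               genotype_hr = gr$hazard_ratio, genotype_p = gr$p,
               expression_significant = sp$p_value < alpha,
               genotype_significant = gr$p < alpha)
  }))
}
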