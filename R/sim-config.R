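#' Simulation configuration
#'
#' Bundles every tunable parameter of the synthetic-data generators into one
#' validated object. All generators are deterministic given `seed`: the same
#' configuration produces byte-identical output on every run.
#'
#' The defaults emulate the study conditions of the source data sets: 150-bp
#' reads from haploid embryos at modest locus coverage; a deletion-allele
#' frequency around 0.9 as observed in temperate European collections; qPCR
#' with 26 biological and 2 technical replicates and per-background fold
#' effects of 1.20 (M9) and 1.85 (M12); survival on two oxidative-stress
#' agents with a protective deletion effect on MSB only; and a 15-kb
#' two-population alignment at 5% between-population divergence, 0.5%
#' within-population diversity, 5 migrant haplotypes, and two distant
#' outgroups.
#'
#' @param seed integer seed controlling all randomness downstream.
#' @param read_length_range integer pair, min and max read length (bp).
#' @param paired logical; emit read pairs from fragment ends instead of
#'   single reads.
#' @param coverage expected number of reads overlapping the indel locus per
#'   line.
#' @param error_rate per-base substitution error probability.
#' @param p_del deletion-allele frequency in `[0, 1]`.
#' @param inbreeding_f Wright's F in `[-1, 1]` used for genotype simulation.
#' @param qpcr list of qPCR model parameters: `baseline_target`,
#'   `baseline_ref` (cycles), `effect` (named per-background genotype effect
#'   on the target Ct, in cycles, i.e. log2 fold change), `bio_sd`, `tech_sd`
#'   (cycles), `n_bio`, `n_tech` (replicate counts).
#' @param survival list of survival model parameters: `n_lines`,
#'   `baseline_hours` (exponential mean survival), `hr_genotype` (named per
#'   agent, hazard ratio of the deletion allele), `hr_male` (hazard ratio of
#'   males vs females), `censor_hours` (administrative censoring time),
#'   `expr_effect` (log2 expression increase of deletion lines), `expr_sd`,
#'   `expr_male_shift` (log2 male-vs-female expression shift).
#' @param alignment list of alignment model parameters: `n_per_pop`,
#'   `length_bp`, `divergence` (expected between-population p-distance from
#'   the split), `diversity` (expected within-population p-distance),
#'   `n_migrants` (population-B haplotypes relabelled as population A),
#'   `n_outgroups`, `outgroup_divergence`.
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, coverage = 10)
#' cfg$qpcr$n_bio
#' @export
sim_config <- function(seed = 1L,
                       read_length_range = c(150L, 150L),
                       paired = FALSE,
                       coverage = 20,
                       error_rate = 0.001,
                       p_del = 0.9,
                       inbreeding_f = 0,
                       qpcr = list(),
                       survival = list(),
                       alignment = list()) {
  qpcr_def <- list(baseline_target = 22, baseline_ref = 18,
                   effect = c(M9 = log2(1.20), M12 = log2(1.85)),
                   bio_sd = 0.3, tech_sd = 0.1, n_bio = 26L, n_tech = 2L)
  surv_def <- list(n_lines = 146L, baseline_hours = 60,
                   hr_genotype = c(MSB = 0.6, paraquat = 1.0),
                   hr_male = 0.7, censor_hours = 500,
                   expr_effect = log2(1.4), expr_sd = 0.4,
                   expr_male_shift = log2(1.67))
  aln_def <- list(n_per_pop = 20L, length_bp = 15000L, divergence = 0.05,
                  diversity = 0.005, n_migrants = 5L, n_outgroups = 2L,
                  outgroup_divergence = 0.15)
  cfg <- list(seed = as.integer(seed),
              read_length_range = as.integer(read_length_range),
              paired = isTRUE(paired),
              coverage = coverage,
              error_rate = error_rate,
              p_del = p_del,
              inbreeding_f = inbreeding_f,
              qpcr = utils::modifyList(qpcr_def, qpcr),
              survival = utils::modifyList(surv_def, survival),
              alignment = utils::modifyList(aln_def, alignment))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    length(cfg$seed) == 1L, is.finite(cfg$seed),
    length(cfg$read_length_range) == 2L,
    all(cfg$read_length_range >= 1L),
    cfg$read_length_range[1] <= cfg$read_length_range[2],
    cfg$coverage > 0,
    cfg$error_rate >= 0, cfg$error_rate <= 1,
    cfg$p_del >= 0, cfg$p_del <= 1,
    cfg$inbreeding_f >= -1, cfg$inbreeding_f <= 1
  )
  with(cfg$qpcr, stopifnot(bio_sd >= 0, tech_sd >= 0, n_bio >= 1, n_tech >= 1))
  with(cfg$survival, stopifnot(n_lines >= 1, baseline_hours > 0,
                               all(hr_genotype > 0), hr_male > 0,
                               censor_hours > 0, expr_sd >= 0))
  with(cfg$alignment, stopifnot(n_per_pop >= 1, length_bp >= 1,
                                divergence >= 0, divergence <= 1,
                                diversity >= 0, diversity <= 1,
                                n_migrants >= 0, n_migrants <= n_per_pop,
                                n_outgroups >= 0,
                                outgroup_divergence >= 0,
                                outgroup_divergence <= 1))
  invisible(cfg)
}
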