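#' Simulate a qPCR Ct table
#'
#' Generates cycle-threshold measurements for a target gene (MtnA) and a
#' reference gene (RpL32) across genetic backgrounds, genotypes, biological
#' and technical replicates, under the additive model
#' \deqn{Ct_{ref} = \mu_{ref} + b, \qquad
#'       Ct_{target} = \mu_{target} - \beta_{bg}\,[genotype = deletion] + b'}
#' where \eqn{b, b'} are independent biological-replicate normals with sd
#' `bio_sd`, and every technical replicate adds independent Normal(0,
#' `tech_sd`) noise to each gene. The genotype effect \eqn{\beta_{bg}} is in
#' cycles, i.e. equals the log2 of the true fold change, so the default
#' effects correspond to folds of 1.20 (M9) and 1.85 (M12).
#'
#' @param config a [sim_config()]; uses `seed` and the `qpcr` block.
#' @return a `ct_table` data.frame with columns `background`, `genotype`,
#'   `bio_rep`, `tech_rep`, `ct_target`, `ct_ref`.
#' @examples
#' ct <- simulate_qpcr(sim_config(seed = 1))
#' head(ct)
#' @export
simulate_qpcr <- function(config = sim_config()) {
  q <- config$qpcr
  backgrounds <- names(q$effect) %||% paste0("B", seq_along(q$effect))
  withr::with_seed(config$seed, {
    rows <- list()
    for (bg in seq_along(q$effect)) {
      for (geno in c("deletion", "non_deletion")) {
        eff <- if (geno == "deletion") q$effect[[bg]] else 0
        for (b in seq_len(q$n_bio)) {
          bio_t <- q$baseline_target - eff + rnorm(1, 0, q$bio_sd)
          bio_r <- q$baseline_ref + rnorm(1, 0, q$bio_sd)
          rows[[length(rows) + 1L]] <- data.frame(
            background = backgrounds[bg], genotype = geno, bio_rep = b,
            tech_rep = seq_len(q$n_tech),
            ct_target = bio_t + rnorm(q$n_tech, 0, q$tech_sd),
            ct_ref = bio_r + rnorm(q$n_tech, 0, q$tech_sd))
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("ct_table", "data.frame")
    out
  })
}
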