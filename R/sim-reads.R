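#' Construct the dual allele references for the indel locus
#'
#' Builds the two reference sequences used for read-based allele calling:
#' the deletion reference is the concatenation of the upstream and downstream
#' flanks; the non-deletion reference carries `indel_length` extra bases (the
#' insertion) between the same flanks. The defaults reproduce the 90-bp
#' deletion reference (49 bp upstream + 41 bp downstream of the deletion
#' site) and 139-bp non-deletion reference used to genotype the MtnA 3' UTR
#' indel.
#'
#' Junction coordinates are 0-based: the deletion allele stores the single
#' inter-base junction position (equal to the upstream flank length), the
#' non-deletion allele the half-open interval `[start, end)` covering the
#' inserted bases. Outside that interval the two sequences are identical.
#'
#' @param upstream_flank,downstream_flank flank lengths in bp (>= 1).
#' @param indel_length length of the inserted/deleted segment in bp.
#' @param context optional DNA string giving the full non-deletion sequence
#'   (length `upstream_flank + indel_length + downstream_flank`); when absent
#'   the sequence is drawn uniformly over A/C/G/T.
#' @param seed integer seed used when `context` is absent.
#' @return a list of class `allele_reference_pair` with elements `deletion`
#'   and `non_deletion`, each a list with `allele_id`, `sequence`, and either
#'   `junction` (deletion) or `interval` (non-deletion). The genomic location
#'   of the real locus (chromosome 3R, 1-based inclusive) is attached as
#'   attribute `genomic_interval` for provenance only.
#' @examples
#' refs <- make_references(seed = 1)
#' nchar(refs$deletion$sequence)      # 90
#' nchar(refs$non_deletion$sequence)  # 139
#' @export
make_references <- function(upstream_flank = 49L, downstream_flank = 41L,
                            indel_length = 49L, context = NULL, seed = 1L) {
  stopifnot(upstream_flank >= 1, downstream_flank >= 1, indel_length >= 1)
  total <- upstream_flank + indel_length + downstream_flank
  if (is.null(context)) {
    context <- withr::with_seed(seed, random_dna(total))
  } else {
    if (!is_dna(context))
      stop("`context` contains non-DNA characters")
    if (nchar(context) != total)
      stop("`context` must have length upstream + indel + downstream = ", total)
    context <- toupper(context)
  }
  up <- substr(context, 1L, upstream_flank)
  ins <- substr(context, upstream_flank + 1L, upstream_flank + indel_length)
  down <- substr(context, upstream_flank + indel_length + 1L, total)
  refs <- list(
    deletion = list(allele_id = "deletion",
                    sequence = paste0(up, down),
                    junction = upstream_flank),
    non_deletion = list(allele_id = "non_deletion",
                        sequence = context,
                        interval = c(upstream_flank, upstream_flank + indel_length))
  )
  attr(refs, "genomic_interval") <- "3R:9,783,407-9,784,370"
  class(refs) <- "allele_reference_pair"
  refs
}

#' Simulate short reads from one fly line at the indel locus
#'
#' Draws reads from the chosen allele embedded in a 2-kb genomic context
#' centred on the indel, so that most reads do not span the junction and the
#' informative-read filter of the classifier is exercised. Substitution
#' errors are applied per base at `config$error_rate`; quality strings are
#' constant (`"I"`, Phred 40). Half of the reads (in expectation) are
#' reverse-complemented. `genotype = "mixed"` draws each read's template
#' allele independently: with probability `mixed_fraction` the deletion
#' haplotype, otherwise the non-deletion haplotype (emulating residual
#' polymorphism in pooled inbred-line sequencing).
#'
#' The total read count is chosen so that the expected number of reads
#' overlapping the junction equals `config$coverage`. With
#' `config$paired = TRUE` each template yields a mate pair drawn from the two
#' ends of a fragment (twice the read length), classified downstream as
#' independent reads.
#'
#' @param genotype `"deletion"`, `"non_deletion"`, or `"mixed"`.
#' @param refs an [make_references()] pair.
#' @param config a [sim_config()]; uses `seed`, `read_length_range`,
#'   `paired`, `coverage` and `error_rate`.
#' @param mixed_fraction deletion-allele fraction for `genotype = "mixed"`.
#' @param line_id label used to form read ids.
#' @return data.frame with columns `read_id`, `sequence`, `quality`.
#' @examples
#' refs <- make_references(seed = 1)
#' reads <- simulate_line_reads("deletion", refs, sim_config(seed = 2, coverage = 5))
#' head(reads$sequence, 2)
#' @export
simulate_line_reads <- function(genotype = c("deletion", "non_deletion", "mixed"),
                                refs, config = sim_config(),
                                mixed_fraction = 0.5, line_id = "line") {
  genotype <- match.arg(genotype)
  stopifnot(inherits(refs, "allele_reference_pair"), config$coverage > 0)
  if (genotype == "mixed" &&
      (!is.numeric(mixed_fraction) || mixed_fraction < 0 || mixed_fraction > 1))
    stop("`mixed_fraction` must be in [0, 1]")

  # The flanking context gets its own RNG stream (scrambled seed) so that a
  # reference pair and a read set built from the same integer seed never
  # share a stream prefix -- otherwise the context would start with the
  # reference sequence itself, planting a spurious allele copy in the
  # simulated genome.
  ctx_seed <- as.integer((as.double(config$seed) * 2654435761) %% 2147483647)
  ctx <- withr::with_seed(ctx_seed, {
    non_len <- nchar(refs$non_deletion$sequence)
    pad <- max(0L, (2000L - non_len) %/% 2L)
    list(left = random_dna(pad), right = random_dna(pad), pad = pad)
  })
  withr::with_seed(config$seed, {
    # shared 2-kb context; the allele sits in the middle
    left <- ctx$left
    right <- ctx$right
    pad <- ctx$pad
    hap <- c(deletion = paste0(left, refs$deletion$sequence, right),
             non_deletion = paste0(left, refs$non_deletion$sequence, right))
    # junction midpoint within each haplotype (0-based)
    jpos <- c(deletion = pad + refs$deletion$junction,
              non_deletion = pad + mean(refs$non_deletion$interval))

    lmin <- config$read_length_range[1]
    lmax <- config$read_length_range[2]
    lbar <- (lmin + lmax) / 2
    w <- nchar(hap[["deletion"]])
    n_reads <- max(1L, as.integer(round(config$coverage * (w - lbar + 1) / lbar)))

    allele <- switch(genotype,
      deletion = rep("deletion", n_reads),
      non_deletion = rep("non_deletion", n_reads),
      mixed = ifelse(runif(n_reads) < mixed_fraction, "deletion", "non_deletion"))

    out_seq <- character(0)
    out_id <- character(0)
    k <- 0L
    for (i in seq_len(n_reads)) {
      tmpl <- hap[[allele[i]]]
      tl <- nchar(tmpl)
      len <- if (lmin == lmax) lmin else sample(lmin:lmax, 1L)
      if (config$paired) {
        frag <- min(tl, 2L * len)
        start <- sample.int(tl - frag + 1L, 1L)
        r1 <- substr(tmpl, start, start + len - 1L)
        r2 <- revcomp(substr(tmpl, start + frag - len, start + frag - 1L))
        out_seq <- c(out_seq, apply_errors(r1, config$error_rate),
                     apply_errors(r2, config$error_rate))
        k <- k + 1L
        out_id <- c(out_id, sprintf("%s_%04d/1", line_id, k),
                    sprintf("%s_%04d/2", line_id, k))
      } else {
        start <- sample.int(tl - len + 1L, 1L)
        r <- substr(tmpl, start, start + len - 1L)
        if (runif(1) < 0.5) r <- revcomp(r)
        k <- k + 1L
        out_seq <- c(out_seq, apply_errors(r, config$error_rate))
        out_id <- c(out_id, sprintf("%s_%04d", line_id, k))
      }
    }
    data.frame(read_id = out_id, sequence = out_seq,
               quality = strrep("I", nchar(out_seq)))
  })
}

# Per-base substitution errors: each base replaced, with prob `rate`, by a
# uniformly chosen different base.
apply_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  v <- dna_to_int(seq)
  hit <- which(runif(length(v)) < rate & v > 0L)
  if (length(hit)) {
    v[hit] <- ((v[hit] - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L
  }
  int_to_dna(v)
}

#' Simulate genotype counts for a wild-caught sample
#'
#' Draws (Del/Del, Del/Non, Non/Non) counts from the multinomial with
#' genotype probabilities `p^2 + F p q`, `2 p q (1 - F)`, `q^2 + F p q`,
#' i.e. Hardy-Weinberg proportions deformed by Wright's inbreeding
#' coefficient F.
#'
#' @param p_del deletion-allele frequency.
#' @param n_individuals sample size.
#' @param inbreeding_f Wright's F; must leave all three probabilities
#'   non-negative for the given `p_del`.
#' @param seed integer seed.
#' @param stratum,sex labels attached to the output row.
#' @return a one-row [genotype_counts()] data.frame.
#' @examples
#' simulate_population(0.9, 200, seed = 1)
#' @export
simulate_population <- function(p_del, n_individuals, inbreeding_f = 0,
                                seed = 1L, stratum = "sim", sex = "All") {
  stopifnot(p_del >= 0, p_del <= 1, n_individuals >= 1)
  q <- 1 - p_del
  probs <- c(p_del^2 + inbreeding_f * p_del * q,
             2 * p_del * q * (1 - inbreeding_f),
             q^2 + inbreeding_f * p_del * q)
  if (any(probs < -1e-12))
    stop("infeasible inbreeding coefficient for p_del = ", p_del)
  probs <- pmax(probs, 0)
  cnt <- withr::with_seed(seed, drop(rmultinom(1L, n_individuals, probs)))
  genotype_counts(cnt[1], cnt[2], cnt[3], stratum = stratum, sex = sex)
}
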