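refs <- make_references(seed = 1)

test_that("align_read finds exact substrings and is strand-symmetric", {
  sub <- substr(refs$non_deletion$sequence, 21, 50)
  a <- align_read(sub, refs$non_deletion)
  expect_equal(a$matches, 30)
  expect_equal(a$mismatches, 0)
  expect_equal(a$offset, 20)
  expect_equal(a$strand, "+")

  b <- align_read(revcomp(sub), refs$non_deletion)
  expect_equal(b$score, a$score)
  expect_equal(b$strand, "-")
  expect_equal(b$offset, a$offset)

  expect_error(align_read("", refs$deletion), "non-empty")
})

test_that("align_read agrees with a brute-force all-offsets scan", {
  set.seed(101)
  for (k in 1:200) {
    read <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                  collapse = "")
    ref <- paste(sample(c("A", "C", "G", "T"), 139, replace = TRUE),
                 collapse = "")
    expect_equal(align_read(read, ref)$score, brute_align_score(read, ref))
  }
})

test_that("junction-spanning reads classify to their allele; flank reads are uninformative", {
  # perfect read across the deletion junction
  del_read <- substr(refs$deletion$sequence, 10, 80)
  expect_equal(classify_read(del_read, refs, min_overlap = 15)$best_allele,
               "deletion")
  # perfect read across the whole inserted interval
  non_read <- refs$non_deletion$sequence
  expect_equal(classify_read(non_read, refs, min_overlap = 15)$best_allele,
               "non_deletion")
  # read entirely inside the shared upstream flank: equal scores
  flank <- substr(refs$non_deletion$sequence, 5, 40)
  r <- classify_read(flank, refs, min_overlap = 8)
  expect_equal(r$best_allele, "uninformative")
  expect_equal(r$score_del, r$score_non)
})

test_that("the 8-bp overlap rule admits short-read evidence that the 15-bp rule rejects", {
  # 45-bp read with 8 aligned bases left of the junction and 37 right
  j <- refs$deletion$junction
  read <- substr(refs$deletion$sequence, j - 8 + 1, j + 37)
  expect_equal(nchar(read), 45)
  lenient <- classify_read(read, refs, min_overlap = 8)
  strict <- classify_read(read, refs, min_overlap = 15)
  expect_equal(lenient$best_allele, "deletion")
  expect_equal(lenient$overlap_left, 8)
  expect_equal(strict$best_allele, "uninformative")
})

test_that("raising min_overlap never increases the number of informative reads", {
  cfg <- sim_config(seed = 17, coverage = 15, error_rate = 0.005)
  reads <- simulate_line_reads("mixed", refs, cfg, mixed_fraction = 0.5)
  n_inf <- vapply(c(5, 8, 15, 25, 40), function(mo) {
    sum(classify_reads(reads$sequence, refs, min_overlap = mo)$best_allele !=
          "uninformative")
  }, numeric(1))
  expect_true(all(diff(n_inf) <= 0))
})

test_that("the classifier has no allele-label bias on mirrored evidence", {
  # error-free junction-spanning reads from each allele, same geometry:
  # the call always matches the generating allele, never the opposite
  for (shift in seq(0, 30, by = 5)) {
    dr <- substr(refs$deletion$sequence, 1 + shift, 75 + shift)
    nr <- substr(refs$non_deletion$sequence, 1 + shift, 124 + shift)
    expect_equal(classify_read(dr, refs, min_overlap = 15)$best_allele,
                 "deletion")
    expect_equal(classify_read(nr, refs, min_overlap = 15)$best_allele,
                 "non_deletion")
  }
})

test_that("call_line applies the majority rule exactly", {
  # the published exclusion case: 1 deletion vs 18 non-deletion reads
  asn <- data.frame(best_allele = c("deletion", rep("non_deletion", 18)))
  r <- call_line(asn, majority_threshold = 0.95)
  expect_equal(r$call, "ambiguous")
  expect_equal(r$major_fraction, 18 / 19)

  expect_equal(call_line(data.frame(best_allele = rep("deletion", 20)))$call,
               "deletion")
  none <- call_line(data.frame(best_allele = character(0)))
  expect_equal(none$call, "no_data")
  expect_true(is.na(none$major_fraction))
  expect_error(call_line(asn, majority_threshold = 0.4))
})

test_that("error-free haploid lines with junction coverage are always called correctly", {
  for (s in 1:10) {
    truth <- if (s %% 2) "deletion" else "non_deletion"
    reads <- simulate_line_reads(truth, refs,
                                 sim_config(seed = 40 + s, coverage = 8,
                                            error_rate = 0))
    asn <- classify_reads(reads$sequence, refs, min_overlap = 15)
    if (sum(asn$best_allele != "uninformative") >= 1) {
      expect_equal(call_line(asn)$call, truth)
    }
  }
})

test_that("cohort genotyping recovers every line on clean data", {
  set.seed(7)
  truth <- sample(c("deletion", "non_deletion"), 12, replace = TRUE,
                  prob = c(0.3, 0.7))
  lines <- lapply(seq_along(truth), function(i)
    simulate_line_reads(truth[i], refs,
                        sim_config(seed = 300 + i, coverage = 20,
                                   error_rate = 0)))
  names(lines) <- sprintf("L%02d", seq_along(truth))
  res <- genotype_cohort(lines, refs, min_overlap = 15)
  expect_equal(res$calls$call, truth)
  expect_equal(res$summary$n_classified, 12)
  expect_equal(res$summary$n_deletion, sum(truth == "deletion"))
})

test_that("a strongly mixed line is flagged ambiguous, and bad files do not stop the cohort", {
  amb <- 0
  for (s in 1:8) {
    reads <- simulate_line_reads("mixed", refs,
                                 sim_config(seed = 500 + s, coverage = 40),
                                 mixed_fraction = 0.25)
    asn <- classify_reads(reads$sequence, refs, min_overlap = 15)
    amb <- amb + (call_line(asn)$call == "ambiguous")
  }
  # minor-allele fraction 0.25 with ~30 informative reads essentially never
  # reaches the 95% majority
  expect_gte(amb, 7)

  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+"), bad)  # truncated record
  ok <- simulate_line_reads("deletion", refs, sim_config(seed = 1, coverage = 5))
  res <- genotype_cohort(list(good = ok, broken = bad), refs)
  expect_equal(res$calls$call[res$calls$line_id == "broken"], "error")
  expect_equal(res$summary$n_error, 1)
  expect_equal(res$calls$call[res$calls$line_id == "good"], "deletion")
})

test_that("pooled short-read lines follow the DGRP-style 8-bp / 95% rules", {
  cfg <- function(s) sim_config(seed = s, coverage = 25, error_rate = 0.002,
                                read_length_range = c(45L, 126L))
  pure <- simulate_line_reads("deletion", refs, cfg(61))
  resid <- simulate_line_reads("mixed", refs, cfg(62), mixed_fraction = 0.7)
  res <- genotype_cohort(list(pure = pure, resid = resid), refs,
                         min_overlap = 8)
  expect_equal(res$calls$call[1], "deletion")
  expect_equal(res$calls$call[2], "ambiguous")
})
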