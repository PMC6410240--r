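#' Sequence, table and tree readers/writers
#'
#' Thin, lossless wrappers around the standard format libraries:
#' FASTA/FASTQ via Biostrings (gzip handled transparently by extension),
#' Newick via ape, and tab-separated tables via base R with `#`-prefixed
#' comment/provenance headers. FASTQ is 4-line Sanger (Phred+33).
#'
#' @param path file path (`.gz` allowed for sequence files).
#' @param x object to write: named character vector (FASTA), data.frame
#'   with `read_id`/`sequence`/`quality` (FASTQ), data.frame (TSV), or
#'   [ape::phylo] (Newick).
#' @param comments character vector written as `# `-prefixed header lines
#'   before a TSV body (e.g. echoed generator parameters).
#' @return readers return the parsed object (`read_fasta` a named character
#'   vector, `read_fastq` a data.frame with `read_id`, `sequence`,
#'   `quality`, `read_tsv` a data.frame, `read_newick` an [ape::phylo]);
#'   writers return `path` invisibly.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' write_fasta(c(s1 = "ACGT"), tf)
#' read_fasta(tf)
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname pipeline_io
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  n_lines <- length(readLines(con, warn = FALSE))
  if (n_lines %% 4 != 0)
    stop("malformed FASTQ in ", path, ": truncated record at line ",
         n_lines + 1, " (records are 4 lines)", call. = FALSE)
  x <- withCallingHandlers(
    tryCatch(
      Biostrings::readQualityScaledDNAStringSet(path),
      error = function(e)
        stop("malformed FASTQ in ", path, ": ", conditionMessage(e),
             call. = FALSE)),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  data.frame(read_id = names(x),
             sequence = as.character(x),
             quality = as.character(Biostrings::quality(x)),
             row.names = NULL)
}

#' @rdname pipeline_io
#' @export
write_fastq <- function(x, path) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(x)),
            all(nchar(x$sequence) == nchar(x$quality)))
  s <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(x$sequence),
    Biostrings::PhredQuality(x$quality))
  names(s) <- x$read_id
  # Biostrings warns about dropping (empty) metadata columns on write
  withCallingHandlers(
    Biostrings::writeQualityScaledXStringSet(
      s, path, compress = grepl("\\.gz$", path)),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_tsv <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else path
  read.delim(con, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' @rdname pipeline_io
#' @export
write_tsv <- function(x, path, comments = NULL) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (length(comments))
    writeLines(paste0("# ", comments), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' @rdname pipeline_io
#' @export
write_newick <- function(x, path) {
  ape::write.tree(x, file = path)
  invisible(path)
}

#' Packaged genotype-count fixtures
#'
#' Paths to the genotype count tables shipped with the package: the
#' collection-level genotype counts (Del/Del, Del/Non, Non/Non per
#' collection) and the sex-level chromosome counts of the Munich seasonal
#' survey, so the population-genetic report can be reproduced offline.
#'
#' @param which `"genotype"` (collection x genotype counts) or `"allele"`
#'   (collection x sex chromosome counts).
#' @return path to a TSV readable with [read_tsv()].
#' @examples
#' head(read_tsv(munich_counts_path("genotype")))
#' @export
munich_counts_path <- function(which = c("genotype", "allele")) {
  which <- match.arg(which)
  fn <- switch(which,
               genotype = "munich_genotype_counts.tsv",
               allele = "munich_allele_counts.tsv")
  system.file("extdata", fn, package = "mtnadel", mustWork = TRUE)
}
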