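# small in-code fixtures shared across test files

make_track <- function(chrom, pos, strand = "+", meth, total, context = "CG") {
  n <- max(length(chrom), length(pos), length(meth), length(total))
  tibble::tibble(
    chrom = rep_len(chrom, n),
    pos = as.integer(rep_len(pos, n)),
    strand = rep_len(strand, n),
    context = rep_len(context, n),
    meth_count = as.integer(rep_len(meth, n)),
    total_count = as.integer(rep_len(total, n)),
    ratio = ifelse(rep_len(total, n) > 0,
                   rep_len(meth, n) / rep_len(total, n), NA_real_)
  )
}

# random valid strand-resolved track on one or more chromosomes
random_track <- function(n = 50, chroms = c("chr1", "chr2"), seed = 1) {
  withr::with_seed(seed, {
    chrom <- sample(chroms, n, replace = TRUE)
    pos <- sample(seq(2, 20000, by = 2), n)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    total <- rpois(n, 10)
    meth <- rbinom(n, total, runif(n))
    dplyr::distinct(
      dplyr::arrange(make_track(chrom, pos, strand, meth, total),
                     chrom, pos, strand),
      chrom, pos, strand, .keep_all = TRUE)
  })
}

write_methratio_fixture <- function(track, path = tempfile(fileext = ".tsv"),
                                    header = TRUE, scramble_ratio = FALSE) {
  out <- track[, c("chrom", "pos", "strand", "context", "ratio",
                   "meth_count", "total_count")]
  if (scramble_ratio) out$ratio <- 0.123  # files never trusted for ratios
  out$ratio[is.na(out$ratio)] <- 0
  readr::write_tsv(out, path, col_names = header, progress = FALSE)
  path
}

interval_tbl <- function(chrom, start, end, segment_class = "generic") {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), segment_class = segment_class,
                 n_cpgs = NA_integer_, mean_methylation = NA_real_)
}

# parse "chrom:start-end" feature ids back into an interval tibble
features_to_intervals <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  tibble::tibble(chrom = vapply(m, `[`, "", 2),
                 start = as.integer(vapply(m, `[`, "", 3)),
                 end = as.integer(vapply(m, `[`, "", 4)))
}

responsive_feature_ids <- function(genome) {
  r <- genome$regions[genome$regions$class == "age_responsive", ]
  sprintf("%s:%d-%d", r$chrom, r$start, r$end)
}
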