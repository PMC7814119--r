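#' Specification of a synthetic methylome genome
#'
#' Defines the ground-truth structure the generator plants: a mostly
#' highly-methylated background with short low-methylated regions, a subset
#' of which drift with age (linearly on the logit scale, so methylation
#' stays in (0, 1)); tissue-specific offsets confined to the planted
#' regions (tissue separation in real methylomes is driven by LMR
#' methylation); per-sample region-level biological noise; SNP-flagged
#' CpGs with genotype-driven ratios; and an optional sex chromosome.
#' Planted regions are CpG-dense relative to the background, as regulatory
#' elements are.
#'
#' @param chromosomes Named numeric vector of chromosome lengths in bp
#'   (default two 2-Mb autosomes).
#' @param include_sex_chrom Add a 0.5-Mb `chrZ` with background methylation
#'   only? Default `TRUE`.
#' @param cpg_spacing_mean Mean background CpG spacing in bp (default 100).
#' @param region_cpg_spacing Mean CpG spacing inside planted regions
#'   (default 40).
#' @param n_regions Number of planted low-methylation regions (default 500).
#' @param region_length Length range in bp (default `c(300, 800)`).
#' @param frac_age_responsive Fraction of regions with a nonzero age slope
#'   (default 0.1).
#' @param slope_range Magnitude range of age slopes in logit units per day
#'   (default `c(0.03, 0.08)`); sign is positive with probability
#'   `prob_hyper`.
#' @param prob_hyper Probability that an age-responsive region gains
#'   methylation with age (default 0.55, the observed hyper:hypo balance).
#' @param background_meth Background methylation level (default 0.8).
#' @param region_meth0 Baseline planted-region methylation (default 0.1):
#'   the age-0 level for static and hypermethylating regions, and the
#'   end-of-lifespan level for demethylating regions (which start high and
#'   descend into it).
#' @param tissue_offset_sd SD of per-(region, tissue) logit offsets
#'   (default 0.5).
#' @param region_noise_sd SD of per-(region, sample) logit noise, the
#'   inter-individual biological variability of LMR methylation
#'   (default 0.1, calibrated so that a clock cross-validated on the
#'   default cohort reaches an error on the scale real broiler cohorts
#'   support).
#' @param snp_fraction Fraction of CpGs flagged as SNPs (default 0.01).
#' @param coverage_mean Default mean total read coverage per CpG dyad
#'   (default 40).
#' @param dispersion Default beta-binomial overdispersion rho in \[0, 1)
#'   (default 0.015; 0 gives pure binomial counts).
#' @param seed Integer seed for genome generation.
#' @return A `synthetic_genome_spec` list.
#' @export
synthetic_genome_spec <- function(chromosomes = c(chr1 = 2e6, chr2 = 2e6),
                                  include_sex_chrom = TRUE,
                                  cpg_spacing_mean = 100,
                                  region_cpg_spacing = 40,
                                  n_regions = 500,
                                  region_length = c(300, 800),
                                  frac_age_responsive = 0.1,
                                  slope_range = c(0.03, 0.08),
                                  prob_hyper = 0.55,
                                  background_meth = 0.8,
                                  region_meth0 = 0.1,
                                  tissue_offset_sd = 0.5,
                                  region_noise_sd = 0.1,
                                  snp_fraction = 0.01,
                                  coverage_mean = 40,
                                  dispersion = 0.015,
                                  seed = 1L) {
  stopifnot(length(names(chromosomes)) == length(chromosomes))
  stopifnot(all(chromosomes > 0), cpg_spacing_mean > 0, region_cpg_spacing > 0,
            n_regions >= 0, length(region_length) == 2, all(region_length > 0),
            frac_age_responsive >= 0, frac_age_responsive <= 1,
            background_meth > 0, background_meth < 1,
            region_meth0 > 0, region_meth0 < 1,
            snp_fraction >= 0, snp_fraction <= 1,
            dispersion >= 0, dispersion < 1, coverage_mean > 0)
  structure(as.list(environment()), class = "synthetic_genome_spec")
}

#' Default broiler tissues of the clock training design
#' @return Character vector of tissue names.
#' @export
clock_tissues <- function() c("ileum", "breast_muscle", "spleen", "jejunum")

# place n non-overlapping regions of the given lengths on a chromosome,
# returning sorted 0-based starts; uniform via the spacings construction
# (sorted uniform cuts in the free space, regions inserted between them)
place_regions <- function(chrom_len, lengths) {
  n <- length(lengths)
  if (n == 0) return(integer())
  free <- chrom_len - sum(lengths) - 2
  if (free <= n) {
    abort("could not place regions without overlap; reduce n_regions or lengths")
  }
  cuts <- sort(runif(n, 0, free))
  as.integer(cuts + c(0, cumsum(lengths))[seq_len(n)]) + 1L
}

#' Generate a synthetic genome with planted ground truth
#'
#' Draws CpG positions with exponential spacing (denser inside planted
#' regions), places non-overlapping low-methylation regions, assigns age
#' slopes and per-tissue offsets, and flags SNP CpGs. Deterministic given
#' the spec seed.
#'
#' @param spec A [synthetic_genome_spec()].
#' @param tissues Tissues for which offsets are drawn
#'   (default [clock_tissues()]).
#' @return A `synthetic_genome` list: `spec`, `cpgs` (tibble `chrom`,
#'   `pos`, `region_id`, `is_snp`), `regions` (truth tibble with
#'   coordinates, class, `slope`, `baseline_logit`), `tissue_offsets`
#'   (long tibble `region_id`, `tissue`, `offset`), `snp_positions`,
#'   `tissues`.
#' @export
simulate_genome <- function(spec = synthetic_genome_spec(),
                            tissues = clock_tissues()) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  withr::with_seed(spec$seed, {
    chroms <- spec$chromosomes
    if (spec$include_sex_chrom) chroms <- c(chroms, chrZ = 5e5)
    autosomes <- setdiff(names(chroms), c("chrZ", "chrW", "Z", "W"))

    # allocate regions to autosomes proportional to length
    n_by_chrom <- setNames(rep(0L, length(chroms)), names(chroms))
    if (spec$n_regions > 0) {
      alloc <- table(factor(
        sample(autosomes, spec$n_regions, replace = TRUE,
               prob = chroms[autosomes]), levels = names(chroms)))
      n_by_chrom[names(alloc)] <- as.integer(alloc)
    }

    regions <- list(); cpgs <- list(); rid0 <- 0L
    for (ch in names(chroms)) {
      len <- chroms[[ch]]
      n_r <- n_by_chrom[[ch]]
      rl <- as.integer(runif(n_r, spec$region_length[1], spec$region_length[2]))
      starts <- if (n_r > 0) place_regions(len, rl) else integer()
      ends <- starts + rl  # 0-based half-open: [start, end)
      reg <- tibble::tibble(region_id = rid0 + seq_len(n_r),
                            chrom = ch, start = starts, end = ends)
      rid0 <- rid0 + n_r

      # background CpG anchors along the chromosome
      n_draw <- ceiling(len / spec$cpg_spacing_mean * 1.3) + 10
      bg <- cumsum(ceiling(stats::rexp(n_draw, 1 / spec$cpg_spacing_mean)) + 1)
      bg <- bg[bg < len - 1]
      # dense CpGs inside regions replace background ones there
      reg_cpgs <- purrr::map2(starts, ends, function(s, e) {
        n_d <- ceiling((e - s) / spec$region_cpg_spacing * 1.5) + 5
        p <- s + cumsum(ceiling(stats::rexp(n_d, 1 / spec$region_cpg_spacing)) + 1)
        p[p <= e - 1]
      })
      in_region <- rep(FALSE, length(bg))
      if (n_r > 0) {
        iv <- findInterval(bg, as.vector(rbind(starts + 1, ends + 1)))
        in_region <- iv %% 2 == 1
      }
      pos <- c(bg[!in_region], unlist(reg_cpgs))
      rid <- c(rep(NA_integer_, sum(!in_region)),
               rep(reg$region_id, lengths(reg_cpgs)))
      o <- order(pos)
      cpgs[[ch]] <- tibble::tibble(chrom = ch, pos = as.integer(pos[o]),
                                   region_id = rid[o])
      regions[[ch]] <- reg
    }
    cpgs <- dplyr::bind_rows(cpgs)
    cpgs <- dplyr::distinct(cpgs, .data$chrom, .data$pos, .keep_all = TRUE)
    cpgs$is_snp <- runif(nrow(cpgs)) < spec$snp_fraction
    regions <- dplyr::bind_rows(regions)

    # a planted region is only observable through its CpGs: record its
    # coordinates as the realized CpG footprint (first to last anchor,
    # half-open), not the internal placement slot
    if (nrow(regions) > 0) {
    span <- cpgs[!is.na(cpgs$region_id), ] %>%
      dplyr::group_by(.data$region_id) %>%
      dplyr::summarise(start = min(.data$pos) - 1L, end = max(.data$pos),
                       n_cpgs = dplyr::n(), .groups = "drop")
    regions <- regions %>%
      dplyr::select(-"start", -"end") %>%
      dplyr::inner_join(span, by = "region_id") %>%
      dplyr::arrange(.data$chrom, .data$start)
    } else {
      regions$n_cpgs <- integer()
    }

    n_reg <- nrow(regions)
    n_resp <- round(spec$frac_age_responsive * n_reg)
    resp <- sample(n_reg, n_resp)
    slope <- rep(0, n_reg)
    slope[resp] <- runif(n_resp, spec$slope_range[1], spec$slope_range[2]) *
      ifelse(runif(n_resp) < spec$prob_hyper, 1, -1)
    regions$class <- ifelse(seq_len(n_reg) %in% resp, "age_responsive", "static")
    regions$slope <- slope
    # hypermethylating regions start at the low baseline and rise;
    # demethylating regions start high and descend to the baseline by the
    # end of the broiler lifespan (they *become* low-methylated with age)
    regions$baseline_logit <- stats::qlogis(spec$region_meth0) +
      ifelse(slope < 0, -slope * 35, 0)

    tissue_offsets <- tidyr::expand_grid(region_id = regions$region_id,
                                         tissue = tissues)
    tissue_offsets$offset <- rnorm(nrow(tissue_offsets), 0, spec$tissue_offset_sd)

    snp_positions <- dplyr::select(cpgs[cpgs$is_snp, ], "chrom", "pos")
    # SNP flags apply to the dyad: both strand positions
    snp_positions <- dplyr::bind_rows(
      snp_positions,
      dplyr::mutate(snp_positions, pos = .data$pos + 1L)) %>%
      dplyr::arrange(.data$chrom, .data$pos)

    structure(list(spec = spec, cpgs = cpgs, regions = regions,
                   tissue_offsets = tissue_offsets,
                   snp_positions = snp_positions, tissues = tissues),
              class = "synthetic_genome")
  })
}

# beta-binomial (or binomial) methylated-read counts for given mu and
# per-site success probabilities shared by the two strands of a dyad
draw_site_probs <- function(mu, rho) {
  if (rho <= 0) return(mu)
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  rbeta(length(mu), a, b)
}

#' Simulate one sample's methylation track
#'
#' Per-CpG true methylation is
#' inverse-logit(logit(base) + slope x (age + acceleration) + tissue
#' offset + region noise), where base is the background level or the
#' planted-region baseline; the slope, offset and noise terms apply only
#' inside planted regions. Per-strand coverage is Poisson(coverage/2) and
#' methylated counts are beta-binomial around the site's methylation
#' (binomial when `dispersion = 0`), with the latent site probability
#' shared by the two strands of a dyad. SNP-flagged CpGs get
#' genotype-driven ratios (0, 1/2 or 1). Deterministic given `seed`.
#'
#' @param genome A `synthetic_genome`.
#' @param tissue Tissue label (must be present in the genome's truth).
#' @param age_days Chronological age in days.
#' @param acceleration_days Shift of the effective epigenetic age in days
#'   (default 0); enters the age-slope term only.
#' @param coverage_mean Mean total coverage per dyad (default from spec).
#' @param dispersion Beta-binomial rho (default from spec).
#' @param seed Integer seed.
#' @return A strand-resolved methylation track tibble.
#' @export
simulate_sample <- function(genome, tissue, age_days, acceleration_days = 0,
                            coverage_mean = genome$spec$coverage_mean,
                            dispersion = genome$spec$dispersion, seed = 1L) {
  stopifnot(inherits(genome, "synthetic_genome"))
  if (!tissue %in% genome$tissues) {
    abort(sprintf("tissue '%s' has no offsets in the genome truth", tissue))
  }
  spec <- genome$spec
  cpgs <- genome$cpgs
  regions <- genome$regions
  withr::with_seed(seed, {
    eff_age <- age_days + acceleration_days
    toff <- genome$tissue_offsets[genome$tissue_offsets$tissue == tissue, ]
    reg_noise <- rnorm(nrow(regions), 0, spec$region_noise_sd)
    reg_logit <- regions$baseline_logit + regions$slope * eff_age +
      toff$offset[match(regions$region_id, toff$region_id)] + reg_noise
    idx <- match(cpgs$region_id, regions$region_id)
    mu <- ifelse(is.na(idx), stats::qlogis(spec$background_meth), reg_logit[idx])
    mu <- stats::plogis(mu)
    # SNP sites: genotype-driven apparent methylation
    snp <- cpgs$is_snp
    if (any(snp)) {
      mu[snp] <- sample(c(0, 0.5, 1), sum(snp), replace = TRUE,
                        prob = c(0.25, 0.5, 0.25))
    }
    p_site <- mu
    if (dispersion > 0) {
      non_snp <- !snp & mu > 0 & mu < 1
      p_site[non_snp] <- draw_site_probs(mu[non_snp], dispersion)
    }
    n <- nrow(cpgs)
    cov_p <- rpois(n, coverage_mean / 2)
    cov_m <- rpois(n, coverage_mean / 2)
    meth_p <- rbinom(n, cov_p, p_site)
    meth_m <- rbinom(n, cov_m, p_site)
    track <- dplyr::bind_rows(
      new_track(cpgs$chrom, cpgs$pos, "+", "CG", meth_p, cov_p),
      new_track(cpgs$chrom, cpgs$pos + 1L, "-", "CG", meth_m, cov_m)
    )
    sort_track(track)
  })
}

#' Default cohort design mirroring the clock training set
#'
#' Four tissues, three ages each, three replicates (36 samples): ileum,
#' breast muscle and spleen at days 3/15/34, jejunum at days 14/16/34.
#'
#' @param n_reps Replicates per (tissue, age) cell (default 3).
#' @return A design tibble `tissue`, `age_days`, `n`, `group`,
#'   `acceleration`.
#' @export
default_cohort_design <- function(n_reps = 3) {
  dplyr::bind_rows(
    tidyr::expand_grid(tissue = c("ileum", "breast_muscle", "spleen"),
                       age_days = c(3, 15, 34)),
    tidyr::expand_grid(tissue = "jejunum", age_days = c(14, 16, 34))
  ) %>%
    dplyr::mutate(n = n_reps, group = "control", acceleration = 0)
}

#' Simulate a multi-sample cohort
#'
#' Expands a design table into per-sample tracks with seeds derived from a
#' single master seed (full reproducibility), and returns the tracks, the
#' sample sheet and the ground truth.
#'
#' @param design A design tibble (`tissue`, `age_days`, `n`, optionally
#'   `group` and `acceleration`); default [default_cohort_design()].
#' @param genome A `synthetic_genome` (default: from the default spec).
#' @param seed Master integer seed.
#' @param coverage_mean,dispersion Passed to [simulate_sample()].
#' @return A list: `tracks` (named list of track tibbles), `metadata`
#'   (sample sheet tibble with `sample_id`, `tissue`, `age_days`, `group`,
#'   `acceleration`, `seed`), `genome`.
#' @export
simulate_cohort <- function(design = default_cohort_design(),
                            genome = simulate_genome(),
                            seed = 1L,
                            coverage_mean = genome$spec$coverage_mean,
                            dispersion = genome$spec$dispersion) {
  stopifnot(nrow(design) > 0)
  if (!"group" %in% names(design)) design$group <- "control"
  if (!"acceleration" %in% names(design)) design$acceleration <- 0
  sheet <- tidyr::uncount(design, weights = .data$n, .id = "rep")
  sheet$sample_id <- sprintf("%s_d%02d_%s_r%d", sheet$tissue, sheet$age_days,
                             sheet$group, sheet$rep)
  sheet$seed <- (as.integer(seed) + 7919L * seq_len(nrow(sheet))) %% 2147483647L
  tracks <- purrr::pmap(
    list(sheet$tissue, sheet$age_days, sheet$acceleration, sheet$seed),
    function(tt, age, acc, s) {
      simulate_sample(genome, tt, age, acc, coverage_mean, dispersion, seed = s)
    })
  names(tracks) <- sheet$sample_id
  list(tracks = tracks,
       metadata = dplyr::select(sheet, "sample_id", "tissue", "age_days",
                                "group", "acceleration", "seed"),
       genome = genome)
}
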