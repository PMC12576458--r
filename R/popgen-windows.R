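#' Tile chromosomes with sliding windows
#'
#' Windows start at 0 on each chromosome, advance by `step` and are truncated
#' at the chromosome end — the 20-kb / 5-kb sliding scheme used for
#' genome-wide diversity and differentiation scans. Intervals are half-open
#' 0-based internally; `start1`/`end1` give the 1-based inclusive rendering
#' used in written outputs.
#'
#' @param chrom_lengths Named numeric vector (names = chromosomes) or a data
#'   frame with columns `chrom`, `length`.
#' @param size Window size in bp (default 20000).
#' @param step Step size in bp (default 5000); `step <= size`.
#' @return A tibble: `window_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `start1`, `end1`.
#' @export
make_windows <- function(chrom_lengths, size = 20000, step = 5000) {
  stopifnot(size >= step, step >= 1)
  if (is.data.frame(chrom_lengths)) {
    lens <- stats::setNames(chrom_lengths$length, chrom_lengths$chrom)
  } else {
    lens <- chrom_lengths
  }
  if (any(lens <= 0)) stop("chromosome lengths must be positive", call. = FALSE)
  out <- purrr::imap_dfr(as.list(lens), function(len, ch) {
    # a chromosome shorter than one window yields a single truncated window
    starts <- if (len <= size) 0 else seq(0, len - 1, by = step)
    tibble::tibble(chrom = ch, start = starts,
                   end = pmin(starts + size, len))
  })
  out$window_id <- seq_len(nrow(out))
  out$start1 <- out$start + 1
  out$end1 <- out$end
  out[, c("window_id", "chrom", "start", "end", "start1", "end1")]
}

# Site row indices falling in a half-open 0-based window. Positions are
# 1-based, so pos p occupies [p-1, p).
window_site_index <- function(gm, windows) {
  s <- gm$sites
  purrr::pmap(list(windows$chrom, windows$start, windows$end),
              function(ch, lo, hi) {
                idx <- which(s$chrom == ch)
                idx[s$pos[idx] >= lo + 1 & s$pos[idx] <= hi]
              })
}

#' Nucleotide diversity in windows
#'
#' Per window and population, pi per bp = sum over usable sites of
#' `2 * p * q * n / (n - 1)` divided by the window length, where `p` is the
#' alternate-allele frequency among the population's `n` non-missing
#' haplotypes at the site. Sites with fewer than 2 haplotypes are skipped;
#' a window with no usable site gets pi = 0 and `empty = TRUE`.
#'
#' @param gm A [geno_matrix()].
#' @param labels Label tibble (see [read_labels()]).
#' @param population Population code(s) pooled for the estimate.
#' @param windows Window tibble from [make_windows()].
#' @return `windows` with columns `pi`, `n_sites`, `empty` appended.
#' @export
window_pi <- function(gm, labels, population, windows) {
  cols <- pop_columns(gm, labels, population)
  st <- site_allele_stats(gm, cols)
  per_site <- ifelse(st$n_hap >= 2,
                     2 * st$p * (1 - st$p) * st$n_hap / (st$n_hap - 1), 0)
  usable <- st$n_hap >= 2
  idx <- window_site_index(gm, windows)
  windows$pi <- purrr::map2_dbl(idx, windows$end - windows$start,
                                ~sum(per_site[.x]) / .y)
  windows$n_sites <- purrr::map_int(idx, ~sum(usable[.x]))
  windows$empty <- windows$n_sites == 0
  windows
}

# Per-site Hudson Fst components between two frequency/haplotype-count sets.
hudson_components <- function(p1, n1, p2, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ok <- !is.na(p1) & !is.na(p2) & n1 >= 2 & n2 >= 2
  list(num = ifelse(ok, num, NA_real_), den = ifelse(ok, den, NA_real_),
       ok = ok)
}

#' Windowed Hudson Fst
#'
#' Hudson's estimator with "ratio of averages" windowing: the per-site
#' numerators and denominators are summed within a window before the ratio
#' is taken. Sites monomorphic in both populations contribute nothing; a
#' window whose summed denominator is zero gets `NA` and `undefined = TRUE`.
#' Negative windowed estimates are legitimate and retained.
#'
#' @inheritParams window_pi
#' @param pop_a,pop_b Population codes (each may pool several labels).
#' @return `windows` with columns `fst`, `n_sites_fst`, `undefined`.
#' @export
hudson_fst <- function(gm, labels, pop_a, pop_b, windows) {
  a <- site_allele_stats(gm, pop_columns(gm, labels, pop_a))
  b <- site_allele_stats(gm, pop_columns(gm, labels, pop_b))
  hc <- hudson_components(a$p, a$n_hap, b$p, b$n_hap)
  idx <- window_site_index(gm, windows)
  sums <- purrr::map(idx, function(i) {
    i <- i[hc$ok[i]]
    c(num = sum(hc$num[i]), den = sum(hc$den[i]), n = length(i))
  })
  num <- purrr::map_dbl(sums, "num")
  den <- purrr::map_dbl(sums, "den")
  windows$fst <- ifelse(den > 0, num / den, NA_real_)
  windows$n_sites_fst <- purrr::map_int(sums, ~as.integer(.x[["n"]]))
  windows$undefined <- !(den > 0)
  windows
}

# Per-site Hudson Fst (used for fixed-difference calling).
per_site_fst <- function(gm, labels, pop_a, pop_b) {
  a <- site_allele_stats(gm, pop_columns(gm, labels, pop_a))
  b <- site_allele_stats(gm, pop_columns(gm, labels, pop_b))
  hc <- hudson_components(a$p, a$n_hap, b$p, b$n_hap)
  ifelse(hc$ok & hc$den > 0, hc$num / hc$den, NA_real_)
}

#' Reduction of diversity
#'
#' `ROD = 1 - pi_target / pi_control`, oriented so that diversity loss in the
#' target population yields positive values that feed the same top-quantile
#' candidate rule as Fst.
#'
#' @param pi_target,pi_control Non-negative diversity values (vectorised).
#' @return Numeric vector; `NA` where `pi_control` is 0.
#' @export
rod <- function(pi_target, pi_control) {
  if (any(pi_target < 0, na.rm = TRUE) || any(pi_control < 0, na.rm = TRUE)) {
    stop("pi values must be non-negative", call. = FALSE)
  }
  ifelse(pi_control > 0, 1 - pi_target / pi_control, NA_real_)
}

#' Standardise window statistics and flag top candidates
#'
#' Transforms values into z-scores (population standard deviation over the
#' finite values) and flags as candidates the windows carrying the top
#' `top_fraction` largest z-scores (one-tailed "top 1%" rule;
#' `ceiling(top_fraction * m)` windows, boundary ties all included).
#'
#' @param values Numeric vector (one per window); non-finite values are
#'   carried as `NA` and excluded from the mean/sd and the quantile count.
#' @param top_fraction Fraction of windows to flag (default 0.01).
#' @return A tibble with columns `value`, `z`, `candidate`.
#' @export
zscore_candidates <- function(values, top_fraction = 0.01) {
  fin <- is.finite(values)
  if (sum(fin) < 2) stop("need at least 2 finite values", call. = FALSE)
  mu <- mean(values[fin])
  sdev <- sqrt(mean((values[fin] - mu)^2))
  z <- rep(NA_real_, length(values))
  candidate <- rep(FALSE, length(values))
  if (sdev == 0) {
    warning("all values equal; no candidates flagged", call. = FALSE)
    z[fin] <- 0
  } else {
    z[fin] <- (values[fin] - mu) / sdev
    k <- ceiling(top_fraction * sum(fin))
    if (k >= 1) {
      cutoff <- sort(z[fin], decreasing = TRUE)[k]
      candidate <- !is.na(z) & z >= cutoff
    }
  }
  tibble::tibble(value = values, z = z, candidate = candidate)
}

#' Overlap fraction between two candidate window sets
#'
#' @param candidates_a,candidates_b Integer vectors of window ids drawn from
#'   the same tiling.
#' @return `|A intersect B| / |A|`; `NA` with a warning when A is empty.
#' @export
overlap_fraction <- function(candidates_a, candidates_b) {
  if (length(candidates_a) == 0) {
    warning("empty candidate set A; overlap undefined", call. = FALSE)
    return(NA_real_)
  }
  length(intersect(candidates_a, candidates_b)) / length(unique(candidates_a))
}

#' Genome-wide sweep scan
#'
#' One call chaining the windowed statistics: per-population diversity,
#' Hudson Fst between a stated pair, reduction of diversity for a
#' target/control pair, z-scores and top-fraction candidate flags for both
#' Fst and ROD.
#'
#' @inheritParams window_pi
#' @param windows Window tibble; built from `chrom_lengths` when `NULL`.
#' @param chrom_lengths Passed to [make_windows()] when `windows` is `NULL`.
#' @param populations Populations for which to report diversity.
#' @param fst_pair Length-2 character: populations contrasted by Fst.
#' @param rod_target,rod_control Populations for the ROD ratio.
#' @param size,step Window geometry (defaults 20 kb / 5 kb).
#' @param top_fraction Candidate fraction (default 0.01).
#' @return A tibble of class `sweep_scan`: windows with `pi_<pop>` columns,
#'   `fst`, `rod`, `z_fst`, `z_rod`, `candidate_fst`, `candidate_rod`.
#' @export
sweep_scan <- function(gm, labels, windows = NULL, chrom_lengths = NULL,
                       populations = c("P1", "P2", "HYB"),
                       fst_pair = c("P1", "P2"),
                       rod_target = "P2", rod_control = "P1",
                       size = 20000, step = 5000, top_fraction = 0.01) {
  if (is.null(windows)) {
    if (is.null(chrom_lengths)) {
      chrom_lengths <- tapply(gm$sites$pos, gm$sites$chrom, max)
    }
    windows <- make_windows(chrom_lengths, size = size, step = step)
  }
  populations <- intersect(populations, unique(labels$population))
  out <- windows
  for (pop in populations) {
    wp <- window_pi(gm, labels, pop, windows)
    out[[paste0("pi_", pop)]] <- wp$pi
  }
  wf <- hudson_fst(gm, labels, fst_pair[1], fst_pair[2], windows)
  out$fst <- wf$fst
  out$rod <- rod(out[[paste0("pi_", rod_target)]],
                 out[[paste0("pi_", rod_control)]])
  zf <- zscore_candidates(out$fst, top_fraction)
  zr <- zscore_candidates(out$rod, top_fraction)
  out$z_fst <- zf$z
  out$z_rod <- zr$z
  out$candidate_fst <- zf$candidate
  out$candidate_rod <- zr$candidate
  class(out) <- c("sweep_scan", class(out))
  out
}

#' @export
autoplot.sweep_scan <- function(object, statistic = c("z_rod", "z_fst"), ...) {
  statistic <- match.arg(statistic)
  mid <- (object$start + object$end) / 2
  df <- tibble::tibble(chrom = object$chrom, mid = mid,
                       value = object[[statistic]],
                       candidate = object[[sub("^z_", "candidate_",
                                               statistic)]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid / 1e6, y = .data$value,
                                   colour = .data$candidate)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "position (Mb)", y = statistic) +
    ggplot2::theme_minimal()
}
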