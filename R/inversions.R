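#' Genotype samples across an inversion region
#'
#' Calls each sample's inversion genotype from its diagnostic-site genotypes
#' inside the region: the fractions of non-missing diagnostic calls that are
#' heterozygous, homozygous for the P1 allele, or homozygous for the P2
#' allele are computed, and the call is the unique class whose fraction
#' reaches `call_threshold` (otherwise `ambiguous`). Mirrors the observation
#' that intact heterozygous-inversion carriers show > 94% heterozygosity
#' while collinear carriers show > 98% P1-like homozygosity.
#'
#' @param gm A [geno_matrix()].
#' @param diag Diagnostic-site tibble ([find_diagnostic_sites()] /
#'   [genotype_hybrids()]); only qualifying sites are used.
#' @param region One-row data frame or list with `chrom`, `start`, `end`
#'   (1-based inclusive) and optionally `label`.
#' @param samples Samples to call (default: all in `gm`).
#' @param call_threshold Minimum class fraction for an unambiguous call
#'   (default 0.8).
#' @param min_sites Minimum qualifying diagnostic sites in the region
#'   (default 20); below it the region is uncallable and a zero-row tibble
#'   with attribute `uncallable = TRUE` is returned with a warning.
#' @return A tibble with one row per sample: `sample`, `region`, `n_sites`,
#'   `n_called`, `het_fraction`, `p1_hom_fraction`, `p2_hom_fraction`,
#'   `call`.
#' @export
genotype_inversion_region <- function(gm, diag, region, samples = NULL,
                                      call_threshold = 0.8, min_sites = 20) {
  if (is.null(samples)) samples <- gm$samples
  label <- if (!is.null(region$label)) region$label else
    sprintf("%s:%d-%d", region$chrom, region$start, region$end)
  d <- diag[diag$qualifies & diag$chrom == region$chrom &
              diag$pos >= region$start & diag$pos <= region$end, ,
            drop = FALSE]
  if (nrow(d) < min_sites) {
    warning(sprintf("region %s: only %d qualifying diagnostic sites (< %d); uncallable",
                    label, nrow(d), min_sites), call. = FALSE)
    out <- tibble::tibble(sample = character(), region = character(),
                          n_sites = integer(), n_called = integer(),
                          het_fraction = numeric(),
                          p1_hom_fraction = numeric(),
                          p2_hom_fraction = numeric(), call = character())
    attr(out, "uncallable") <- TRUE
    return(out)
  }
  cols <- match(samples, gm$samples)
  g <- gm$geno[d$site, cols, drop = FALSE]
  p1_code <- ifelse(d$p1_allele == "ref", 0L, 2L)
  p2_code <- 2L - p1_code
  n_called <- colSums(!is.na(g))
  frac <- function(code) {
    hits <- colSums(g == matrix(code, nrow(g), ncol(g)), na.rm = TRUE)
    ifelse(n_called > 0, hits / n_called, NA_real_)
  }
  het <- colSums(g == 1L, na.rm = TRUE) / pmax(n_called, 1)
  het[n_called == 0] <- NA_real_
  p1f <- frac(p1_code)
  p2f <- frac(p2_code)
  call <- dplyr::case_when(
    n_called == 0 ~ "ambiguous",
    het >= call_threshold ~ "heterozygous",
    p1f >= call_threshold ~ "P1_homozygous",
    p2f >= call_threshold ~ "P2_homozygous",
    TRUE ~ "ambiguous"
  )
  tibble::tibble(sample = samples, region = label,
                 n_sites = nrow(d), n_called = as.integer(n_called),
                 het_fraction = het, p1_hom_fraction = p1f,
                 p2_hom_fraction = p2f, call = call)
}

#' Genotype samples across several inversion regions
#'
#' @inheritParams genotype_inversion_region
#' @param regions Region tibble (`chrom`, `start`, `end`, `label`), e.g.
#'   from [read_regions_bed()].
#' @return Row-bound per-region call tibbles.
#' @export
genotype_inversions <- function(gm, diag, regions, samples = NULL,
                                call_threshold = 0.8, min_sites = 20) {
  purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    genotype_inversion_region(gm, diag, regions[i, ], samples = samples,
                              call_threshold = call_threshold,
                              min_sites = min_sites)
  })
}

#' Linkage-disequilibrium contrast: inversions versus collinear background
#'
#' Computes the pairwise r-squared profile inside each inversion region and
#' over background spans sampled from the same chromosomes outside all
#' inversions (matched in total span), then compares distance-matched mean
#' r-squared (average over the distance bins populated on both sides).
#' Elevated inversion LD is the signature of suppressed recombination in
#' heterozygous-inversion carriers.
#'
#' @param gm A [geno_matrix()].
#' @param regions Inversion region tibble (`chrom`, `start`, `end`).
#' @param background Optional background region tibble; when `NULL`,
#'   background spans are taken immediately outside the inversions on the
#'   same chromosomes, matched in total length.
#' @param samples Optional sample subset (e.g. the hybrid accessions).
#' @param ... Filters passed to [ld_r2_profile()].
#' @return A list of class `ld_contrast`: `mean_r2_inversion`,
#'   `mean_r2_background`, `difference`, `bins` (per-bin means for both
#'   sides), `undefined`.
#' @export
ld_contrast <- function(gm, regions, background = NULL, samples = NULL, ...) {
  profile_regions <- function(regs) {
    bins <- purrr::map_dfr(seq_len(nrow(regs)), function(i) {
      pr <- tryCatch(
        ld_r2_profile(gm, chrom = regs$chrom[i], start = regs$start[i],
                      end = regs$end[i], samples = samples, ...),
        warning = function(w) NULL)
      if (is.null(pr)) tibble::tibble() else pr$bins
    })
    if (nrow(bins) == 0) return(bins)
    bins |>
      dplyr::group_by(bin = .data$bin) |>
      dplyr::summarise(mid = dplyr::first(.data$mid),
                       mean_r2 = stats::weighted.mean(.data$mean_r2,
                                                      .data$n_pairs),
                       n_pairs = sum(.data$n_pairs), .groups = "drop")
  }
  if (is.null(background)) {
    background <- complement_regions(gm, regions)
  }
  inv_bins <- profile_regions(regions)
  bg_bins <- profile_regions(background)
  if (nrow(inv_bins) == 0 || nrow(bg_bins) == 0) {
    warning("empty LD profile on one side; contrast undefined", call. = FALSE)
    return(structure(list(mean_r2_inversion = NA_real_,
                          mean_r2_background = NA_real_,
                          difference = NA_real_,
                          bins = tibble::tibble(), undefined = TRUE),
                     class = "ld_contrast"))
  }
  shared <- dplyr::inner_join(inv_bins, bg_bins, by = "bin",
                              suffix = c("_inv", "_bg"))
  if (nrow(shared) == 0) {
    warning("no shared distance bins; contrast undefined", call. = FALSE)
    return(structure(list(mean_r2_inversion = NA_real_,
                          mean_r2_background = NA_real_,
                          difference = NA_real_,
                          bins = tibble::tibble(), undefined = TRUE),
                     class = "ld_contrast"))
  }
  m_inv <- mean(shared$mean_r2_inv)
  m_bg <- mean(shared$mean_r2_bg)
  structure(list(mean_r2_inversion = m_inv, mean_r2_background = m_bg,
                 difference = m_inv - m_bg, bins = shared,
                 undefined = FALSE),
            class = "ld_contrast")
}

# Background spans on the inversion chromosomes outside all inversions,
# matched in total span.
complement_regions <- function(gm, regions) {
  target <- sum(regions$end - regions$start + 1)
  out <- list()
  for (ch in unique(regions$chrom)) {
    pos <- gm$sites$pos[gm$sites$chrom == ch]
    if (!length(pos)) next
    lo <- min(pos); hi <- max(pos)
    inv <- regions[regions$chrom == ch, , drop = FALSE]
    inv <- inv[order(inv$start), , drop = FALSE]
    gaps <- tibble::tibble(
      start = c(lo, inv$end + 1),
      end = c(inv$start - 1, hi)
    )
    gaps <- gaps[gaps$end > gaps$start, , drop = FALSE]
    if (nrow(gaps)) out[[ch]] <- dplyr::mutate(gaps, chrom = ch)
  }
  if (!length(out)) {
    stop("no collinear background available on the inversion chromosomes",
         call. = FALSE)
  }
  bg <- dplyr::bind_rows(out)[, c("chrom", "start", "end")]
  # trim to roughly the inversions' total span, largest gaps first
  bg <- bg[order(bg$end - bg$start, decreasing = TRUE), , drop = FALSE]
  cum <- cumsum(bg$end - bg$start + 1)
  keep <- which(cum - (bg$end - bg$start + 1) < target)
  bg <- bg[keep, , drop = FALSE]
  excess <- sum(bg$end - bg$start + 1) - target
  if (excess > 0) bg$end[nrow(bg)] <- bg$end[nrow(bg)] - excess
  bg[bg$end > bg$start, , drop = FALSE]
}

#' @export
print.ld_contrast <- function(x, ...) {
  if (x$undefined) {
    cat("<ld_contrast> undefined (empty profile)\n")
  } else {
    cat(sprintf(
      "<ld_contrast> mean r2: inversion %.3f vs background %.3f (diff %+.3f; %d shared bins)\n",
      x$mean_r2_inversion, x$mean_r2_background, x$difference, nrow(x$bins)))
  }
  invisible(x)
}

#' @export
autoplot.ld_contrast <- function(object, ...) {
  if (object$undefined) stop("contrast undefined", call. = FALSE)
  df <- tidyr::pivot_longer(
    object$bins[, c("mid_inv", "mean_r2_inv", "mean_r2_bg")],
    cols = c("mean_r2_inv", "mean_r2_bg"),
    names_to = "side", values_to = "mean_r2")
  df$side <- ifelse(df$side == "mean_r2_inv", "inversion", "background")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid_inv / 1000,
                                   y = .data$mean_r2,
                                   colour = .data$side)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "distance (kb)", y = expression(mean ~ r^2),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
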