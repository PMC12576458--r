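#' Patterson's D (ABBA/BABA) from population allele frequencies
#'
#' Frequency-weighted four-taxon site-pattern sums for the taxon order
#' (P1, P2, P3, outgroup), with the alternate allele polarised by the
#' outgroup frequency `p4`:
#' `ABBA = sum (1 - p1) p2 p3 (1 - p4)`, `BABA = sum p1 (1 - p2) p3 (1 - p4)`,
#' `D = (ABBA - BABA) / (ABBA + BABA)`. A positive D signals excess allele
#' sharing between P2 and P3. Sites with any missing frequency are skipped.
#'
#' @param freqs A data frame with numeric columns `p1`, `p2`, `p3`, `p4`
#'   (per-site alternate-allele frequencies in `[0, 1]`).
#' @return A list of class `dstat_result` with `abba`, `baba`, `D`
#'   (`NA` and `undefined = TRUE` when `abba + baba = 0`), `n_sites`.
#' @export
d_statistic <- function(freqs) {
  freqs <- tibble::as_tibble(freqs)
  need <- c("p1", "p2", "p3", "p4")
  stopifnot(all(need %in% names(freqs)))
  ns <- vapply(freqs[need], length, integer(1))
  if (length(unique(ns)) != 1) stop("frequency vectors differ in length",
                                    call. = FALSE)
  p <- freqs[need]
  rng <- range(unlist(p), na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stop("frequencies must lie in [0, 1]",
                                     call. = FALSE)
  ok <- stats::complete.cases(p)
  abba <- (1 - p$p1[ok]) * p$p2[ok] * p$p3[ok] * (1 - p$p4[ok])
  baba <- p$p1[ok] * (1 - p$p2[ok]) * p$p3[ok] * (1 - p$p4[ok])
  A <- sum(abba); B <- sum(baba)
  structure(list(abba = A, baba = B,
                 D = if (A + B > 0) (A - B) / (A + B) else NA_real_,
                 undefined = !(A + B > 0), n_sites = sum(ok),
                 Z = NA_real_, se = NA_real_, n_blocks = NA_integer_,
                 block_d = NULL),
            class = "dstat_result")
}

#' Block-jackknife Z score for Patterson's D
#'
#' Delete-one-block jackknife over contiguous genomic blocks: for each block
#' the statistic is recomputed without it, the jackknife variance is
#' `(B - 1) / B * sum((D_i - mean(D_i))^2)` and `Z = D / SE`. With identical
#' blocks the SE is 0 and Z is flagged undefined.
#'
#' @inheritParams d_statistic
#' @param blocks Block assignment per site: integer/factor of the same
#'   length as the frequency vectors (contiguous genomic blocks).
#' @return A `dstat_result` with `Z`, `se`, `n_blocks` and per-block D
#'   values (`block_d`) filled.
#' @export
block_jackknife_z <- function(freqs, blocks) {
  freqs <- tibble::as_tibble(freqs)
  stopifnot(nrow(freqs) == length(blocks))
  res <- d_statistic(freqs)
  ok <- stats::complete.cases(freqs[c("p1", "p2", "p3", "p4")])
  f <- freqs[ok, ]
  blocks <- factor(blocks[ok])
  if (nlevels(blocks) < 2) stop("need at least 2 non-empty blocks",
                                call. = FALSE)
  ab <- (1 - f$p1) * f$p2 * f$p3 * (1 - f$p4)
  ba <- f$p1 * (1 - f$p2) * f$p3 * (1 - f$p4)
  A_b <- tapply(ab, blocks, sum)
  B_b <- tapply(ba, blocks, sum)
  A <- sum(A_b); B <- sum(B_b)
  denom <- (A - A_b) + (B - B_b)
  d_i <- ifelse(denom > 0, ((A - A_b) - (B - B_b)) / denom, NA_real_)
  res$n_blocks <- nlevels(blocks)
  res$block_d <- as.numeric(d_i)
  if (anyNA(d_i)) {
    warning("delete-one D undefined for some block(s); Z flagged undefined",
            call. = FALSE)
    return(res)
  }
  nb <- length(d_i)
  v <- (nb - 1) / nb * sum((d_i - mean(d_i))^2)
  res$se <- sqrt(v)
  res$Z <- if (res$se > 0) res$D / res$se else NA_real_
  if (!res$se > 0) warning("jackknife SE is 0; Z undefined", call. = FALSE)
  res
}

#' @export
print.dstat_result <- function(x, ...) {
  cat(sprintf("ABBA/BABA test: ABBA = %.3f, BABA = %.3f, D = %s",
              x$abba, x$baba,
              if (is.na(x$D)) "undefined" else sprintf("%.4f", x$D)))
  if (!is.na(x$Z)) cat(sprintf(", Z = %.2f (%d blocks)", x$Z, x$n_blocks))
  cat("\n")
  invisible(x)
}

#' @export
tidy.dstat_result <- function(x, ...) {
  tibble::tibble(
    statistic = c("abba", "baba", "D", "Z"),
    value = c(x$abba, x$baba, x$D, x$Z)
  )
}

#' @export
glance.dstat_result <- function(x, ...) {
  tibble::tibble(abba = x$abba, baba = x$baba, D = x$D, se = x$se, Z = x$Z,
                 n_sites = x$n_sites, n_blocks = x$n_blocks)
}

#' @export
autoplot.dstat_result <- function(object, ...) {
  if (is.null(object$block_d)) {
    stop("no per-block values; run block_jackknife_z() first", call. = FALSE)
  }
  df <- tibble::tibble(block = seq_along(object$block_d),
                       d = object$block_d)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$block, y = .data$d)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$D, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "deleted block", y = "delete-one D") +
    ggplot2::theme_minimal()
}
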