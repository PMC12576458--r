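#' Build a genotype matrix object
#'
#' The central substrate of the package: diploid genotype codes for a set of
#' biallelic sites across a set of samples. Codes are `0` (homozygous
#' reference), `1` (heterozygous), `2` (homozygous alternate) and `NA`
#' (missing call).
#'
#' @param sites A data frame with one row per site and at least columns
#'   `chrom`, `pos` (1-based), `ref`, `alt`. Optional columns `site_class`
#'   (`"SNP"` or `"InDel"`; derived from allele lengths when absent),
#'   `gene_id`, `region` (`"exon"`, `"intron"` or `"intergenic"`) and `effect`
#'   (`"synonymous"`, `"nonsynonymous"` or `"noncoding"`).
#' @param geno Integer matrix, `nrow(sites)` rows by `length(samples)`
#'   columns, values in `{0, 1, 2, NA}`.
#' @param samples Character vector of sample identifiers (unique).
#'
#' @return An object of class `geno_matrix`: a list with elements `sites`
#'   (tibble), `samples` (character) and `geno` (integer matrix with sample
#'   column names).
#' @export
#' @examples
#' gm <- geno_matrix(
#'   sites = data.frame(chrom = "chr1", pos = c(100, 200),
#'                      ref = "A", alt = "T"),
#'   geno = rbind(c(0L, 1L), c(2L, NA)),
#'   samples = c("s1", "s2")
#' )
#' gm
geno_matrix <- function(sites, geno, samples) {
  sites <- tibble::as_tibble(sites)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  if (!is.matrix(geno)) geno <- matrix(geno, nrow = nrow(sites))
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(sites)) {
    stop("`geno` must have one row per site", call. = FALSE)
  }
  if (ncol(geno) != length(samples)) {
    stop("`geno` must have one column per sample", call. = FALSE)
  }
  if (anyDuplicated(samples)) stop("duplicate sample identifiers", call. = FALSE)
  bad <- !(geno %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  if (nrow(sites) > 0) {
    if (any(sites$pos < 1)) stop("positions must be >= 1", call. = FALSE)
    if (any(sites$ref == sites$alt)) {
      stop("ref and alt alleles must differ", call. = FALSE)
    }
    ord <- order(sites$chrom, sites$pos)
    if (!all(ord == seq_len(nrow(sites))) ||
        anyDuplicated(sites[, c("chrom", "pos")])) {
      stop("sites must be strictly increasing by (chrom, pos)", call. = FALSE)
    }
  }
  if (!"site_class" %in% names(sites)) {
    sites$site_class <- ifelse(nchar(sites$ref) == 1 & nchar(sites$alt) == 1,
                               "SNP", "InDel")
  }
  for (col in c("gene_id", "region", "effect")) {
    if (!col %in% names(sites)) sites[[col]] <- NA_character_
  }
  dimnames(geno) <- list(NULL, samples)
  structure(list(sites = sites, samples = as.character(samples), geno = geno),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  n_miss <- sum(is.na(x$geno))
  cat(sprintf("<geno_matrix> %d sites x %d samples (%.1f%% missing)\n",
              nrow(x$sites), length(x$samples),
              if (length(x$geno)) 100 * n_miss / length(x$geno) else 0))
  chroms <- unique(x$sites$chrom)
  if (length(chroms)) {
    cat("  chromosomes:", paste(utils::head(chroms, 6), collapse = ", "),
        if (length(chroms) > 6) "..." else "", "\n")
  }
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) c(nrow(x$sites), length(x$samples))

#' Convert a genotype matrix to a long tibble
#'
#' @param x A [geno_matrix()].
#' @param ... Unused.
#' @return A tibble with one row per site x sample: site columns plus
#'   `sample` and `genotype`.
#' @exportS3Method tibble::as_tibble
as_tibble.geno_matrix <- function(x, ...) {
  long <- tibble::tibble(
    site = rep(seq_len(nrow(x$sites)), times = length(x$samples)),
    sample = rep(x$samples, each = nrow(x$sites)),
    genotype = as.integer(x$geno)
  )
  dplyr::bind_cols(x$sites[long$site, , drop = FALSE],
                   long[, c("sample", "genotype")])
}

#' Subset a genotype matrix by sites and/or samples
#'
#' @param gm A [geno_matrix()].
#' @param sites Integer or logical index over site rows (default: all).
#' @param samples Character names, integer or logical index over samples.
#' @return A `geno_matrix`.
#' @export
gm_subset <- function(gm, sites = NULL, samples = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (is.null(sites)) sites <- seq_len(nrow(gm$sites))
  if (is.null(samples)) samples <- seq_along(gm$samples)
  if (is.character(samples)) samples <- match(samples, gm$samples)
  geno_matrix(gm$sites[sites, , drop = FALSE],
              gm$geno[sites, samples, drop = FALSE],
              gm$samples[samples])
}

# Column indices of a population's samples; errors on unlabelled samples.
pop_columns <- function(gm, labels, population) {
  labs <- labels$population[match(gm$samples, labels$sample)]
  if (anyNA(labs)) {
    stop("samples without a population label: ",
         paste(utils::head(gm$samples[is.na(labs)], 5), collapse = ", "),
         call. = FALSE)
  }
  which(labs %in% population)
}

# Per-site allele bookkeeping for a set of sample columns: non-missing
# haplotype count, alt-allele count and alt frequency.
site_allele_stats <- function(gm, cols) {
  g <- gm$geno[, cols, drop = FALSE]
  n_hap <- 2L * rowSums(!is.na(g))
  alt <- rowSums(g, na.rm = TRUE)
  p <- ifelse(n_hap > 0, alt / n_hap, NA_real_)
  list(n_hap = n_hap, alt = alt, p = p)
}

#' Read a sample-to-population label table
#'
#' Expects a tab-separated file with columns `sample`, `population`
#' (one of `P1`, `P2`, `HYB`, `OUT`) and optionally `source`
#' (`genome` or `transcriptome`).
#'
#' @param path File path.
#' @return A tibble with columns `sample`, `population`, `source`.
#' @export
read_labels <- function(path) {
  labs <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("sample", "population") %in% names(labs)))
  bad <- setdiff(unique(labs$population), c("P1", "P2", "HYB", "OUT"))
  if (length(bad)) {
    stop("unknown population labels: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(labs$source)) labs$source <- NA_character_
  tibble::as_tibble(labs[, c("sample", "population", "source")])
}
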