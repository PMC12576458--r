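#' Read a VCF file into a genotype matrix
#'
#' Parses a VCF v4.x file (via the vcfR parser) and converts biallelic
#' records with a GT field into genotype codes: `0/0 -> 0`, `0/1 -> 1`,
#' `1/1 -> 2`, `./. -> NA`. Multiallelic records and records whose FORMAT
#' lacks GT are skipped; their count is attached as the `n_skipped`
#' attribute and reported with a message.
#'
#' Site annotations are recovered from INFO keys when present:
#' `GENE=` (gene assignment), `REG=` (exon/intron/intergenic) and
#' `EFF=` (synonymous/nonsynonymous/noncoding) — the convention used by
#' [write_vcf()] and [write_dataset()]. Effect annotation is consumed, never
#' recomputed.
#'
#' @param path Path to a VCF file.
#' @param min_depth Optional per-genotype depth mask: when the VCF carries a
#'   DP FORMAT field, calls with depth strictly below `min_depth` are set to
#'   missing. `NULL` (default) leaves all calls untouched.
#' @return A [geno_matrix()] with attribute `n_skipped`.
#' @export
read_vcf <- function(path, min_depth = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, n = 1L)
  if (!length(lines) || !grepl("^##fileformat=VCF", lines[1])) {
    stop("missing VCF header (##fileformat) in ", path, call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  n_rec <- nrow(fix)
  if (is.null(n_rec) || n_rec == 0) {
    samples <- colnames(vcf@gt)
    samples <- samples[samples != "FORMAT"]
    if (is.null(samples)) samples <- character()
    empty <- tibble::tibble(chrom = character(), pos = integer(),
                            ref = character(), alt = character())
    gm <- geno_matrix(empty, matrix(integer(), 0, length(samples)), samples)
    attr(gm, "n_skipped") <- 0L
    return(gm)
  }
  alt <- fix[, "ALT"]
  fmt <- vcf@gt[, "FORMAT"]
  keep <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    vapply(strsplit(fmt, ":"), function(f) "GT" %in% f, logical(1))
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    message(sprintf("read_vcf: skipped %d multiallelic or GT-less record(s)",
                    n_skipped))
  }
  vcf <- vcf[keep, ]
  fix <- vcf@fix
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt_clean <- gsub("|", "/", gt, fixed = TRUE)
  codes <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  geno <- matrix(codes[gt_clean], nrow = nrow(gt), ncol = ncol(gt))
  missing_gt <- is.na(gt_clean) | gt_clean %in% c("./.", ".")
  bad <- which(is.na(geno) & !missing_gt, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]
    stop(sprintf("malformed GT '%s' at %s:%s (record %d)",
                 gt[bad[1, 1], bad[1, 2]], fix[i, "CHROM"], fix[i, "POS"], i),
         call. = FALSE)
  }
  if (!is.null(min_depth)) {
    dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP",
                                            as.numeric = TRUE))
    if (!is.null(dp) && any(!is.na(dp))) {
      geno[!is.na(dp) & dp < min_depth] <- NA_integer_
    }
  }
  info <- fix[, "INFO"]
  info_field <- function(key) {
    out <- rep(NA_character_, length(info))
    hit <- grepl(paste0("(?:^|;)", key, "="), info)
    out[hit] <- sub(paste0("^;?", key, "="), "",
                    regmatches(info, regexpr(paste0("(?:^|;)", key, "=[^;]+"),
                                             info)))
    out
  }
  sites <- tibble::tibble(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    gene_id = info_field("GENE"),
    region = info_field("REG"),
    effect = info_field("EFF")
  )
  samples <- colnames(gt)
  gm <- geno_matrix(sites, geno, samples)
  attr(gm, "n_skipped") <- n_skipped
  gm
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a valid VCF v4.2 file with `##contig` lines, GT-only FORMAT and the
#' package's INFO annotation keys (`GENE`, `REG`, `EFF`) for any non-missing
#' site annotation, so that `read_vcf(write_vcf(x))` reproduces `x`.
#'
#' @param gm A [geno_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "geno_matrix"))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot write to ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  s <- gm$sites
  chroms <- unique(s$chrom)
  for (ch in chroms) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>", ch,
                       max(s$pos[s$chrom == ch]) + 1000L), con)
  }
  writeLines(c(
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Assigned gene">',
    '##INFO=<ID=REG,Number=1,Type=String,Description="exon|intron|intergenic">',
    '##INFO=<ID=EFF,Number=1,Type=String,Description="Coding effect">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  ), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$samples), collapse = "\t"), con)
  if (nrow(s) > 0) {
    info <- rep("", nrow(s))
    add <- function(info, key, val) {
      has <- !is.na(val)
      piece <- paste0(key, "=", val[has])
      info[has] <- ifelse(info[has] == "", piece, paste0(info[has], ";", piece))
      info
    }
    info <- add(info, "GENE", s$gene_id)
    info <- add(info, "REG", s$region)
    info <- add(info, "EFF", s$effect)
    info[info == ""] <- "."
    gt <- matrix(c("0/0", "0/1", "1/1")[gm$geno + 1L],
                 nrow = nrow(s), ncol = length(gm$samples))
    gt[is.na(gm$geno)] <- "./."
    body <- paste(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS", info, "GT",
                  sep = "\t")
    if (length(gm$samples) > 0) {
      body <- paste(body, apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    }
    writeLines(body, con)
  }
  invisible(path)
}

#' Filter variants on minor-allele frequency and missingness
#'
#' Retains sites whose minor-allele frequency exceeds `min_maf` (computed
#' from allele counts of the non-missing diploid calls) and whose fraction of
#' missing calls is strictly below `max_missing` — the standard
#' resequencing-panel filter (MAF > 0.05, missing rate < 20%). Sites with all
#' calls missing are removed and counted.
#'
#' @param gm A [geno_matrix()].
#' @param min_maf Minor-allele-frequency threshold in `[0, 0.5]`; strict.
#' @param max_missing Maximum missing-call fraction in `[0, 1]`; strict.
#' @return A filtered `geno_matrix` (site order preserved) with attribute
#'   `filter_counts`, a named vector of removal tallies.
#' @export
filter_variants <- function(gm, min_maf = 0.05, max_missing = 0.20) {
  stopifnot(inherits(gm, "geno_matrix"),
            min_maf >= 0, min_maf <= 0.5, max_missing >= 0, max_missing <= 1)
  n_samp <- length(gm$samples)
  st <- site_allele_stats(gm, seq_len(n_samp))
  miss_frac <- 1 - (st$n_hap / 2) / n_samp
  maf <- pmin(st$p, 1 - st$p)
  all_missing <- st$n_hap == 0
  keep <- !all_missing & maf > min_maf & miss_frac < max_missing
  out <- gm_subset(gm, sites = which(keep))
  attr(out, "filter_counts") <- c(
    removed_all_missing = sum(all_missing),
    removed_maf = sum(!all_missing & maf <= min_maf),
    removed_missing = sum(!all_missing & maf > min_maf &
                            miss_frac >= max_missing),
    retained = sum(keep)
  )
  out
}

#' Read gene models from GFF3 or BED
#'
#' Accepts either a GFF3 file with `gene` and `exon` features (exons linked
#' to their gene through the `Parent`/`ID` attributes) or a BED-like
#' tab-separated table (>= 4 columns: chrom, start, end, name, optional
#' score and strand; 0-based half-open, converted to the internal 1-based
#' inclusive convention, with the whole span treated as a single exon).
#' Overlapping exons of a gene are merged with a warning.
#'
#' @param path File path; format chosen by extension (`.gff`/`.gff3` vs
#'   `.bed`) or overridden with `format`.
#' @param format `"auto"`, `"gff3"` or `"bed"`.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` and `exons` (list column of two-column integer matrices with
#'   columns `start`, `end`, 1-based inclusive).
#' @export
read_gene_models <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  if (format == "bed") {
    bed <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                           show_col_types = FALSE)
    stopifnot(ncol(bed) >= 4)
    genes <- tibble::tibble(
      gene_id = as.character(bed[[4]]),
      chrom = as.character(bed[[1]]),
      start = as.integer(bed[[2]]) + 1L,
      end = as.integer(bed[[3]]),
      strand = if (ncol(bed) >= 6) as.character(bed[[6]]) else "+",
      exons = purrr::map2(start, end,
                          ~cbind(start = .x, end = .y))
    )
    return(validate_gene_models(genes))
  }
  gff <- ape::read.gff(path)
  attr_field <- function(x, key) {
    hit <- regexpr(paste0("(?:^|;)", key, "=[^;]+"), x)
    out <- rep(NA_character_, length(x))
    ok <- hit > 0
    out[ok] <- sub(paste0("^;?", key, "="), "", regmatches(x, hit))
    out
  }
  is_gene <- gff$type == "gene"
  gene_tab <- gff[is_gene, , drop = FALSE]
  gene_ids <- attr_field(gene_tab$attributes, "ID")
  exon_tab <- gff[gff$type == "exon", , drop = FALSE]
  exon_parent <- attr_field(exon_tab$attributes, "Parent")
  genes <- tibble::tibble(
    gene_id = gene_ids,
    chrom = as.character(gene_tab$seqid),
    start = as.integer(gene_tab$start),
    end = as.integer(gene_tab$end),
    strand = as.character(gene_tab$strand)
  )
  genes$exons <- purrr::map(gene_ids, function(id) {
    ex <- exon_tab[!is.na(exon_parent) & exon_parent == id, , drop = FALSE]
    if (nrow(ex) == 0) return(cbind(start = integer(), end = integer()))
    cbind(start = as.integer(ex$start), end = as.integer(ex$end))
  })
  # genes without exon features: span as single exon
  no_ex <- vapply(genes$exons, nrow, integer(1)) == 0
  genes$exons[no_ex] <- purrr::map2(genes$start[no_ex], genes$end[no_ex],
                                    ~cbind(start = .x, end = .y))
  validate_gene_models(genes)
}

# Sort/merge exons, enforce span invariants.
validate_gene_models <- function(genes) {
  merged_any <- FALSE
  genes$exons <- purrr::pmap(
    list(genes$exons, genes$gene_id, genes$start, genes$end),
    function(ex, id, gs, ge) {
      if (any(ex[, "start"] < gs) || any(ex[, "end"] > ge)) {
        stop("exon outside gene span in gene ", id, call. = FALSE)
      }
      ex <- ex[order(ex[, "start"]), , drop = FALSE]
      if (nrow(ex) > 1) {
        out <- ex[1, , drop = FALSE]
        for (i in 2:nrow(ex)) {
          if (ex[i, "start"] <= out[nrow(out), "end"] + 0L) {
            if (ex[i, "start"] <= out[nrow(out), "end"]) merged_any <<- TRUE
            out[nrow(out), "end"] <- max(out[nrow(out), "end"], ex[i, "end"])
          } else {
            out <- rbind(out, ex[i, , drop = FALSE])
          }
        }
        ex <- out
      }
      ex
    })
  if (merged_any) warning("overlapping exons merged", call. = FALSE)
  stopifnot(all(genes$start <= genes$end))
  genes
}

#' Assign sites to genes and genic regions
#'
#' Fills the `gene_id` and `region` columns of a genotype matrix from a gene
#' model table: a site inside a gene span is assigned to that gene (ties
#' between overlapping genes broken by smallest span, then lexicographic
#' gene id), labelled `exon` when inside any exon of the assigned gene and
#' `intron` otherwise; sites outside all genes are `intergenic`.
#'
#' @param gm A [geno_matrix()].
#' @param genes Gene model tibble from [read_gene_models()].
#' @return The `geno_matrix` with `gene_id` and `region` filled. Existing
#'   `effect` labels are preserved.
#' @export
assign_sites_to_genes <- function(gm, genes) {
  stopifnot(inherits(gm, "geno_matrix"))
  s <- gm$sites
  gene_id <- rep(NA_character_, nrow(s))
  region <- rep("intergenic", nrow(s))
  span <- genes$end - genes$start + 1L
  for (ch in unique(s$chrom)) {
    si <- which(s$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (!length(si) || !length(gi)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(s$pos[si], s$pos[si]),
      IRanges::IRanges(genes$start[gi], genes$end[gi])
    )
    if (!length(hits)) next
    hit_tbl <- tibble::tibble(
      site = si[S4Vectors::queryHits(hits)],
      gene = gi[S4Vectors::subjectHits(hits)]
    )
    hit_tbl <- hit_tbl[order(hit_tbl$site, span[hit_tbl$gene],
                             genes$gene_id[hit_tbl$gene]), ]
    hit_tbl <- hit_tbl[!duplicated(hit_tbl$site), ]
    gene_id[hit_tbl$site] <- genes$gene_id[hit_tbl$gene]
    in_exon <- purrr::map2_lgl(hit_tbl$site, hit_tbl$gene, function(i, g) {
      ex <- genes$exons[[g]]
      any(s$pos[i] >= ex[, "start"] & s$pos[i] <= ex[, "end"])
    })
    region[hit_tbl$site] <- ifelse(in_exon, "exon", "intron")
  }
  gm$sites$gene_id <- gene_id
  gm$sites$region <- region
  gm
}

#' Read an allele-resolved RNA read-count table
#'
#' Tab-separated with header columns `gene_id`, `sample`, `tissue`,
#' `condition`, `count_p1`, `count_p2`. Counts must be non-negative integers
#' and (gene, sample, tissue, condition) unique.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_allele_counts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("gene_id", "sample", "tissue", "condition", "count_p1", "count_p2")
  stopifnot(all(need %in% names(x)))
  if (any(x$count_p1 < 0) || any(x$count_p2 < 0) ||
      any(x$count_p1 != round(x$count_p1)) ||
      any(x$count_p2 != round(x$count_p2))) {
    stop("allele counts must be non-negative integers", call. = FALSE)
  }
  if (anyDuplicated(x[, c("gene_id", "sample", "tissue", "condition")])) {
    stop("duplicate (gene, sample, tissue, condition) records", call. = FALSE)
  }
  tibble::as_tibble(x[, need])
}

#' Read genomic regions from a BED file
#'
#' 0-based half-open BED intervals converted to 1-based inclusive.
#'
#' @param path File path.
#' @return A tibble with columns `chrom`, `start`, `end`, `label`.
#' @export
read_regions_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE)
  tibble::tibble(
    chrom = as.character(bed[[1]]),
    start = as.integer(bed[[2]]) + 1L,
    end = as.integer(bed[[3]]),
    label = if (ncol(bed) >= 4) as.character(bed[[4]]) else
      paste0("region", seq_len(nrow(bed)))
  )
}
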