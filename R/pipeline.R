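#' Run the full analysis pipeline on a synthetic dataset
#'
#' Chains every stage in dependency order on a simulated study —
#' variant filtering, windowed diversity/differentiation scan with sweep
#' candidates, diagnostic-site discovery and hybrid genotyping, gene-level
#' ASE testing and classification, the HKA scan with PSG selection,
#' inversion genotyping with the LD contrast, and the four-taxon D test —
#' then scores every stage against the planted ground truth. Identical
#' configs produce identical results.
#'
#' @param config A [sim_config()] describing the synthetic study, or an
#'   existing `sim_dataset`.
#' @param out_dir Optional directory; when given, stage outputs are written
#'   as TSV/JSON via [write_pipeline_outputs()].
#' @param window_size,window_step Sweep-scan window geometry (defaults
#'   20 kb / 5 kb).
#' @param top_fraction Sweep-candidate fraction (default 0.01).
#' @param min_het Minimum heterozygous hybrids per diagnostic site.
#' @param inversion_min_sites Minimum diagnostic sites per inversion call.
#' @return A list of class `pipeline_result` with elements `dataset`,
#'   `filtered`, `scan`, `diagnostics`, `gene_diagnoses`, `ase`,
#'   `classification`, `hka`, `inversion_calls`, `ld`, `dstat` and
#'   `report` (the truth-versus-called [evaluation report][evaluate_run]).
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         window_size = 20000, window_step = 5000,
                         top_fraction = 0.01, min_het = 3,
                         inversion_min_sites = 20) {
  dataset <- if (inherits(config, "sim_dataset")) config else
    simulate_dataset(config)
  cfg <- dataset$config
  gm <- assign_sites_to_genes(dataset$gm, dataset$genes)
  labels <- dataset$labels

  filtered <- filter_variants(gm)

  chrom_lengths <- stats::setNames(rep(cfg$chrom_length, cfg$n_chrom),
                                   paste0("chr", seq_len(cfg$n_chrom)))
  scan <- sweep_scan(filtered, labels, chrom_lengths = chrom_lengths,
                     rod_target = cfg$sweep_pop,
                     rod_control = if (cfg$sweep_pop == "P1") "P2" else "P1",
                     size = window_size, step = window_step,
                     top_fraction = top_fraction)

  diag <- find_diagnostic_sites(gm, labels)
  diag <- genotype_hybrids(diag, gm, labels, min_het = min_het)
  gene_diag <- assemble_gene_diagnoses(diag)

  usable_genes <- gene_diag$gene_id[gene_diag$usable]
  counts_usable <- dataset$counts[dataset$counts$gene_id %in% usable_genes, ]
  ase <- ase_test(counts_usable)
  classification <- classify_asegs(ase)

  hka <- hka_scan(gm, labels)
  hka <- select_psgs(hka, gm, labels)

  hyb_samples <- labels$sample[labels$population == "HYB"]
  inv_calls <- genotype_inversions(gm, diag, dataset$truth$inversions,
                                   samples = hyb_samples,
                                   min_sites = inversion_min_sites)
  ld <- ld_contrast(gm, dataset$truth$inversions, samples = hyb_samples)

  dstat <- block_jackknife_z(dataset$four_taxon, dataset$four_taxon$block)

  result <- structure(
    list(dataset = dataset, filtered = filtered, scan = scan,
         diagnostics = diag, gene_diagnoses = gene_diag, ase = ase,
         classification = classification, hka = hka,
         inversion_calls = inv_calls, ld = ld, dstat = dstat),
    class = "pipeline_result")
  result$report <- evaluate_run(result)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' Score a pipeline run against its planted ground truth
#'
#' Computes per-stage recovery metrics: precision/recall of diagnostic-site
#' discovery, sweep-window recall, ASE sensitivity / direction accuracy /
#' empirical FDR and class accuracy, PSG recall and precision, inversion
#' genotyping accuracy, the D and Z of the four-taxon test, and the LD
#' contrast difference.
#'
#' @param result A `pipeline_result`.
#' @return A tibble of class `evaluation_report` with columns `metric`,
#'   `value`, `n`.
#' @export
evaluate_run <- function(result) {
  truth <- result$dataset$truth
  gm <- result$dataset$gm
  out <- list()
  add <- function(metric, value, n) {
    out[[length(out) + 1]] <<- tibble::tibble(metric = metric,
                                              value = as.numeric(value),
                                              n = as.numeric(n))
  }

  # diagnostic sites: precision against all effectively fixed-discordant
  # sites, recall against the planted (hybrid-heterozygous) subset
  called <- result$diagnostics$site[result$diagnostics$qualifies]
  planted <- truth$diagnostic_sites
  discordant <- if (!is.null(truth$discordant_sites))
    truth$discordant_sites else planted
  add("diagnostic_precision", mean(called %in% discordant), length(called))
  add("diagnostic_recall", mean(planted %in% called), length(planted))

  # sweep windows: recall of planted-overlap among candidates
  scan <- result$scan
  in_sweep <- rep(FALSE, nrow(scan))
  contained <- rep(FALSE, nrow(scan))
  for (i in seq_len(nrow(truth$sweeps))) {
    in_sweep <- in_sweep | (scan$chrom == truth$sweeps$chrom[i] &
                              scan$start1 <= truth$sweeps$end[i] &
                              scan$end1 >= truth$sweeps$start[i])
    contained <- contained | (scan$chrom == truth$sweeps$chrom[i] &
                                scan$start1 >= truth$sweeps$start[i] &
                                scan$end1 <= truth$sweeps$end[i])
  }
  add("sweep_candidate_hit",
      as.numeric(any(scan$candidate_rod & in_sweep)), sum(in_sweep))
  add("sweep_mean_rod_in_sweep", mean(scan$rod[contained], na.rm = TRUE),
      sum(contained))

  # ASE recovery
  cls <- result$classification$genes
  tr <- truth$ase
  merged <- dplyr::inner_join(cls, tr, by = "gene_id",
                              suffix = c("_called", "_true"))
  biased <- merged$class_true %in% c("consistent", "direction_shifting",
                                     "non_directional")
  if (any(biased)) {
    add("ase_sensitivity", mean(merged$class_called[biased] != "not_aseg"),
        sum(biased))
    add("ase_class_accuracy",
        mean(merged$class_called[biased] == merged$class_true[biased]),
        sum(biased))
  }
  null_genes <- merged$class_true == "none"
  sig_calls <- merged$class_called != "not_aseg"
  if (any(sig_calls)) {
    add("ase_empirical_fdr", mean(null_genes[sig_calls]), sum(sig_calls))
  }
  dir_tab <- dplyr::inner_join(
    result$ase[result$ase$bias %in% c("P1", "P2"), ],
    tibble::tibble(gene_id = tr$gene_id, class = tr$class,
                   direction = tr$direction),
    by = "gene_id")
  dir_tab <- dir_tab[dir_tab$class == "consistent", ]
  if (nrow(dir_tab)) {
    add("ase_direction_accuracy",
        mean(dir_tab$bias == dir_tab$direction), nrow(dir_tab))
  }

  # PSGs
  called_psg <- result$hka$gene_id[result$hka$psg]
  if (length(truth$psg_genes)) {
    add("psg_recall", mean(truth$psg_genes %in% called_psg),
        length(truth$psg_genes))
    if (length(called_psg)) {
      add("psg_precision", mean(called_psg %in% truth$psg_genes),
          length(called_psg))
    }
  }

  # inversions
  ic <- result$inversion_calls
  if (nrow(ic)) {
    ic$truth <- truth$inversion_genotypes[ic$sample]
    add("inversion_accuracy", mean(ic$call == ic$truth), nrow(ic))
  }

  # D statistic
  add("d_statistic", result$dstat$D, result$dstat$n_sites)
  add("d_z", result$dstat$Z, result$dstat$n_blocks)

  # LD contrast
  add("ld_r2_difference", result$ld$difference, nrow(result$ld$bins))

  report <- dplyr::bind_rows(out)
  class(report) <- c("evaluation_report", class(report))
  report
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$report)
  invisible(x)
}

#' Write pipeline stage outputs to a directory
#'
#' Emits the window-statistics TSV, diagnostic-site and gene-diagnosis
#' TSVs, ASE result and classification TSVs, the HKA/PSG TSV, inversion
#' calls TSV, and JSON summaries for the D test, LD contrast and the
#' evaluation report.
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory.
#' @return Named file paths, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(name) file.path(dir, name)
  readr::write_tsv(tibble::as_tibble(result$scan), p("window_stats.tsv"))
  readr::write_tsv(result$diagnostics, p("diagnostic_sites.tsv"))
  readr::write_tsv(result$gene_diagnoses, p("gene_diagnoses.tsv"))
  readr::write_tsv(result$ase, p("ase_results.tsv"))
  readr::write_tsv(result$classification$genes, p("aseg_classes.tsv"))
  hka_flat <- result$hka[, setdiff(names(result$hka), "fixed_sites")]
  readr::write_tsv(tibble::as_tibble(hka_flat), p("hka_psg.tsv"))
  readr::write_tsv(result$inversion_calls, p("inversion_calls.tsv"))
  jsonlite::write_json(
    list(abba = result$dstat$abba, baba = result$dstat$baba,
         D = result$dstat$D, Z = result$dstat$Z,
         n_blocks = result$dstat$n_blocks),
    p("dstat.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(mean_r2_inversion = result$ld$mean_r2_inversion,
         mean_r2_background = result$ld$mean_r2_background,
         difference = result$ld$difference),
    p("ld_contrast.json"), auto_unbox = TRUE, digits = NA)
  readr::write_tsv(result$report, p("evaluation_report.tsv"))
  invisible(c(dir = dir))
}
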