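#' Run the end-to-end selection-scan pipeline
#'
#' Orchestrates simulate (or load) -> QC -> scan -> standardize ->
#' window -> peak call -> merge regions -> gene intersection, writing
#' every intermediate as plain TSV/BED next to a run log (config hash,
#' seed, per-stage record counts). Re-running with an identical config
#' and seed reproduces identical outputs.
#'
#' The `config` list understands the sections:
#' \describe{
#'   \item{seed}{Integer; seeds all randomness.}
#'   \item{simulate}{`list(n_hap, n_site, sweep = list(core_index,
#'     target_daf, halfwidth, template_noise), ...)` — panel arguments
#'     passed to [simulate_panel()]; omit `sweep` for a neutral panel.}
#'   \item{vcf}{Path to a phased VCF (alternative to `simulate`).}
#'   \item{scan}{`list(metric, maf_floor, cutoff, truncation)`.}
#'   \item{standardize}{`list(n_daf_bins, min_bin_count)`.}
#'   \item{peaks}{`list(window_size, seed_threshold, edge_threshold)`.}
#'   \item{genes}{Path to a GFF3 file for gene-peak intersection.}
#' }
#'
#' @param config Nested configuration list (see Details).
#' @param out_dir Output directory (created if missing).
#' @return A `sweep_run` list with elements `scores`, `windows`, `peaks`,
#'   `regions`, `genes`, `files`, `log`; inspect with [glance()] and
#'   [tidy()].
#' @export
run_selection_pipeline <- function(config, out_dir) {
  if (is.null(config$simulate) && is.null(config$vcf)) {
    abort("config must provide either a 'simulate' section or a 'vcf' path")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  log_lines <- c(sprintf("config_hash: %s", rlang::hash(config)),
                 sprintf("seed: %d", as.integer(seed)))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  hap <- stage("input", {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      set.seed(as.integer(seed))
      panel_args <- sim[setdiff(names(sim), "sweep")]
      panel <- do.call(simulate_panel, panel_args)
      if (!is.null(sim$sweep)) {
        panel <- do.call(implant_sweep, c(list(panel), sim$sweep))
      }
      panel
    } else {
      vcf_to_hap(read_vcf(config$vcf))
    }
  })
  log_lines <- c(log_lines,
                 sprintf("input: %d haplotypes x %d sites",
                         n_haplotypes(hap), n_sites(hap)))

  sc <- config$scan %||% list()
  scores <- stage("scan", do.call(scan_haplotypes, c(list(hap), sc)))
  st <- config$standardize %||% list()
  scores <- stage("standardize",
                  do.call(standardize_scores, c(list(scores), st)))
  log_lines <- c(log_lines,
                 sprintf("scan: %d sites, %d valid", nrow(scores),
                         sum(scores$valid)))

  pk <- config$peaks %||% list()
  windows <- stage("windows",
                   window_means(scores, pk$window_size %||% 100))
  peaks <- stage("peaks", call_peaks(
    windows, seed_threshold = pk$seed_threshold %||% 1.5,
    edge_threshold = pk$edge_threshold %||% 0.5))
  regions <- stage("regions", merge_peak_regions(peaks))
  log_lines <- c(log_lines,
                 sprintf("windows: %d; peaks: %d; regions: %d",
                         nrow(windows), nrow(peaks), nrow(regions)))

  genes <- NULL
  if (!is.null(config$genes)) {
    gene_models <- stage("genes", read_gff3_genes(config$genes))
    genes <- stage("genes", genes_in_peaks(peaks, gene_models))
    log_lines <- c(log_lines, sprintf("gene overlaps: %d", nrow(genes)))
  }

  files <- c(scores = file.path(out_dir, "scores.tsv"),
             windows = file.path(out_dir, "windows.tsv"),
             peaks = file.path(out_dir, "peaks.tsv"),
             regions = file.path(out_dir, "regions.bed"),
             log = file.path(out_dir, "run_log.txt"))
  readr::write_tsv(tibble::as_tibble(scores), files[["scores"]])
  readr::write_tsv(tibble::as_tibble(windows), files[["windows"]])
  readr::write_tsv(tibble::as_tibble(peaks), files[["peaks"]])
  write_bed(regions, files[["regions"]])
  if (!is.null(genes)) {
    files <- c(files, genes = file.path(out_dir, "genes.tsv"))
    readr::write_tsv(genes, files[["genes"]])
  }
  readr::write_lines(log_lines, files[["log"]])

  structure(list(scores = scores, windows = windows, peaks = peaks,
                 regions = regions, genes = genes, files = files,
                 log = log_lines, hap = hap),
            class = "sweep_run")
}

#' @export
print.sweep_run <- function(x, ...) {
  cat("<sweep_run>\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}
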