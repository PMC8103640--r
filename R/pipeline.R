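PIPELINE_CONFIG_KEYS <- c("vcf", "gff", "pop_tolerance", "pop_control",
                          "out_dir", "window", "step", "top", "combine",
                          "min_snps", "min_call_rate", "gene2go", "seed")

#' Read (or normalize) a pipeline configuration
#'
#' Accepts a YAML file path or a named list; fills defaults and rejects
#' unknown keys.
#'
#' @param config YAML path or named list.
#' @return Normalized configuration list of class `run_config`.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), PIPELINE_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(window = 40000, step = 20000, top = 0.05,
                   combine = "intersection", min_snps = 10,
                   min_call_rate = 0, gene2go = NULL, seed = 1L)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  for (k in c("vcf", "gff", "pop_tolerance", "pop_control", "out_dir"))
    if (is.null(config[[k]])) stop("config key '", k, "' is required")
  structure(config, class = "run_config")
}

#' Validate pipeline input files
#'
#' Per-file format checks with machine-readable pass/fail reasons: VCF
#' header and samples, GFF3 feature types, population IDs being VCF samples,
#' FASTA line discipline for any sequence inputs.
#'
#' @param config A configuration (path or list; see [read_run_config()]).
#' @return data.frame `input`, `ok`, `reason`; all-pass means zero `ok ==
#'   FALSE` rows.
#' @export
validate_inputs <- function(config) {
  config <- read_run_config(config)
  checks <- list()
  add <- function(input, ok, reason = "")
    checks[[length(checks) + 1L]] <<- data.frame(input = input, ok = ok,
                                                 reason = reason,
                                                 stringsAsFactors = FALSE)
  for (k in c("vcf", "gff", "pop_tolerance", "pop_control")) {
    if (!file.exists(config[[k]])) add(k, FALSE, paste0("missing file: ", config[[k]]))
  }
  if (length(checks)) return(do.call(rbind, checks))

  first <- readLines(config$vcf, n = 1L)
  if (!startsWith(first, "##fileformat=VCF"))
    add("vcf", FALSE, "missing ##fileformat=VCF header")
  vcf_samples <- tryCatch({
    hdr <- grep("^#CHROM", readLines(config$vcf, n = 500L), value = TRUE)
    strsplit(hdr[1], "\t")[[1]][-(1:9)]
  }, error = function(e) character(0))
  if (!length(vcf_samples)) add("vcf", FALSE, "no sample columns")

  for (k in c("pop_tolerance", "pop_control")) {
    ids <- readLines(config[[k]])
    ids <- ids[nzchar(ids)]
    if (!length(ids)) add(k, FALSE, "empty population file")
    missing <- setdiff(ids, vcf_samples)
    if (length(missing))
      add(k, FALSE, paste0("IDs absent from VCF: ", paste(missing, collapse = ",")))
  }

  gff_ok <- tryCatch({
    genes <- suppressWarnings(read_gff_genes(config$gff))
    nrow(genes) > 0L
  }, error = function(e) { add("gff", FALSE, conditionMessage(e)); TRUE })
  if (!isTRUE(gff_ok)) add("gff", FALSE, "no gene features")

  if (!length(checks))
    return(data.frame(input = character(), ok = logical(), reason = character()))
  do.call(rbind, checks)
}

#' Run the selective-sweep pipeline end to end
#'
#' Reads the VCF and populations, computes windowed Fst / diversity
#' statistics, screens the top fraction of both statistics, merges the
#' combined windows into sweep regions, extracts candidate genes from the
#' GFF and (when an annotation is configured) performs GO enrichment.
#' All stage outputs are written under `out_dir` together with the resolved
#' configuration and a run manifest; outputs are byte-identical across runs
#' of the same configuration.
#'
#' @param config YAML path or named list; see [read_run_config()]. Keys:
#'   `vcf`, `gff`, `pop_tolerance`, `pop_control` (one sample ID per line),
#'   `out_dir`, and optional `window`, `step`, `top`, `combine`, `min_snps`,
#'   `min_call_rate`, `gene2go`.
#' @return Invisibly, a list with the stage results and output paths.
#' @export
run_sweep_pipeline <- function(config) {
  config <- read_run_config(config)
  fails <- validate_inputs(config)
  fails <- fails[!fails$ok, , drop = FALSE]
  if (nrow(fails))
    stop("input validation failed: ",
         paste(sprintf("%s (%s)", fails$input, fails$reason), collapse = "; "))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0))
    res
  }

  gm <- stage("read_vcf", read_vcf_biallelic(config$vcf, config$min_call_rate))
  split <- stage("populations", population_split(
    readLines(config$pop_tolerance), readLines(config$pop_control), gm))
  scan <- stage("scan", sweep_scan(
    gm, split, size = config$window, step = config$step, q = config$top,
    min_snps = config$min_snps, combine = config$combine))
  genes <- stage("genes", genes_in_regions(config$gff, scan$regions))

  win <- scan$windows
  num <- vapply(win, is.numeric, logical(1)) &
    !names(win) %in% c("start", "end", "n_snps")
  win[num] <- lapply(win[num], function(x) round(x, 8))
  write_tsv(win, file.path(out_dir, "windows.tsv"))
  jsonlite::write_json(
    list(fst_threshold = scan$top_fst$threshold,
         ratio_threshold = scan$top_ratio$threshold,
         n_windows_fst_ranked = scan$top_fst$n_usable,
         n_windows_ratio_ranked = scan$top_ratio$n_usable,
         n_selected_fst = nrow(scan$top_fst$selected),
         n_selected_ratio = nrow(scan$top_ratio$selected),
         n_regions = nrow(scan$regions$regions)),
    file.path(out_dir, "thresholds.json"), auto_unbox = TRUE, digits = NA)
  write_bed3(scan$regions$regions, file.path(out_dir, "regions.bed"))
  write_tsv(genes, file.path(out_dir, "candidate_genes.tsv"))

  enr <- NULL
  if (!is.null(config$gene2go)) {
    term2genes <- read_gene2go(config$gene2go)
    enr <- stage("enrichment", go_enrichment(genes$gene_id, term2genes))
    write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
  }

  resolved <- unclass(config)
  yaml::write_yaml(resolved, file.path(out_dir, "config_resolved.yaml"))
  manifest <- list(
    package = "medsweep",
    version = as.character(packageVersion("medsweep")),
    config_hash = unname(tools::md5sum(file.path(out_dir, "config_resolved.yaml"))),
    n_sites = nrow(gm$sites), n_samples = length(gm$sample_ids),
    n_windows = nrow(scan$windows), n_regions = nrow(scan$regions$regions),
    n_candidate_genes = nrow(genes))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(gm = gm, scan = scan, genes = genes, enrichment = enr,
                 out_dir = out_dir))
}
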