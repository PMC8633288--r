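# End-to-end orchestration: a single YAML (or list) configuration drives
# simulate -> filter -> scan -> finemap, counts -> deg, and fasta -> motifs,
# with every output checksummed into a manifest so a rerun is verifiable.

stage_error <- function(stage, parent) {
  abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(parent)))
}

require_input <- function(cfg, stage, key) {
  val <- cfg[[stage]][[key]]
  if (is.null(val)) {
    abort(sprintf("config error: stage '%s' needs input '%s'", stage, key))
  }
  if (is.character(val) && !file.exists(val)) {
    abort(sprintf("config error: stage '%s' input '%s' not found: %s",
                  stage, key, val))
  }
  val
}

#' Run the pipeline from a configuration
#'
#' Executes the selected stages in dependency order and writes a
#' `manifest.json` recording inputs, parameters, the seed, and an MD5
#' checksum of every output, so two runs from the same configuration can be
#' compared byte for byte.
#'
#' Supported stages and their blocks:
#' \describe{
#'   \item{`simulate`}{any [sim_config()] argument; writes `bulks.vcf` and
#'     `truth.tsv`.}
#'   \item{`scan`}{`window_kb`, `step_kb`, `alpha`, `n_sims`; consumes the
#'     simulated bulks (after the default retention filters) and writes
#'     `snp_index.tsv`, `windows.tsv`, and `regions.bed` (0-based half-open
#'     BED with the peak absolute delta in the score column).}
#'   \item{`finemap`}{`markers` and `lines` TSV paths; writes
#'     `interval.tsv`.}
#'   \item{`deg`}{`counts` and `samples` TSV paths, `control`, optional
#'     `min_k`; writes one `deg_<comparison>.tsv` per comparison and
#'     `shared_down.txt`.}
#'   \item{`motifs`}{`fasta` and `pwm` paths, optional `min_rel_score`;
#'     writes `motif_hits.tsv`.}
#' }
#'
#' @param config Path to a YAML file or an equivalent named list. Top-level
#'   keys: `out_dir`, `seed`, `stages` (character vector), plus one optional
#'   block per stage.
#' @return The manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(sprintf("config error: file not found: %s", config))
    }
    config <- yaml::read_yaml(config)
  }
  stages <- config$stages %||% "simulate"
  known <- c("simulate", "scan", "finemap", "deg", "motifs")
  if (any(!stages %in% known)) {
    abort(sprintf("config error: unknown stage(s): %s",
                  paste(setdiff(stages, known), collapse = ", ")))
  }
  out_dir <- config$out_dir %||% abort("config error: out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  outputs <- character(0)
  params <- list()

  if ("scan" %in% stages && !"simulate" %in% stages) {
    abort("config error: stage 'scan' needs stage 'simulate' (it consumes the simulated bulks)")
  }

  sim <- NULL
  if ("simulate" %in% stages) {
    tryCatch({
      sim_args <- config$simulate %||% list()
      sim_args$seed <- seed
      cfg <- do.call(sim_config, sim_args)
      pop <- simulate_f2_population(cfg)
      bulks <- select_bulks(pop)
      records <- simulate_bulk_reads(pop, bulks$high, bulks$low, cfg)
      vcf_path <- file.path(out_dir, "bulks.vcf")
      truth_path <- file.path(out_dir, "truth.tsv")
      write_bulk_vcf(records, vcf_path)
      write_truth_tsv(pop, cfg, truth_path)
      outputs <- c(outputs, vcf_path, truth_path)
      params$simulate <- sim_args
      sim <- list(cfg = cfg, records = records, bulks = bulks)
    }, error = function(e) stage_error("simulate", e))
  }

  if ("scan" %in% stages) {
    tryCatch({
      sc <- config$scan %||% list()
      filtered <- apply_quality_filters(sim$records)
      scan <- bsa_scan(
        filtered,
        chrom_length = sim$cfg$chrom_length_bp,
        window_bp = (sc$window_kb %||% 1000) * 1e3,
        step_bp = (sc$step_kb %||% 10) * 1e3,
        n_high = length(sim$bulks$high), n_low = length(sim$bulks$low),
        alpha = sc$alpha %||% 0.01, n_sims = sc$n_sims %||% 1000,
        seed = seed
      )
      idx_path <- file.path(out_dir, "snp_index.tsv")
      win_path <- file.path(out_dir, "windows.tsv")
      bed_path <- file.path(out_dir, "regions.bed")
      readr::write_tsv(scan$points, idx_path)
      readr::write_tsv(
        dplyr::mutate(scan$windows, start0 = .data$start - 1L,
                      .before = "start"),
        win_path
      )
      # BED: 0-based half-open, peak |delta| in the score column
      bed <- scan$regions
      writeLines(
        if (nrow(bed) == 0L) character(0) else sprintf(
          "%s\t%d\t%d\tcandidate_%d\t%.4f\t.",
          bed$chrom, bed$start - 1L, bed$end - 1L, seq_len(nrow(bed)),
          bed$peak_abs_delta),
        bed_path
      )
      outputs <- c(outputs, idx_path, win_path, bed_path)
      params$scan <- sc
    }, error = function(e) stage_error("scan", e))
  }

  if ("finemap" %in% stages) {
    tryCatch({
      markers <- readr::read_tsv(require_input(config, "finemap", "markers"),
                                 show_col_types = FALSE)
      lines <- readr::read_tsv(require_input(config, "finemap", "lines"),
                               show_col_types = FALSE)
      fm <- narrow_interval(lines, marker_map(markers))
      out <- file.path(out_dir, "interval.tsv")
      readr::write_tsv(glance(fm), out)
      outputs <- c(outputs, out)
      params$finemap <- config$finemap
    }, error = function(e) stage_error("finemap", e))
  }

  if ("deg" %in% stages) {
    tryCatch({
      counts <- readr::read_tsv(require_input(config, "deg", "counts"),
                                show_col_types = FALSE)
      samples <- readr::read_tsv(require_input(config, "deg", "samples"),
                                 show_col_types = FALSE)
      control <- config$deg$control %||%
        abort("config error: stage 'deg' needs 'control'")
      res <- deg_analysis(counts, samples, control = control)
      for (cmp in unique(res$table$comparison)) {
        f <- file.path(out_dir,
                       sprintf("deg_%s.tsv", gsub("[^A-Za-z0-9._-]", "_", cmp)))
        readr::write_tsv(res$table[res$table$comparison == cmp, ], f)
        outputs <- c(outputs, f)
      }
      sd_path <- file.path(out_dir, "shared_down.txt")
      writeLines(shared_down(res, min_k = config$deg$min_k %||% 2), sd_path)
      outputs <- c(outputs, sd_path)
      params$deg <- config$deg
    }, error = function(e) stage_error("deg", e))
  }

  if ("motifs" %in% stages) {
    tryCatch({
      fasta <- require_input(config, "motifs", "fasta")
      pwm <- load_pwm(require_input(config, "motifs", "pwm"))
      seqs <- Biostrings::readDNAStringSet(fasta)
      hits <- dplyr::bind_rows(lapply(seq_along(seqs), function(i) {
        scan_pwm(seqs[[i]], pwm,
                 min_rel_score = config$motifs$min_rel_score %||% 0.8,
                 seq_id = names(seqs)[i] %||% sprintf("seq%d", i))
      }))
      out <- file.path(out_dir, "motif_hits.tsv")
      readr::write_tsv(hits, out)
      outputs <- c(outputs, out)
      params$motifs <- config$motifs
    }, error = function(e) stage_error("motifs", e))
  }

  manifest <- list(
    stages = stages,
    seed = seed,
    params = params,
    outputs = lapply(setNames(outputs, basename(outputs)), function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
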