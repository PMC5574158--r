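# Configuration files, fixtures and run manifests.

config_keys <- c("architecture", "model", "direction", "n_generations",
                 "N", "n_sires", "n_dams", "offspring_per_mating",
                 "burn_generations", "n_replicates", "n_sites", "n_lines",
                 "sfs_shape", "n_qtn_large", "n_qtn_small", "exp_rate",
                 "target_H2", "target_corr", "target_mean_p_plus",
                 "n_iter", "burn_in", "progeny_test_n",
                 "progeny_test_offspring", "keep_populations", "seed")

#' Read an experiment configuration from a YAML file
#'
#' Unknown keys are rejected by name; missing keys take the defaults of
#' [experiment_config()].  `parse -> write -> parse` is the identity.
#'
#' @param path YAML file.
#' @return an `episel_config`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), config_keys)
  if (length(unknown))
    stop_invalid("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(experiment_config, raw)
}

#' Write an experiment configuration to YAML
#' @param config an `episel_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Build a small self-contained test fixture
#'
#' `"tiny"` (3 chromosomes x 200 sites, 20 founder lines, 8 QTN in 4
#' pairs, N = 40) runs the full pipeline in seconds; `"small"` (2,000
#' sites, 205 lines, 400 QTN, N = 250) exercises one desk-scale
#' replicate end-to-end.
#'
#' @param size `"tiny"` or `"small"`.
#' @param seed integer seed.
#' @param architecture,model,direction forwarded to the config.
#' @return list with `panel`, `qtn`, `trait` (uncalibrated) and
#'   `config`.
#' @export
make_fixture <- function(size = c("tiny", "small"), seed = 1L,
                         architecture = "additive", model = "A-SEQ",
                         direction = "up") {
  size <- match.arg(size)
  seeds <- child_seeds(seed, 3L)
  if (size == "tiny") {
    n_sites <- 200L; n_lines <- 20L
    n_large <- 2L; n_small <- 6L
    cfg <- experiment_config(architecture, model, direction,
                             n_generations = 2L, N = 40L, n_sires = 4L,
                             n_dams = 4L, offspring_per_mating = 10L,
                             burn_generations = 3L, n_replicates = 1L,
                             n_sites = n_sites, n_lines = n_lines,
                             n_qtn_large = n_large, n_qtn_small = n_small,
                             n_iter = 300L, burn_in = 100L, seed = seed)
  } else {
    n_sites <- 2000L; n_lines <- 205L
    n_large <- 103L; n_small <- 297L
    cfg <- experiment_config(architecture, model, direction,
                             n_generations = 7L, N = 250L, n_sires = 25L,
                             n_dams = 25L, offspring_per_mating = 10L,
                             burn_generations = 10L, n_replicates = 1L,
                             n_sites = n_sites, n_lines = n_lines,
                             n_qtn_large = n_large, n_qtn_small = n_small,
                             n_iter = 2000L, burn_in = 500L, seed = seed)
  }
  p <- draw_site_frequencies(n_sites, cfg$sfs_shape, seed = seeds[1])
  panel <- make_founder_panel(p, n_lines)
  eff <- sample_qtn_effects(n_large, n_small, cfg$exp_rate,
                            seed = seeds[2])
  qtn <- if (size == "tiny") {
    # too few loci to calibrate correlation targets: random placement
    set.seed(seeds[3])
    assign_qtn_sites(eff, panel_freqs(panel), target_corr = 0,
                     target_mean_p_plus = mean(pmin(panel_freqs(panel),
                                                    1 - panel_freqs(panel))))
  } else {
    assign_qtn_sites(eff, panel_freqs(panel), cfg$target_corr,
                     cfg$target_mean_p_plus, seed = seeds[3])
  }
  list(panel = panel, qtn = qtn,
       trait = trait_model(qtn, if (architecture == "additive")
         "additive" else "complementary", target_H2 = cfg$target_H2),
       config = cfg)
}

#' Write a run manifest
#'
#' Records the configuration snapshot, root and per-replicate seeds,
#' package version, timestamps and an inventory of output files with
#' MD5 checksums — enough to reproduce a run bit-identically.
#'
#' @param dir run directory containing the outputs.
#' @param config the `episel_config` used.
#' @param files character vector of output files (relative to `dir`).
#' @return the manifest path, invisibly.
#' @export
write_run_manifest <- function(dir, config, files = list.files(dir)) {
  files <- setdiff(files, "manifest.json")
  paths <- file.path(dir, files)
  manifest <- list(
    config = unclass(config),
    root_seed = config$seed,
    replicate_seeds = child_seeds(config$seed, config$n_replicates + 2L),
    package_version = as.character(utils::packageVersion("episel")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    files = data.frame(file = files,
                       md5 = unname(tools::md5sum(paths)),
                       stringsAsFactors = FALSE))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export per-generation metrics as TSV
#' @param result an `episel_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(result, path) {
  write.table(result$metrics, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Export a kernel matrix as square TSV with id header row/column
#' @param K square matrix.
#' @param path output file.
#' @param ids individual ids (default 1..n).
#' @return `path`, invisibly.
#' @export
write_kernel_tsv <- function(K, path, ids = seq_len(nrow(K))) {
  out <- cbind(id = ids, as.data.frame(K))
  names(out) <- c("id", ids)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a genetic map as 4-column TSV
#'
#' Columns: `chrom`, `bp`, `cM_female`, `cM_male`.
#'
#' @param sites site table (for writing).
#' @param path TSV file.
#' @return for `read_map_tsv`, a data frame; for `write_map_tsv`,
#'   `path` invisibly.
#' @export
write_map_tsv <- function(sites, path) {
  write.table(data.frame(chrom = sites$chrom, bp = sites$pos_bp,
                         cM_female = sites$cm_female,
                         cM_male = sites$cm_male),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_map_tsv
#' @export
read_map_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
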