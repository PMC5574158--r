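# Orchestration of the divergent selection experiment.

#' Configuration of one experimental cell
#'
#' Defaults mirror the reference design: base population of N = 500
#' formed by random mating from inbred founder lines, 10% selected per
#' sex (25 sires + 25 dams), monogamous matings of 20 offspring each,
#' seven discrete generations, ten replicates.
#'
#' @param architecture `"additive"` or `"complementary"`.
#' @param model evaluation model variant (see [model_spec()]).
#' @param direction `"up"` or `"down"`.
#' @param n_generations selected generations (default 7).
#' @param N population size per generation.
#' @param n_sires,n_dams parents selected per sex.
#' @param offspring_per_mating litter size (equal sex ratio).
#' @param burn_generations random-mating rounds used to build each base
#'   population from the founder lines (the first round crosses the
#'   lines themselves; 0 is treated as "direct line crosses").
#' @param n_replicates replicates per cell.
#' @param n_sites,n_lines,sfs_shape founder generator settings.
#' @param n_qtn_large,n_qtn_small,exp_rate QTN effect generator settings.
#' @param target_H2,target_corr,target_mean_p_plus trait calibration.
#' @param n_iter,burn_in MCMC settings passed to [model_spec()].
#' @param progeny_test_n individuals progeny-tested per generation for
#'   accuracy / additive-variance tracking (0 disables the tracking;
#'   each tested individual simulates `progeny_test_offspring`
#'   offspring, so this dominates run time when enabled).
#' @param progeny_test_offspring offspring per progeny test.
#' @param keep_populations keep first and last population of each
#'   replicate in the result (needed for LD analyses).
#' @param seed root seed; replicate seeds are derived from it.
#' @return list of class `episel_config`.
#' @export
experiment_config <- function(architecture = c("additive", "complementary"),
                              model = c("A-SEQ", "A-QTN", "E-SEQ", "E-QTN"),
                              direction = c("up", "down"),
                              n_generations = 7L, N = 500L,
                              n_sires = 25L, n_dams = 25L,
                              offspring_per_mating = 20L,
                              burn_generations = 10L, n_replicates = 10L,
                              n_sites = 5000L, n_lines = 205L,
                              sfs_shape = 0.2,
                              n_qtn_large = 103L, n_qtn_small = 297L,
                              exp_rate = 5,
                              target_H2 = 0.5, target_corr = -0.42,
                              target_mean_p_plus = 0.17,
                              n_iter = 10000L, burn_in = 2000L,
                              progeny_test_n = 0L,
                              progeny_test_offspring = 1000L,
                              keep_populations = TRUE, seed = 1L) {
  cfg <- list(architecture = match.arg(architecture),
              model = match.arg(model),
              direction = match.arg(direction),
              n_generations = check_count(n_generations, "n_generations"),
              N = check_count(N, "N"),
              n_sires = check_count(n_sires, "n_sires"),
              n_dams = check_count(n_dams, "n_dams"),
              offspring_per_mating = check_count(offspring_per_mating,
                                                 "offspring_per_mating"),
              burn_generations = check_count(burn_generations,
                                             "burn_generations", min = 0L),
              n_replicates = check_count(n_replicates, "n_replicates"),
              n_sites = check_count(n_sites, "n_sites"),
              n_lines = check_count(n_lines, "n_lines", min = 2L),
              sfs_shape = check_positive(sfs_shape, "sfs_shape"),
              n_qtn_large = check_count(n_qtn_large, "n_qtn_large", 0L),
              n_qtn_small = check_count(n_qtn_small, "n_qtn_small", 0L),
              exp_rate = check_positive(exp_rate, "exp_rate"),
              target_H2 = target_H2, target_corr = target_corr,
              target_mean_p_plus = target_mean_p_plus,
              n_iter = check_count(n_iter, "n_iter"),
              burn_in = check_count(burn_in, "burn_in", min = 0L),
              progeny_test_n = check_count(progeny_test_n,
                                           "progeny_test_n", min = 0L),
              progeny_test_offspring =
                check_count(progeny_test_offspring,
                            "progeny_test_offspring"),
              keep_populations = isTRUE(keep_populations),
              seed = check_count(seed, "seed", min = 0L))
  if (cfg$n_sires * cfg$offspring_per_mating != cfg$N)
    stop_invalid("n_sires * offspring_per_mating must equal N ",
                 "(monogamous pairing)")
  class(cfg) <- "episel_config"
  cfg
}

#' Build a base population from a founder panel
#'
#' Runs `max(burn_generations, 1)` rounds of random mating at size `N`
#' starting from the founder lines themselves (so the first round *is*
#' the line crosses), which decays the founder linkage disequilibrium
#' and creates heterozygous individuals from the homozygous lines.
#' Genotypic values are computed on the result; if `trait$sigma_e2` is
#' not yet set it is calibrated here to `trait$target_H2` and phenotypes
#' are drawn.
#'
#' @param panel `episel_panel`.
#' @param trait `episel_trait`.
#' @param N base population size.
#' @param burn_generations random-mating rounds (see above).
#' @param seed optional integer seed.
#' @return list with `pop` (generation relabelled 0), the calibrated
#'   `trait`, and `base_freqs` (allele-1 frequencies of the base
#'   population, the reference for inbreeding).
#' @export
build_base_population <- function(panel, trait, N = 500L,
                                  burn_generations = 10L, seed = NULL) {
  maybe_seed(seed)
  pop <- founder_population(panel)
  for (r in seq_len(max(burn_generations, 1L)))
    pop <- random_mating_generation(pop, N)
  pop$generation <- 0L
  pop$g <- genotypic_value(pop_dosages(pop), trait$qtn, trait$architecture)
  if (is.na(trait$sigma_e2))
    trait$sigma_e2 <- calibrate_environmental_variance(pop$g,
                                                       trait$target_H2)
  pop$y <- pop$g + rnorm(pop_size(pop), 0, sqrt(trait$sigma_e2))
  list(pop = pop, trait = trait, base_freqs = colMeans(pop_dosages(pop)) / 2)
}

#' Truncation selection within each sex
#'
#' Picks the top `n_sires` males and top `n_dams` females by the
#' criterion (descending for `"up"`, ascending for `"down"`); ties are
#' broken by id for determinism, with a warning when the criterion is
#' completely flat.
#'
#' @param pop candidate population.
#' @param criterion numeric vector, one value per individual.
#' @param n_sires,n_dams numbers to select.
#' @param direction `"up"` or `"down"`.
#' @return list with indices `sires` and `dams`.
#' @export
select_parents <- function(pop, criterion, n_sires = 25L, n_dams = 25L,
                           direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (length(criterion) != pop_size(pop))
    stop_invalid("criterion length must match population size")
  if (sd(criterion) == 0)
    warning("selection criterion is constant; selecting by id")
  crit <- if (direction == "up") -criterion else criterion
  ord <- order(crit, pop$ids)
  males <- ord[pop$sex[ord] == "M"]
  females <- ord[pop$sex[ord] == "F"]
  if (length(males) < n_sires || length(females) < n_dams)
    stop_invalid("not enough candidates of one sex")
  list(sires = males[seq_len(n_sires)], dams = females[seq_len(n_dams)])
}

#' Mate the selected parents
#'
#' Monogamous random pairing: a random permutation matches each sire to
#' exactly one dam, and every mating produces `offspring_per_mating`
#' offspring with an equal sex ratio.
#'
#' @param pop population holding the parents.
#' @param sires,dams index vectors of equal length.
#' @param offspring_per_mating litter size.
#' @param trait `episel_trait` (calibrated).
#' @return offspring `episel_pop`.
#' @export
mate_selected <- function(pop, sires, dams, offspring_per_mating = 20L,
                          trait = NULL) {
  if (length(sires) != length(dams))
    stop_invalid("sires and dams counts must match")
  dams <- dams[sample.int(length(dams))]
  n_off <- offspring_per_mating
  sex1 <- rep(c("M", "F"), length.out = n_off)
  if (n_off %% 2L == 0L) sex1 <- rep(c("M", "F"), each = n_off %/% 2L)
  sire_idx <- rep(sires, each = n_off)
  dam_idx <- rep(dams, each = n_off)
  sex <- rep(sex1, length(sires))
  Hoff <- make_offspring(pop, sire_idx, dam_idx, sex)
  pop_from_offspring(pop, Hoff, sex, trait, pop$generation + 1L)
}

#' Run a divergent-selection experiment cell
#'
#' For each replicate: a fresh base population is built from the shared
#' founder panel (same QTN effects, new burn-in seed), then for each of
#' `n_generations` cycles the cumulative data are evaluated with the
#' configured GBLUP variant ([predict_candidates()]), the top 10% per
#' sex are selected, and the next generation is produced.  Phenotypic
#' mean/SD, response in base-SD units, variance-component posterior
#' means, QTN allele frequencies and mean genomic inbreeding are
#' recorded per generation; accuracy and additive variance via progeny
#' testing are recorded when `progeny_test_n > 0`.
#'
#' @param config an [experiment_config()].
#' @param panel,qtn optionally pre-built founder panel and QTN set
#'   (built from `config` when omitted); supplying them lets several
#'   cells share identical founders and effects.
#' @return list of class `episel_result` with `metrics` (one row per
#'   replicate x generation), `qtn_freq` (increasing-allele frequencies,
#'   replicate x generation x locus), `config`, `qtn`, and per-replicate
#'   first/last populations when `keep_populations`.
#' @export
run_experiment <- function(config, panel = NULL, qtn = NULL) {
  seeds <- child_seeds(config$seed, config$n_replicates + 2L)
  if (is.null(panel)) {
    p <- draw_site_frequencies(config$n_sites, config$sfs_shape,
                               seed = seeds[1])
    panel <- make_founder_panel(p, config$n_lines)
  }
  if (is.null(qtn)) {
    eff <- sample_qtn_effects(config$n_qtn_large, config$n_qtn_small,
                              config$exp_rate, seed = seeds[2])
    qtn <- assign_qtn_sites(eff, panel_freqs(panel), config$target_corr,
                            config$target_mean_p_plus)
  }
  spec <- model_spec(config$model, n_iter = config$n_iter,
                     burn_in = config$burn_in)
  rows <- list(); freq_list <- list(); pops_kept <- list()
  for (rep_i in seq_len(config$n_replicates)) {
    trait <- trait_model(qtn, config$architecture,
                         target_H2 = config$target_H2)
    base <- build_base_population(panel, trait, config$N,
                                  config$burn_generations,
                                  seed = seeds[rep_i + 2L])
    trait <- base$trait
    pops <- list(base$pop)
    mean0 <- mean(base$pop$y); sd0 <- sd(base$pop$y)
    # inbreeding on autosomes only: the duplicated male X haplotype would
    # otherwise count as structural homozygosity
    aut <- which(panel$sites$chrom != "X")
    test_idx <- function(pop)
      seq_len(min(config$progeny_test_n, pop_size(pop)))
    rec <- function(pop) {
      va <- NA_real_
      if (config$progeny_test_n > 0L) {
        bv <- empirical_breeding_value(
          pop, trait, individuals = test_idx(pop),
          n_offspring = config$progeny_test_offspring)
        va <- var(bv$bv)
      }
      data.frame(replicate = rep_i, generation = pop$generation,
                 mean_phenotype = mean(pop$y), sd_phenotype = sd(pop$y),
                 response_sd = (mean(pop$y) - mean0) / sd0,
                 accuracy = NA_real_, va = va,
                 sigma2_a = NA_real_, sigma2_d = NA_real_,
                 sigma2_p = NA_real_, sigma2_e = NA_real_,
                 mean_F = mean(genomic_inbreeding(pop_dosages(pop, aut),
                                                  base$base_freqs[aut])$F_h))
    }
    inc_freq <- function(pop) {
      p1 <- colMeans(pop_dosages(pop, qtn$site_id)) / 2
      ifelse(qtn$increasing_allele == 1L, p1, 1 - p1)
    }
    reprows <- list(rec(base$pop))
    freq_list[[length(freq_list) + 1L]] <-
      data.frame(replicate = rep_i, generation = 0L,
                 locus = seq_len(nrow(qtn)), p_inc = inc_freq(base$pop))
    for (t in seq_len(config$n_generations)) {
      pred <- predict_candidates(pops, qtn, spec)
      cur <- pops[[length(pops)]]
      # evaluation metrics belong to the candidate generation t - 1
      reprows[[t]]$sigma2_a <- pred$fit$sigma2_a
      reprows[[t]]$sigma2_d <- pred$fit$sigma2_d
      reprows[[t]]$sigma2_p <- pred$fit$sigma2_p
      reprows[[t]]$sigma2_e <- pred$fit$sigma2_e
      if (config$progeny_test_n > 0L) {
        idx <- test_idx(cur)
        bv <- empirical_breeding_value(
          cur, trait, individuals = idx,
          n_offspring = config$progeny_test_offspring)
        reprows[[t]]$accuracy <- cor(bv$bv, pred$criterion[idx])
      }
      sel <- select_parents(cur, pred$criterion, config$n_sires,
                            config$n_dams, config$direction)
      nxt <- mate_selected(cur, sel$sires, sel$dams,
                           config$offspring_per_mating, trait)
      pops[[length(pops) + 1L]] <- nxt
      reprows[[t + 1L]] <- rec(nxt)
      freq_list[[length(freq_list) + 1L]] <-
        data.frame(replicate = rep_i, generation = t,
                   locus = seq_len(nrow(qtn)), p_inc = inc_freq(nxt))
    }
    rows <- c(rows, reprows)
    if (config$keep_populations)
      pops_kept[[rep_i]] <- list(first = pops[[1]],
                                 last = pops[[length(pops)]],
                                 trait = trait,
                                 base_freqs = base$base_freqs)
  }
  structure(list(metrics = do.call(rbind, rows),
                 qtn_freq = do.call(rbind, freq_list),
                 config = config, qtn = qtn,
                 populations = pops_kept),
            class = "episel_result")
}

#' @export
print.episel_result <- function(x, ...) {
  cfg <- x$config
  cat("<episel_result> ", cfg$architecture, " / ", cfg$model, " / ",
      cfg$direction, ": ", cfg$n_replicates, " replicate(s) x ",
      cfg$n_generations, " generations\n", sep = "")
  fin <- x$metrics[x$metrics$generation == cfg$n_generations, ]
  cat("  mean terminal response: ", signif(mean(fin$response_sd), 4),
      " base-SD units\n", sep = "")
  invisible(x)
}
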