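# The quantities reported per generation: progeny-test breeding values,
# additive variance, response, accuracy, substitution effects and
# 2pq*alpha^2 contributions, LD decay with a Hill-Weir fit, and
# excess-homozygosity inbreeding.

#' Progeny-test ("true") breeding values
#'
#' The breeding value of an individual is defined as twice the deviation
#' of the phenotypic mean of its offspring from the population
#' phenotypic mean under random mating.  It is estimated empirically:
#' each focal individual is mated to `n_offspring` randomly chosen
#' opposite-sex individuals of the same generation (one offspring per
#' drawn mate), offspring phenotypes receive fresh environmental
#' deviates with the calibrated variance, and the population mean is
#' taken over a fresh phenotype realisation of the generation so that
#' the focal individual's own environmental luck does not enter the
#' reference.
#'
#' Offspring genotypes are dropped only at the causal sites, which is
#' sufficient because only genotypic values are needed.
#'
#' @param pop an `episel_pop` with genotypic values.
#' @param trait calibrated `episel_trait`.
#' @param individuals indices of focal individuals (default: all).
#' @param n_offspring progeny-test offspring per individual.
#' @param seed optional integer seed.
#' @return data frame (`id`, `bv`, `n_test_offspring`, `se`).
#' @export
empirical_breeding_value <- function(pop, trait, individuals = NULL,
                                     n_offspring = 1000L, seed = NULL) {
  n_offspring <- check_count(n_offspring, "n_offspring")
  maybe_seed(seed)
  if (is.null(individuals)) individuals <- seq_len(pop_size(pop))
  if (is.na(trait$sigma_e2))
    stop_invalid("trait must be calibrated (sigma_e2) for progeny tests")
  males <- which(pop$sex == "M"); females <- which(pop$sex == "F")
  if (!length(males) || !length(females))
    stop_invalid("progeny test requires both sexes in the population")
  qtn <- trait$qtn
  cols <- sort(qtn$site_id)
  qtn_sub <- qtn; qtn_sub$site_id <- match(qtn$site_id, cols)
  Hq <- pop$H[, cols, drop = FALSE]
  blocks <- blocks_for(pop$sites, cols)
  sub_sites <- pop$sites[cols, , drop = FALSE]
  attr(sub_sites, "chromosomes") <- attr(pop$sites, "chromosomes")
  sigma_e <- sqrt(trait$sigma_e2)
  # reference mean over a fresh phenotypic realisation of the generation
  y_ref <- mean(pop$g + rnorm(pop_size(pop), 0, sigma_e))
  sex_off <- rep(c("M", "F"), length.out = n_offspring)
  res <- lapply(individuals, function(i) {
    if (pop$sex[i] == "M") {
      sire_idx <- rep(i, n_offspring)
      dam_idx <- females[sample.int(length(females), n_offspring,
                                    replace = TRUE)]
    } else {
      dam_idx <- rep(i, n_offspring)
      sire_idx <- males[sample.int(length(males), n_offspring,
                                   replace = TRUE)]
    }
    mat <- draw_gametes(Hq, dam_idx, rep(FALSE, n_offspring), blocks)
    pat <- draw_gametes(Hq, sire_idx, rep(TRUE, n_offspring), blocks)
    xc <- blocks$x_cols
    if (length(xc)) {
      sons <- which(sex_off == "M")
      if (length(sons)) pat[sons, xc] <- mat[sons, xc]
    }
    g_off <- genotypic_value(mat + pat, qtn_sub, trait$architecture)
    y_off <- g_off + rnorm(n_offspring, 0, sigma_e)
    c(bv = 2 * (mean(y_off) - y_ref), se = 2 * sd(y_off) / sqrt(n_offspring))
  })
  out <- do.call(rbind, res)
  data.frame(id = pop$ids[individuals], bv = out[, "bv"],
             n_test_offspring = n_offspring, se = out[, "se"])
}

#' Additive genetic variance from progeny-test breeding values
#'
#' The variance of empirical breeding values among the individuals of
#' the generation of interest (optionally a subsample, since each
#' breeding value costs `n_offspring` simulated offspring).
#'
#' @inheritParams empirical_breeding_value
#' @return numeric scalar.
#' @export
additive_variance <- function(pop, trait, individuals = NULL,
                              n_offspring = 1000L, seed = NULL) {
  var(empirical_breeding_value(pop, trait, individuals, n_offspring,
                               seed)$bv)
}

#' Response to selection in base-population SD units
#'
#' Per replicate, `(mean_t - mean_0) / SD_0`; summarised across
#' replicates by mean, median and quartiles.
#'
#' @param result an `episel_result`.
#' @return data frame with one row per generation.
#' @export
response_curve <- function(result) {
  mm <- result$metrics
  agg <- function(f) tapply(mm$response_sd,
                            mm$generation, f)
  data.frame(generation = sort(unique(mm$generation)),
             mean = as.numeric(agg(mean)),
             median = as.numeric(agg(median)),
             q25 = as.numeric(agg(function(x) quantile(x, 0.25))),
             q75 = as.numeric(agg(function(x) quantile(x, 0.75))))
}

#' Prediction accuracy
#'
#' Pearson correlation between true and predicted breeding values of a
#' generation's candidates.
#'
#' @param true_bv,predicted numeric vectors.
#' @return numeric scalar.
#' @export
prediction_accuracy <- function(true_bv, predicted) {
  if (length(true_bv) != length(predicted))
    stop_invalid("vectors must have equal length")
  cor(true_bv, predicted)
}

#' Change in trait-increasing allele frequency
#'
#' Per QTN, the frequency of the trait-increasing allele in `pop_t7`
#' minus that in `pop_t0`.
#'
#' @param pop_t0,pop_t7 populations at the first and last generation.
#' @param qtn `episel_qtn` set.
#' @return data frame (`locus`, `p0`, `p7`, `delta_p`).
#' @export
allele_frequency_change <- function(pop_t0, pop_t7, qtn) {
  pinc <- function(pop) {
    p1 <- colMeans(pop_dosages(pop, qtn$site_id)) / 2
    ifelse(qtn$increasing_allele == 1L, p1, 1 - p1)
  }
  p0 <- pinc(pop_t0); p7 <- pinc(pop_t7)
  data.frame(locus = seq_len(nrow(qtn)), p0 = p0, p7 = p7,
             delta_p = p7 - p0)
}

# expected two-locus pair value for each dominant-dosage at B, averaging
# over the partner's HWE genotype distribution
pair_value_profile <- function(z, q_partner) {
  p_any <- 1 - q_partner^2      # partner carries >= 1 dominant allele
  z * p_any * c(0, 1, 1)        # g_B = 0, 1, 2 dominant alleles
}

#' Allele substitution effect at a causal locus
#'
#' Under the additive architecture the substitution effect is the locus
#' additive value `a` itself.  Under complementary epistasis it is the
#' linear-regression coefficient of the expected pair value on the
#' dominant-allele dosage, computed by exact enumeration: the expected
#' value for each of the three genotypes at the locus is obtained by
#' averaging the 3x3 pair table over the partner's Hardy-Weinberg
#' genotype probabilities at the current frequencies, and the slope is
#' the frequency-weighted least-squares regression on dosage.
#'
#' @param qtn `episel_qtn` set.
#' @param freqs current allele-1 frequencies over panel sites.
#' @param architecture `"additive"` or `"complementary"`.
#' @return data frame (`locus`, `site_id`, `p_dom`, `alpha`,
#'   `contribution` = `2 p q alpha^2`), where `p_dom` is the
#'   dominant-allele frequency; loci fixed in `freqs` get contribution
#'   0.
#' @export
substitution_effect <- function(qtn, freqs,
                                architecture = c("complementary",
                                                 "additive")) {
  architecture <- match.arg(architecture)
  p1 <- freqs[qtn$site_id]
  p_dom <- ifelse(qtn$dominant_allele == 1L, p1, 1 - p1)
  q_rec <- 1 - p_dom
  if (architecture == "additive") {
    alpha <- qtn$a
  } else {
    partner <- integer(nrow(qtn))
    for (pid in unique(qtn$pair_id)) {
      ii <- which(qtn$pair_id == pid)
      partner[ii] <- rev(ii)
    }
    alpha <- vapply(seq_len(nrow(qtn)), function(i) {
      prof <- pair_value_profile(qtn$z[i], q_rec[partner[i]])
      wt <- c(q_rec[i]^2, 2 * p_dom[i] * q_rec[i], p_dom[i]^2)
      g <- 0:2
      if (sum(wt * (g - sum(wt * g))^2) == 0) return(0)
      sum(wt * (g - sum(wt * g)) * prof) / sum(wt * (g - sum(wt * g))^2)
    }, 0)
  }
  contribution <- 2 * p_dom * q_rec * alpha^2
  contribution[p_dom %in% c(0, 1)] <- 0
  data.frame(locus = seq_len(nrow(qtn)), site_id = qtn$site_id,
             p_dom = p_dom, alpha = alpha, contribution = contribution)
}

#' Expected per-locus contributions to additive variance
#'
#' `2 p q alpha^2` per causal locus (the expected contribution in the
#' absence of disequilibrium), sorted in decreasing order together with
#' the cumulative share, plus the fraction of loci needed to explain
#' 90% of the sum.
#'
#' @inheritParams substitution_effect
#' @param cum_target cumulative share defining the concentration
#'   statistic (default 0.9).
#' @return list with `records` (sorted data frame with `cum_share`) and
#'   `frac_loci_90` (fraction of loci explaining `cum_target` of the
#'   total).
#' @export
contribution_spectrum <- function(qtn, freqs,
                                  architecture = c("complementary",
                                                   "additive"),
                                  cum_target = 0.9) {
  rec <- substitution_effect(qtn, freqs, architecture)
  rec <- rec[order(rec$contribution, decreasing = TRUE), ]
  tot <- sum(rec$contribution)
  if (tot <= 0) stop_invalid("all contributions are zero")
  rec$cum_share <- cumsum(rec$contribution) / tot
  n_needed <- which(rec$cum_share >= cum_target)[1]
  list(records = rec, frac_loci_90 = n_needed / nrow(rec))
}

#' Pairwise linkage disequilibrium (r-squared) on genotypes
#'
#' The squared Pearson correlation of dosage vectors for pairs of loci
#' on the same chromosome within `max_dist_bp`.
#'
#' @param dosages `n x k` dosage matrix (columns follow `sites`).
#' @param sites site table aligned with the dosage columns.
#' @param max_dist_bp maximum pair distance (default `Inf`).
#' @param cols optional column subset (e.g. QTN sites).
#' @return data frame (`chrom`, `bp1`, `bp2`, `dist`, `r2`); pairs where
#'   either locus is monomorphic are dropped.
#' @export
ld_r2 <- function(dosages, sites, max_dist_bp = Inf, cols = NULL) {
  if (!is.null(cols)) {
    dosages <- dosages[, cols, drop = FALSE]
    sites <- sites[cols, , drop = FALSE]
  }
  keep <- apply(dosages, 2L, sd) > 0
  dosages <- dosages[, keep, drop = FALSE]
  sites <- sites[keep, , drop = FALSE]
  out <- list()
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    if (length(idx) < 2L) next
    cc <- cor(dosages[, idx, drop = FALSE])
    pr <- which(upper.tri(cc), arr.ind = TRUE)
    bp <- sites$pos_bp[idx]
    d <- abs(bp[pr[, 2L]] - bp[pr[, 1L]])
    sel <- d <= max_dist_bp
    out[[ch]] <- data.frame(chrom = ch, bp1 = bp[pr[sel, 1L]],
                            bp2 = bp[pr[sel, 2L]], dist = d[sel],
                            r2 = cc[pr[sel, , drop = FALSE]]^2)
  }
  if (!length(out)) stop_invalid("no eligible locus pair")
  do.call(rbind, out)
}

#' Hill-Weir expectation of r-squared
#'
#' The sampling expectation of `r^2` as a function of the population
#' recombination parameter `C` in a sample of `n` individuals
#' (Hill & Weir 1988, in the algebraic form popularised by
#' Remington et al. 2001):
#' `E[r2] = (10+C)/((2+C)(11+C)) *
#'    (1 + ((3+C)(12+12C+C^2))/(n(2+C)(11+C)))`.
#'
#' @param C population recombination parameter (>= 0).
#' @param n sample size.
#' @return expected r-squared.
#' @export
hill_weir_expectation <- function(C, n) {
  (10 + C) / ((2 + C) * (11 + C)) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit the Hill-Weir r-squared decay curve
#'
#' Nonlinear least squares of observed `(distance, r2)` pairs against
#' [hill_weir_expectation()] with `C = c_scale * distance`; `c_scale`
#' absorbs the population-scaled recombination rate per base pair
#' (recombination is assumed proportional to physical distance within a
#' chromosome).
#'
#' @param pairs data frame with columns `dist` (bp) and `r2` (e.g. from
#'   [ld_r2()]).
#' @param n_sample number of individuals behind the genotype-based r2.
#' @return list of class `episel_hillweir`: `C_per_bp`, `n_sample`,
#'   `residual_sse`, `flat` (TRUE when the data sit at the sampling
#'   asymptote and the scale is unidentifiable), and `curve`, a
#'   function of distance.
#' @export
fit_hill_weir <- function(pairs, n_sample) {
  if (length(unique(pairs$dist)) < 3L)
    stop_invalid("need at least 3 distinct distances")
  start <- 1 / max(1, median(pairs$dist))
  fit <- minpack.lm::nlsLM(
    r2 ~ hill_weir_expectation(c_scale * dist, n_sample),
    data = pairs, start = list(c_scale = start),
    lower = 0, control = minpack.lm::nls.lm.control(maxiter = 200))
  c_scale <- coef(fit)[["c_scale"]]
  sse <- sum(residuals(fit)^2)
  flat <- c_scale * max(pairs$dist) > 1e6
  structure(list(C_per_bp = c_scale, n_sample = n_sample,
                 residual_sse = sse, flat = flat,
                 curve = function(d)
                   hill_weir_expectation(c_scale * d, n_sample)),
            class = "episel_hillweir")
}

#' Genomic inbreeding from excess homozygosity
#'
#' `F_h = (O - E) / (k - E)` per individual, where `O` is the observed
#' number of homozygous sites, `k` the number of sites, and
#' `E = sum(1 - 2 p q)` the homozygous count expected under
#' Hardy-Weinberg at the base-population frequencies.
#'
#' @param dosages `n x k` dosage matrix.
#' @param base_freqs allele-1 frequencies in the base population.
#' @return data frame (`id`, `O`, `E`, `F_h`).
#' @export
genomic_inbreeding <- function(dosages, base_freqs) {
  if (ncol(dosages) != length(base_freqs))
    stop_invalid("dosage columns and base_freqs length differ")
  k <- ncol(dosages)
  O <- rowSums(dosages != 1L)
  E <- sum(1 - 2 * base_freqs * (1 - base_freqs))
  data.frame(id = seq_len(nrow(dosages)), O = O, E = E,
             F_h = (O - E) / (k - E))
}
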