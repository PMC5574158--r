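#' Sample QTN effect magnitudes
#'
#' Absolute effects come from a two-component mixture: `n_small` draws
#' from Exponential(`exp_rate`) emulating many undetected small effects,
#' plus `n_large` draws from a lognormal component emulating effects
#' estimated in an association study (which are the largest ones, hence
#' upwardly biased).  The lognormal median defaults to ten times the
#' exponential median: this makes the pooled absolute-effect histogram
#' clearly bimodal and reproduces the reported concentration of
#' additive-variance contributions (about 28% of loci explaining 90% of
#' the summed `2pq alpha^2` in the calibrated base population).  Signs
#' are sampled with equal probability; they are typically re-coupled to
#' allele frequencies later by [assign_qtn_sites()].
#'
#' @param n_large,n_small component sizes (defaults 103 and 297; their
#'   sum must be even so loci can be paired).
#' @param exp_rate rate of the exponential component.
#' @param large_meanlog,large_sdlog lognormal parameters of the large
#'   component; `large_meanlog` defaults to `log(10 * log(2) / exp_rate)`.
#' @param seed optional integer seed.
#' @return Data frame with columns `effect` (signed) and `source`
#'   (`"empirical_like"` or `"exponential"`).
#' @export
sample_qtn_effects <- function(n_large = 103, n_small = 297, exp_rate = 5,
                               large_meanlog = log(10 * log(2) / exp_rate),
                               large_sdlog = 0.5, seed = NULL) {
  n_large <- check_count(n_large, "n_large", min = 0L)
  n_small <- check_count(n_small, "n_small", min = 0L)
  exp_rate <- check_positive(exp_rate, "exp_rate")
  if ((n_large + n_small) %% 2L != 0L)
    stop_invalid("n_large + n_small must be even (loci are paired)")
  maybe_seed(seed)
  mag <- c(rlnorm(n_large, large_meanlog, large_sdlog),
           rexp(n_small, exp_rate))
  sgn <- sample(c(-1, 1), n_large + n_small, replace = TRUE)
  data.frame(effect = sgn * mag,
             source = rep(c("empirical_like", "exponential"),
                          c(n_large, n_small)),
             stringsAsFactors = FALSE)
}

#' Place QTN on panel sites and orient trait-increasing alleles
#'
#' Chooses `nrow(effects)` polymorphic sites and orients each locus so
#' that, across loci, (i) the mean frequency of the trait-increasing
#' allele matches `target_mean_p_plus` and (ii) the Pearson correlation
#' between absolute effect and increasing-allele frequency matches
#' `target_corr`.  The dominant allele at every locus is the major
#' allele (the minor allele plays the recessive role, mirroring panels
#' where the alternative allele is the rare, recessive and usually
#' trait-increasing one); orientation is therefore carried by the sign
#' of the locus effect: a negative sign means the recessive (minor)
#' allele increases the trait.
#'
#' The effect/frequency coupling uses Gaussian-copula rank matching
#' between absolute effects and increasing-allele frequencies, with the
#' copula parameter tuned by deterministic bisection until the achieved
#' Pearson correlation sits well inside the contract tolerance of
#' +/- 0.05 (widened to ~2/sqrt(n) for small sets, where correlation
#' noise dominates).  Loci are then grouped
#' into disjoint epistatic pairs at random *within* sign classes, so
#' that the pair value (the arithmetic mean of the two locus effects)
#' never cancels and every locus keeps a well-defined increasing allele.
#'
#' @param effects data frame from [sample_qtn_effects()].
#' @param freqs per-site frequencies of allele 1 (e.g. empirical panel
#'   frequencies from [panel_freqs()]).
#' @param target_corr target Pearson correlation between absolute effect
#'   and increasing-allele frequency, in `(-1, 0]`.
#' @param target_mean_p_plus target mean increasing-allele frequency, in
#'   `(0, 0.5]`.
#' @param sites optional site table used only to exclude sites; QTN are
#'   drawn from polymorphic sites of `freqs`.
#' @param seed optional integer seed.
#' @return An object of class `episel_qtn`: data frame with one row per
#'   locus (`site_id` = column index into the panel, `effect` signed as
#'   described above, `abs_effect`, `source`, `dominant_allele`,
#'   `increasing_allele`, `pair_id`, `z` the signed pair value, `a` the
#'   per-locus additive value, equal to `z`), with achieved calibration
#'   statistics in attributes `achieved_corr` and `achieved_mean_p_plus`.
#' @export
assign_qtn_sites <- function(effects, freqs, target_corr = -0.42,
                             target_mean_p_plus = 0.17, sites = NULL,
                             seed = NULL) {
  n <- nrow(effects)
  if (target_corr > 0 || target_corr <= -1)
    stop_invalid("target_corr must lie in (-1, 0]")
  if (target_mean_p_plus <= 0 || target_mean_p_plus > 0.5)
    stop_invalid("target_mean_p_plus must lie in (0, 0.5]")
  poly <- which(freqs > 0 & freqs < 1)
  if (length(poly) < n)
    stop_invalid("panel has only ", length(poly),
                 " polymorphic sites; need ", n)
  maybe_seed(seed)
  site <- sort(sample(poly, n))
  p1 <- freqs[site]
  f_min <- pmin(p1, 1 - p1)

  # orientation: increasing allele is the minor (recessive) one except at
  # k_pos loci flipped to the major allele so the mean hits the target
  m <- mean(f_min)
  if (m >= 0.5 - 1e-9)
    stop_invalid("cannot reach target mean: minor-allele mean is 0.5")
  k_pos <- round(n * (target_mean_p_plus - m) / (1 - 2 * m))
  k_pos <- min(max(k_pos, 0L), n)
  k_pos <- 2L * round(k_pos / 2)  # keep both sign classes pairable
  flip <- if (k_pos > 0) sample.int(n, k_pos) else integer(0)
  orient <- rep(-1, n); orient[flip] <- 1
  p_plus <- ifelse(orient > 0, 1 - f_min, f_min)
  if (abs(mean(p_plus) - target_mean_p_plus) > max(0.02, 1 / sqrt(n)))
    stop_invalid("infeasible target_mean_p_plus: best achievable ",
                 signif(mean(p_plus), 3))

  # Gaussian-copula rank matching of |effect| to p_plus
  abs_eff <- abs(effects$effect)
  u <- qnorm(rank(p_plus, ties.method = "first") / (n + 1))
  u <- (u - mean(u)) / sd(u)
  eps <- rnorm(n)
  sorted_eff <- sort(abs_eff, decreasing = TRUE)
  match_once <- function(rho_g) {
    w <- rho_g * u + sqrt(1 - rho_g^2) * eps
    out <- numeric(n)
    out[order(w, decreasing = TRUE)] <- sorted_eff
    out
  }
  # correlation tolerance widens for small QTN sets, where the sampling
  # noise of a correlation (~1/sqrt(n)) exceeds the contract window
  tol <- max(0.05, 2 / sqrt(n))
  achieved <- function(rho_g) cor(match_once(rho_g), p_plus)
  # achieved Pearson correlation decreases in the copula parameter
  # (up to rank-matching discreteness); bisect on it
  lo <- -0.999; hi <- 0.999   # slightly positive values can be needed
                              # to cancel copula noise near target 0
  best <- list(corr = achieved(target_corr), rho_g = target_corr)
  if (achieved(lo) > target_corr) {
    best <- list(corr = achieved(lo), rho_g = lo)
  } else {
    for (it in seq_len(40L)) {
      mid <- (lo + hi) / 2
      cc <- achieved(mid)
      if (abs(cc - target_corr) < abs(best$corr - target_corr))
        best <- list(corr = cc, rho_g = mid)
      if (abs(best$corr - target_corr) <= 0.4 * tol) break
      if (cc > target_corr) hi <- mid else lo <- mid
    }
  }
  if (abs(best$corr - target_corr) > tol)
    stop_invalid("infeasible target_corr: best achievable ",
                 signif(best$corr, 3))
  abs_assigned <- match_once(best$rho_g)

  # order of `effects` rows is matched to |effect| rank so `source` tags
  # follow their magnitudes
  ord_eff <- order(abs_eff, decreasing = TRUE)
  ord_ass <- order(abs_assigned, decreasing = TRUE)
  source_tag <- character(n)
  source_tag[ord_ass] <- effects$source[ord_eff]

  dominant <- ifelse(p1 >= 0.5, 1L, 0L)   # major allele is dominant
  increasing <- ifelse(orient > 0, dominant, 1L - dominant)
  signed <- orient * abs_assigned         # > 0: dominant allele increases

  # random pairing within sign classes
  pair_id <- integer(n)
  nxt <- 1L
  for (s in c(-1, 1)) {
    idx <- which(orient == s)
    if (!length(idx)) next
    idx <- sample(idx)
    ids <- rep(seq_len(length(idx) / 2L), each = 2L) + (nxt - 1L)
    pair_id[idx] <- ids
    nxt <- nxt + length(idx) / 2L
  }
  z <- ave(signed, pair_id)               # signed arithmetic mean per pair

  qtn <- data.frame(site_id = site, effect = signed,
                    abs_effect = abs_assigned, source = source_tag,
                    dominant_allele = dominant,
                    increasing_allele = increasing,
                    pair_id = pair_id, z = z, a = z,
                    stringsAsFactors = FALSE)
  structure(qtn, class = c("episel_qtn", "data.frame"),
            achieved_corr = best$corr,
            achieved_mean_p_plus = mean(p_plus))
}

#' Two-locus genotypic value under complementary epistasis
#'
#' Returns `z` when the genotype carries at least one dominant allele at
#' *both* loci of the pair, and 0 otherwise; this is the classical
#' complementary (9:7) epistasis table with complete dominance at each
#' locus.
#'
#' @param gB,gC dominant-allele counts (0, 1 or 2) at the two loci;
#'   vectors are recycled elementwise.
#' @param z pair genotypic value.
#' @return numeric vector of genotypic values.
#' @export
pair_value <- function(gB, gC, z) {
  if (any(!gB %in% 0:2) || any(!gC %in% 0:2))
    stop_invalid("genotype counts must be 0, 1 or 2")
  z * (gB >= 1) * (gC >= 1)
}

# dominant-allele dosage matrix from an allele-1 dosage matrix
dominant_dosage <- function(dosages, qtn) {
  D <- dosages[, qtn$site_id, drop = FALSE]
  flip <- which(qtn$dominant_allele == 0L)
  if (length(flip)) D[, flip] <- 2L - D[, flip]
  D
}

#' Genotypic values of individuals
#'
#' Under the complementary architecture, the genotypic value is the sum
#' over the epistatic pairs of [pair_value()]; under the additive
#' architecture it is the sum over loci of `a`, `0` or `-a` for the
#' dominant homozygote, the heterozygote and the recessive homozygote,
#' with `a` equal to the pair value `z` of the corresponding locus.
#'
#' @param dosages `n x k` matrix of allele-1 dosages over all panel
#'   sites (QTN columns are picked via `qtn$site_id`), or a population
#'   object.
#' @param qtn an `episel_qtn` set.
#' @param architecture `"complementary"` or `"additive"`.
#' @return numeric vector of genotypic values.
#' @export
genotypic_value <- function(dosages, qtn,
                            architecture = c("complementary", "additive")) {
  architecture <- match.arg(architecture)
  if (inherits(dosages, "episel_pop")) dosages <- pop_dosages(dosages)
  if (anyNA(dosages[, qtn$site_id, drop = FALSE]))
    stop_invalid("missing genotype at a QTN site")
  Dd <- dominant_dosage(dosages, qtn)
  if (architecture == "additive") {
    drop(( Dd - 1 ) %*% qtn$a)
  } else {
    pr <- split(seq_len(nrow(qtn)), qtn$pair_id)
    b <- vapply(pr, `[`, integer(1), 1L)
    c_ <- vapply(pr, `[`, integer(1), 2L)
    zp <- qtn$z[b]
    drop(((Dd[, b, drop = FALSE] >= 1) * (Dd[, c_, drop = FALSE] >= 1)) %*% zp)
  }
}

#' Calibrate environmental variance to a target broad-sense heritability
#'
#' `sigma_e2 = Var(g) (1 - H2) / H2`, so that phenotypes
#' `y = g + e`, `e ~ N(0, sigma_e2)` have broad-sense heritability `H2`
#' in expectation in the population whose genotypic values are supplied.
#'
#' @param g genotypic values of the (base) population.
#' @param target_H2 target broad-sense heritability in `(0, 1)`.
#' @return the environmental variance `sigma_e2`.
#' @export
calibrate_environmental_variance <- function(g, target_H2 = 0.5) {
  target_H2 <- check_prob(target_H2, "target_H2", open_lo = TRUE,
                          open_hi = TRUE)
  vg <- var(g)
  if (!is.finite(vg) || vg <= 0)
    stop_invalid("zero genetic variance: cannot calibrate")
  vg * (1 - target_H2) / target_H2
}

#' Bundle a QTN set, architecture and environmental variance
#'
#' @param qtn an `episel_qtn` set.
#' @param architecture `"complementary"` or `"additive"`.
#' @param sigma_e2 environmental variance; `NA` until calibrated.
#' @param target_H2 broad-sense heritability the calibration aims for.
#' @return An object of class `episel_trait`.
#' @export
trait_model <- function(qtn, architecture = c("complementary", "additive"),
                        sigma_e2 = NA_real_, target_H2 = 0.5) {
  architecture <- match.arg(architecture)
  if (!is.na(sigma_e2) && sigma_e2 < 0)
    stop_invalid("sigma_e2 must be >= 0")
  structure(list(qtn = qtn, architecture = architecture,
                 sigma_e2 = sigma_e2, target_H2 = target_H2),
            class = "episel_trait")
}

#' @export
print.episel_trait <- function(x, ...) {
  cat("<episel_trait> ", x$architecture, " architecture, ",
      nrow(x$qtn), " QTN in ", max(x$qtn$pair_id), " pairs, sigma_e2 = ",
      signif(x$sigma_e2, 4), "\n", sep = "")
  invisible(x)
}
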