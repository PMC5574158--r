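# Populations and meiosis.
#
# A population stores all haplotypes in one (2N x k) integer matrix with
# two consecutive rows per individual (maternal, paternal).  Males carry
# a single X haplotype; it is stored duplicated in both rows so that the
# dosage (row sum) automatically counts the male X as two copies, the
# coding used for the genomic relationship matrices.

new_population <- function(H, sex, generation, sites, g = NULL, y = NULL,
                           ids = NULL) {
  n <- nrow(H) / 2L
  structure(list(generation = generation,
                 ids = if (is.null(ids)) seq_len(n) else ids,
                 sex = sex, H = H, sites = sites,
                 g = if (is.null(g)) rep(NA_real_, n) else g,
                 y = if (is.null(y)) rep(NA_real_, n) else y),
            class = "episel_pop")
}

#' Number of individuals in a population
#' @param pop an `episel_pop`.
#' @return integer count.
#' @export
pop_size <- function(pop) nrow(pop$H) / 2L

#' Allele-1 dosage matrix of a population
#'
#' Row sums of the two stored haplotypes per individual.  Because the
#' male X haplotype is stored duplicated, male X dosages are 0 or 2.
#'
#' @param pop an `episel_pop`.
#' @param cols optional column (site) subset.
#' @return `n x k` integer matrix.
#' @export
pop_dosages <- function(pop, cols = NULL) {
  H <- pop$H
  if (!is.null(cols)) H <- H[, cols, drop = FALSE]
  n <- nrow(H) / 2L
  H[seq(1L, 2L * n, 2L), , drop = FALSE] +
    H[seq(2L, 2L * n, 2L), , drop = FALSE]
}

#' @export
print.episel_pop <- function(x, ...) {
  cat("<episel_pop> generation ", x$generation, ": ", pop_size(x),
      " individuals (", sum(x$sex == "M"), " M / ", sum(x$sex == "F"),
      " F), ", ncol(x$H), " sites\n", sep = "")
  invisible(x)
}

#' Turn a founder panel into a generation-0 population
#'
#' Lines become individuals; sexes are assigned alternately so both
#' sexes are always represented.  Inbred lines are homozygous, so a male
#' line's duplicated X rows already represent its single X haplotype.
#'
#' @param panel an `episel_panel`.
#' @return an `episel_pop` at generation 0... labelled `-1` so that the
#'   first round of random mating (the line crosses) produces
#'   generation 0.
#' @export
founder_population <- function(panel) {
  n <- length(panel$line_ids)
  sex <- rep(c("M", "F"), length.out = n)
  H <- panel$H
  # enforce a single X haplotype for male founders (no-op for inbred lines)
  xc <- which(panel$sites$chrom == "X")
  if (length(xc)) {
    mrow <- 2L * which(sex == "M")
    H[mrow, xc] <- H[mrow - 1L, xc]
  }
  new_population(H, sex, generation = -1L, sites = panel$sites)
}

# low-level meiosis over possibly subset site columns.
# H: haplotype matrix; parent: 1-based individual indices (one per
# gamete); male: logical per gamete; blocks: from chrom_blocks() on the
# site table matching H's columns.
draw_gametes <- function(H, parent, male, blocks) {
  gametes_cpp(H, as.integer(parent) - 1L, as.logical(male),
              as.numeric(attr(blocks, "cm")),
              as.integer(blocks$first) - 1L, as.integer(blocks$last) - 1L,
              as.numeric(blocks$cm_lo), as.numeric(blocks$cm_hi))
}

blocks_for <- function(sites, cols = NULL) {
  if (is.null(cols)) {
    b <- chrom_blocks(sites)
    attr(b, "cm") <- sites$cm_female
    return(b)
  }
  sub <- sites[cols, , drop = FALSE]
  full <- chrom_blocks(sites)
  labs <- unique(sub$chrom)
  first <- match(labs, sub$chrom)
  last <- nrow(sub) + 1L - match(labs, rev(sub$chrom))
  sel <- match(labs, full$chrom)
  b <- list(chrom = labs, first = first, last = last,
            cm_lo = full$cm_lo[sel], cm_hi = full$cm_hi[sel],
            x_cols = if ("X" %in% labs) which(sub$chrom == "X") else integer(0))
  attr(b, "cm") <- sub$cm_female
  b
}

#' Sample one or more gametes from a parent
#'
#' Crossover counts are Poisson with mean equal to the parent's map
#' length in Morgans (the female map; the male map has length zero so
#' males always transmit intact haplotypes), crossover positions are
#' uniform on the centimorgan scale, and the gamete alternates between
#' the two parental haplotypes at crossovers, starting from a random
#' one.
#'
#' @param pop an `episel_pop`.
#' @param individual 1-based index of the parent.
#' @param n number of gametes.
#' @return `n x k` matrix of gametes.
#' @export
sample_gamete <- function(pop, individual, n = 1L) {
  male <- pop$sex[individual] == "M"
  draw_gametes(pop$H, rep(individual, n), rep(male, n),
               blocks_for(pop$sites))
}

# Assemble offspring haplotype matrix from per-offspring sire/dam
# indices and sexes.  X transmission: daughters get the sire's X intact
# (automatic: male X rows are duplicates, so his "gamete" X equals his
# single X); sons get only the dam's recombined X, stored duplicated.
make_offspring <- function(pop, sire_idx, dam_idx, sex, trait = NULL,
                           cols = NULL, sites = NULL) {
  if (is.null(sites)) sites <- pop$sites
  H <- if (is.null(cols)) pop$H else pop$H[, cols, drop = FALSE]
  blocks <- blocks_for(pop$sites, cols)
  n <- length(sire_idx)
  mat <- draw_gametes(H, dam_idx, rep(FALSE, n), blocks)
  pat <- draw_gametes(H, sire_idx, rep(TRUE, n), blocks)
  xc <- blocks$x_cols
  if (length(xc)) {
    sons <- which(sex == "M")
    if (length(sons)) pat[sons, xc] <- mat[sons, xc]
  }
  Hoff <- matrix(0L, nrow = 2L * n, ncol = ncol(H))
  Hoff[seq(1L, 2L * n, 2L), ] <- mat
  Hoff[seq(2L, 2L * n, 2L), ] <- pat
  Hoff
}

pop_from_offspring <- function(pop, Hoff, sex, trait, generation) {
  n <- length(sex)
  g <- y <- rep(NA_real_, n)
  if (!is.null(trait)) {
    dos <- Hoff[seq(1L, 2L * n, 2L), , drop = FALSE] +
      Hoff[seq(2L, 2L * n, 2L), , drop = FALSE]
    g <- genotypic_value(dos, trait$qtn, trait$architecture)
    if (!is.na(trait$sigma_e2))
      y <- g + rnorm(n, 0, sqrt(trait$sigma_e2))
  }
  new_population(Hoff, sex, generation, pop$sites, g = g, y = y)
}

#' Mate one sire with one dam
#'
#' Produces `n_offspring` offspring with an exactly equal sex ratio when
#' `n_offspring` is even.  Daughters receive the sire's X intact plus a
#' recombined maternal X; sons receive only a recombined maternal X.
#'
#' @param pop population holding both parents.
#' @param sire,dam 1-based indices; the sire must be male and the dam
#'   female.
#' @param n_offspring number of offspring.
#' @param trait optional `episel_trait`; when supplied, genotypic values
#'   (and phenotypes, if `sigma_e2` is calibrated) are computed.
#' @return an `episel_pop` of the offspring (generation + 1).
#' @export
mate <- function(pop, sire, dam, n_offspring = 20L, trait = NULL) {
  if (pop$sex[sire] != "M" || pop$sex[dam] != "F")
    stop_invalid("mate() needs a male sire and a female dam")
  n <- check_count(n_offspring, "n_offspring")
  sex <- rep(c("M", "F"), length.out = n)
  if (n %% 2L == 0L) sex <- rep(c("M", "F"), each = n %/% 2L)
  Hoff <- make_offspring(pop, rep(sire, n), rep(dam, n), sex)
  pop_from_offspring(pop, Hoff, sex, trait, pop$generation + 1L)
}

#' One generation of random mating
#'
#' Each of the `N` offspring draws a sire and a dam uniformly (with
#' replacement) from the males and females of `pop`; offspring sexes
#' alternate so the sex ratio is as even as possible.  Allele
#' frequencies are conserved in expectation.
#'
#' @param pop parent population (must contain both sexes).
#' @param N number of offspring.
#' @param trait optional `episel_trait` (see [mate()]).
#' @return offspring `episel_pop`.
#' @export
random_mating_generation <- function(pop, N, trait = NULL) {
  N <- check_count(N, "N")
  males <- which(pop$sex == "M"); females <- which(pop$sex == "F")
  if (!length(males) || !length(females))
    stop_invalid("random mating requires both sexes")
  sire_idx <- males[sample.int(length(males), N, replace = TRUE)]
  dam_idx <- females[sample.int(length(females), N, replace = TRUE)]
  sex <- rep(c("M", "F"), length.out = N)
  Hoff <- make_offspring(pop, sire_idx, dam_idx, sex)
  pop_from_offspring(pop, Hoff, sex, trait, pop$generation + 1L)
}
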