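#' Default chromosome layout
#'
#' Three chromosomes emulating the Drosophila melanogaster karyotype used
#' in population-genetic work (the tiny heterochromatic chromosome 4 is
#' ignored): X, 2 and 3, with physical and female-map lengths close to
#' the published genome.  The male map length is zero on every
#' chromosome because male Drosophila do not recombine.
#'
#' @return A data frame with columns `chrom`, `length_bp` and
#'   `length_cm` (female map).
#' @export
fly_chromosomes <- function() {
  data.frame(chrom = c("X", "2", "3"),
             length_bp = c(22e6, 48e6, 52e6),
             length_cm = c(70, 107, 110),
             stringsAsFactors = FALSE)
}

#' Draw per-site allele frequencies from a symmetric Beta
#'
#' Frequencies of the allele coded 1 are drawn i.i.d. from
#' Beta(`sfs_shape`, `sfs_shape`).  With `sfs_shape < 1` the resulting
#' site frequency spectrum is U-shaped, i.e. most sites are close to
#' fixation for one allele, as observed for sequence variants in inbred
#' line panels.  Draws outside `[min_p, 1 - min_p]` are redrawn so that
#' every site has a realistic chance of being polymorphic once a finite
#' line panel is sampled.
#'
#' @param n_sites number of sites.
#' @param sfs_shape positive shape parameter of the symmetric Beta.
#' @param seed optional integer seed.
#' @param min_p lower truncation for the frequency; default `1/410`
#'   corresponds to a singleton in a 205-line homozygous panel.
#' @return Numeric vector of frequencies in `(0, 1)`.
#' @export
draw_site_frequencies <- function(n_sites, sfs_shape, seed = NULL,
                                  min_p = 1 / 410) {
  n_sites <- check_count(n_sites, "n_sites")
  sfs_shape <- check_positive(sfs_shape, "sfs_shape")
  maybe_seed(seed)
  p <- rbeta(n_sites, sfs_shape, sfs_shape)
  bad <- which(p < min_p | p > 1 - min_p)
  while (length(bad)) {
    p[bad] <- rbeta(length(bad), sfs_shape, sfs_shape)
    bad <- bad[p[bad] < min_p | p[bad] > 1 - min_p]
  }
  p
}

#' Build a site table over the default (or supplied) chromosomes
#'
#' Sites are allocated to chromosomes proportionally to physical length
#' and given strictly increasing 1-based bp positions; map positions are
#' then filled in by [make_genetic_map()].
#'
#' @param n_sites total number of sites.
#' @param chromosomes data frame as returned by [fly_chromosomes()].
#' @param seed optional integer seed.
#' @return A data frame (`site_id`, `chrom`, `pos_bp`, `cm_female`,
#'   `cm_male`, `ref_allele`, `alt_allele`) with the chromosome layout
#'   attached as attribute `"chromosomes"`.
#' @export
make_site_table <- function(n_sites, chromosomes = fly_chromosomes(),
                            seed = NULL) {
  n_sites <- check_count(n_sites, "n_sites")
  maybe_seed(seed)
  share <- chromosomes$length_bp / sum(chromosomes$length_bp)
  n_per <- floor(n_sites * share)
  rest <- n_sites - sum(n_per)
  if (rest > 0) n_per[seq_len(rest)] <- n_per[seq_len(rest)] + 1L
  pieces <- lapply(seq_len(nrow(chromosomes)), function(i) {
    n <- n_per[i]
    if (n == 0L) return(NULL)
    pos <- sort(sample.int(chromosomes$length_bp[i], n))
    data.frame(chrom = chromosomes$chrom[i], pos_bp = pos,
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, pieces)
  sites$site_id <- seq_len(nrow(sites))
  sites$ref_allele <- "A"
  sites$alt_allele <- "T"
  sites <- sites[, c("site_id", "chrom", "pos_bp", "ref_allele", "alt_allele")]
  attr(sites, "chromosomes") <- chromosomes
  make_genetic_map(sites, chromosomes)
}

#' Assign genetic-map positions to a site table
#'
#' The female map position is obtained by linear interpolation of
#' cumulative map length against physical position (or through an
#' optional per-chromosome breakpoint table when a non-uniform
#' recombination landscape is wanted).  The male map is zero at every
#' site: male Drosophila do not recombine.
#'
#' @param sites site table with `chrom` and `pos_bp`.
#' @param chromosomes chromosome layout (`chrom`, `length_bp`,
#'   `length_cm`).
#' @param breakpoints optional data frame (`chrom`, `bp`, `cm`) of map
#'   anchor points; positions between anchors are interpolated linearly,
#'   positions outside are clamped.
#' @return `sites` with `cm_female` and `cm_male` columns filled in.
#' @export
make_genetic_map <- function(sites, chromosomes = fly_chromosomes(),
                             breakpoints = NULL) {
  if (any(chromosomes$length_bp <= 0) || any(chromosomes$length_cm < 0))
    stop_invalid("chromosome lengths must be positive")
  unknown <- setdiff(unique(sites$chrom), chromosomes$chrom)
  if (length(unknown))
    stop_invalid("unknown chromosome label: ", paste(unknown, collapse = ", "))
  cmf <- numeric(nrow(sites))
  for (i in seq_len(nrow(chromosomes))) {
    idx <- which(sites$chrom == chromosomes$chrom[i])
    if (!length(idx)) next
    bp <- sites$pos_bp[idx]
    if (is.unsorted(bp)) stop_invalid("positions must be non-decreasing ",
                                      "within a chromosome")
    if (!is.null(breakpoints)) {
      bk <- breakpoints[breakpoints$chrom == chromosomes$chrom[i], ]
      if (nrow(bk) >= 2) {
        cmf[idx] <- stats::approx(bk$bp, bk$cm, xout = bp, rule = 2)$y
        next
      }
    }
    cmf[idx] <- bp / chromosomes$length_bp[i] * chromosomes$length_cm[i]
  }
  sites$cm_female <- cmf
  sites$cm_male <- 0
  attr(sites, "chromosomes") <- chromosomes
  sites[, c("site_id", "chrom", "pos_bp", "cm_female", "cm_male",
            "ref_allele", "alt_allele")]
}

# Per-chromosome column blocks plus the cM range used for crossover
# placement (the full female map length, not just the observed sites).
chrom_blocks <- function(sites) {
  chromosomes <- attr(sites, "chromosomes")
  labs <- unique(sites$chrom)
  first <- match(labs, sites$chrom)
  last <- nrow(sites) + 1L - match(labs, rev(sites$chrom))
  cm_hi <- if (!is.null(chromosomes))
    chromosomes$length_cm[match(labs, chromosomes$chrom)]
  else vapply(labs, function(l) max(sites$cm_female[sites$chrom == l]), 0)
  list(chrom = labs, first = first, last = last,
       cm_lo = rep(0, length(labs)), cm_hi = cm_hi,
       x_cols = if ("X" %in% labs) which(sites$chrom == "X") else integer(0))
}

#' Sample a founder haplotype panel
#'
#' Each founder line draws its allele at each site independently given
#' the site frequency; for fully inbred lines a single Bernoulli draw is
#' copied to both haplotypes, so every line is homozygous at every site.
#' Sites are mutually independent given frequencies, which makes
#' long-range linkage disequilibrium in the panel near zero in
#' expectation (`E[r^2] ~ 1/n_lines`).  Columns monomorphic in the
#' sampled panel are redrawn so that every retained site is polymorphic.
#'
#' @param freqs frequency of the allele coded 1 at each site.
#' @param n_lines number of founder lines (>= 2).
#' @param inbred if `TRUE` (default) lines are fully homozygous.
#' @param seed optional integer seed.
#' @param sites optional pre-built site table; by default a table with
#'   `length(freqs)` sites over [fly_chromosomes()] is generated.
#' @return An object of class `episel_panel`: list with `sites`, the
#'   `(2 n_lines) x k` 0/1 haplotype matrix `H` (two consecutive rows
#'   per line), `line_ids`, and the generating `freqs`.
#' @export
make_founder_panel <- function(freqs, n_lines, inbred = TRUE, seed = NULL,
                               sites = NULL) {
  n_lines <- check_count(n_lines, "n_lines", min = 2L)
  if (any(!is.finite(freqs)) || any(freqs < 0) || any(freqs > 1))
    stop_invalid("freqs must lie in [0, 1]")
  maybe_seed(seed)
  k <- length(freqs)
  if (is.null(sites)) sites <- make_site_table(k)
  if (nrow(sites) != k) stop_invalid("sites and freqs length mismatch")
  draw_lines <- function(cols) {
    p <- freqs[cols]
    matrix(rbinom(n_lines * length(cols), 1L, rep(p, each = n_lines)),
           nrow = n_lines)
  }
  A <- draw_lines(seq_len(k))
  if (!inbred) B <- draw_lines(seq_len(k))
  # condition on panel polymorphism (skip sites fixed by construction)
  can_vary <- freqs > 0 & freqs < 1
  for (it in seq_len(1000L)) {
    cs <- colSums(A) + if (inbred) colSums(A) else colSums(B)
    tot <- if (inbred) 2L * n_lines else 2L * n_lines
    mono <- which(can_vary & (cs == 0L | cs == tot))
    if (!length(mono)) break
    A[, mono] <- draw_lines(mono)
    if (!inbred) B[, mono] <- draw_lines(mono)
  }
  H <- matrix(0L, nrow = 2L * n_lines, ncol = k)
  H[seq(1L, 2L * n_lines, by = 2L), ] <- A
  H[seq(2L, 2L * n_lines, by = 2L), ] <- if (inbred) A else B
  structure(list(sites = sites, H = H,
                 line_ids = paste0("line_", seq_len(n_lines)),
                 freqs = freqs),
            class = "episel_panel")
}

#' @export
print.episel_panel <- function(x, ...) {
  cat("<episel_panel> ", length(x$line_ids), " lines x ", nrow(x$sites),
      " sites on ", length(unique(x$sites$chrom)), " chromosomes\n", sep = "")
  invisible(x)
}

#' Empirical allele-1 frequencies of a panel or haplotype matrix
#' @param x an `episel_panel` or a haplotype matrix.
#' @return numeric vector of per-site frequencies.
#' @export
panel_freqs <- function(x) {
  H <- if (inherits(x, "episel_panel")) x$H else x
  colMeans(H)
}

#' Load phased founder haplotypes from a VCF file
#'
#' Reads phased, biallelic SNP records; indels and multi-allelic records
#' are skipped (counts reported via `message`).  Sites are joined to the
#' supplied site/map table by chromosome and position.  Unphased
#' genotypes are an error; missing genotypes either drop the site or
#' raise an error depending on `strict`.
#'
#' @param path VCF file.
#' @param map_source site table carrying `chrom`, `pos_bp` and the map
#'   columns (see [make_genetic_map()]).
#' @param strict if `TRUE`, any missing genotype is an error; otherwise
#'   sites with missing calls are dropped with a message.
#' @return An `episel_panel`.
#' @export
load_haplotypes_vcf <- function(path, map_source, strict = FALSE) {
  if (!file.exists(path)) stop_invalid("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (!is.null(fix) && is.null(dim(fix))) fix <- t(as.matrix(fix))
  if (is.null(fix) || nrow(fix) == 0L) stop_invalid("no records in VCF")
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt, fixed = TRUE)
  n_skipped <- sum(!snp)
  if (n_skipped) message(n_skipped, " non-biallelic-SNP record(s) skipped")
  if (!any(snp)) stop_invalid("zero usable sites in VCF")
  gt <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  miss <- is.na(gt) | gt %in% c(".", "./.", ".|.")
  if (any(miss)) {
    if (strict) stop_invalid("missing genotypes present and strict = TRUE")
    drop <- rowSums(miss) > 0
    message(sum(drop), " site(s) with missing genotypes dropped")
    gt <- gt[!drop, , drop = FALSE]; fix <- fix[!drop, , drop = FALSE]
    if (nrow(gt) == 0L) stop_invalid("zero usable sites in VCF")
  }
  if (any(grepl("/", gt, fixed = TRUE)))
    stop_invalid("unphased genotypes in VCF; phased GT (|) required")
  key <- paste(fix[, "CHROM"], fix[, "POS"])
  mkey <- paste(map_source$chrom, map_source$pos_bp)
  hit <- match(key, mkey)
  if (all(is.na(hit))) stop_invalid("no VCF site matches the map source")
  keep <- !is.na(hit)
  gt <- gt[keep, , drop = FALSE]
  sites <- map_source[hit[keep], , drop = FALSE]
  sites$ref_allele <- fix[keep, "REF"]; sites$alt_allele <- fix[keep, "ALT"]
  attr(sites, "chromosomes") <- attr(map_source, "chromosomes")
  n_lines <- ncol(gt)
  H <- matrix(0L, nrow = 2L * n_lines, ncol = nrow(gt))
  a1 <- substr(gt, 1L, 1L); a2 <- substr(gt, 3L, 3L)
  H[seq(1L, 2L * n_lines, 2L), ] <- t(matrix(as.integer(a1), nrow(gt)))
  H[seq(2L, 2L * n_lines, 2L), ] <- t(matrix(as.integer(a2), nrow(gt)))
  structure(list(sites = sites, H = H, line_ids = colnames(gt),
                 freqs = colMeans(H)),
            class = "episel_panel")
}
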