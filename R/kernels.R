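# Genomic relationship matrices (VanRaden additive G, Vitezica-style
# dominance D, Hadamard epistatic G*G).

check_poly_freqs <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop_invalid("monomorphic site in frequency reference: every site ",
                 "entering a kernel must have 0 < p < 1 (exclude fixed ",
                 "sites upstream)")
  p
}

#' Additive genomic relationship matrix
#'
#' `G = M M' / sum(2 p q)` where each dosage column is centered by
#' `2 p_j` (entries `-2p`, `1-2p`, `2-2p` for dosages 0, 1, 2) and
#' `p_j` is the frequency of the allele counted by the dosage in the
#' genotyped individuals entering the kernel.
#'
#' @param dosages `n x k` matrix of allele-1 dosages (0/1/2).
#' @param freqs per-site allele-1 frequencies, all in `(0, 1)`.
#' @return `n x n` symmetric matrix.
#' @export
additive_grm <- function(dosages, freqs) {
  if (ncol(dosages) != length(freqs))
    stop_invalid("dosage columns and freqs length differ")
  p <- check_poly_freqs(freqs)
  W <- sweep(dosages, 2L, 2 * p)
  G <- tcrossprod(W) / sum(2 * p * (1 - p))
  (G + t(G)) / 2
}

#' Dominance genomic relationship matrix
#'
#' `D = M_d M_d' / sum(4 p^2 q^2)` with dominance codes `-2q^2`,
#' `2pq` and `-2p^2` for dosages 2, 1 and 0, where `p` is the frequency
#' of the counted allele.  This orientation (the classical orthogonal
#' parameterisation) makes the dominance codes orthogonal to the
#' centered additive codes under Hardy-Weinberg proportions:
#' `E[(g - 2p) m_d(g)] = 4p^2q^2 (p + (1-2p) - q) = 0`.
#'
#' @inheritParams additive_grm
#' @return `n x n` symmetric matrix.
#' @export
dominance_grm <- function(dosages, freqs) {
  if (ncol(dosages) != length(freqs))
    stop_invalid("dosage columns and freqs length differ")
  p <- check_poly_freqs(freqs)
  q <- 1 - p
  Md <- sweep((dosages == 1L), 2L, 2 * p * q, "*") +
    sweep((dosages == 2L), 2L, -2 * q^2, "*") +
    sweep((dosages == 0L), 2L, -2 * p^2, "*")
  D <- tcrossprod(Md) / sum(4 * p^2 * q^2)
  (D + t(D)) / 2
}

#' Hadamard (additive-by-additive) epistatic kernel
#'
#' Elementwise square of `G`, used as the covariance of epistatic
#' deviations `h ~ N(0, (G * G) sigma_p^2)`.
#'
#' @param G square symmetric matrix.
#' @return `G * G` elementwise.
#' @export
hadamard_kernel <- function(G) {
  if (!is.matrix(G) || nrow(G) != ncol(G))
    stop_invalid("G must be a square matrix")
  G * G
}

#' Select marker columns for kernel construction
#'
#' `"all_sites"` keeps every column polymorphic in `freqs`;
#' `"qtn_only"` restricts to the causal sites.  Columns monomorphic in
#' the frequency reference are dropped with a message (a QTN can drift
#' to fixation during selection).
#'
#' @param dosages `n x k` dosage matrix over all panel sites.
#' @param qtn an `episel_qtn` set (used for `"qtn_only"`).
#' @param mode `"all_sites"` or `"qtn_only"`.
#' @param freqs per-site frequencies aligned with `dosages` columns; by
#'   default recomputed from `dosages`.
#' @return list with elements `dosages` (subset matrix), `freqs` and
#'   `cols` (the retained column indices).
#' @export
marker_subset <- function(dosages, qtn = NULL,
                          mode = c("all_sites", "qtn_only"),
                          freqs = colMeans(dosages) / 2) {
  mode <- match.arg(mode)
  cols <- if (mode == "qtn_only") {
    if (is.null(qtn)) stop_invalid("qtn_only mode needs a qtn set")
    qtn$site_id
  } else seq_len(ncol(dosages))
  keep <- freqs[cols] > 0 & freqs[cols] < 1
  if (!all(keep))
    message(sum(!keep), " monomorphic site(s) dropped from the ",
            mode, " marker set")
  cols <- cols[keep]
  if (!length(cols)) stop_invalid("empty marker selection")
  list(dosages = dosages[, cols, drop = FALSE], freqs = freqs[cols],
       cols = cols)
}

#' Build the kernel set required by an evaluation model
#'
#' @param dosages `n x k` dosage matrix over all panel sites.
#' @param qtn `episel_qtn` set.
#' @param variant one of `"A-SEQ"`, `"A-QTN"`, `"E-SEQ"`, `"E-QTN"`.
#' @param freqs frequency reference (default: recomputed from the
#'   individuals entering the kernel, i.e. `dosages`).
#' @return list of class `episel_kernels` with `G`, and for E variants
#'   `D` and `GxG`, plus `freqs_used`, `marker_set` and `cols`.
#' @export
kernel_set <- function(dosages, qtn, variant = "A-SEQ",
                       freqs = colMeans(dosages) / 2) {
  variant <- match.arg(variant, c("A-SEQ", "A-QTN", "E-SEQ", "E-QTN"))
  mode <- if (grepl("QTN", variant)) "qtn_only" else "all_sites"
  ms <- marker_subset(dosages, qtn, mode, freqs)
  G <- additive_grm(ms$dosages, ms$freqs)
  out <- list(G = G, freqs_used = ms$freqs, marker_set = mode,
              cols = ms$cols)
  if (grepl("^E", variant)) {
    out$D <- dominance_grm(ms$dosages, ms$freqs)
    out$GxG <- hadamard_kernel(G)
  }
  class(out) <- "episel_kernels"
  out
}
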