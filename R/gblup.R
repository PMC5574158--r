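# Bayesian GBLUP: y = mu + a (+ d + h) + e with kernel-structured random
# effects, Gibbs-sampled on eigendecomposed kernels.
#
# Each random effect u ~ N(0, K sigma2) is reparameterised through the
# eigendecomposition K = U diag(lambda) U' as u = U b with independent
# prior components b_i ~ N(0, lambda_i sigma2).  Because U'U = I the
# full conditional of b is diagonal, so one Gibbs update costs O(m) for
# a single-kernel model; this is the decomposition strategy with good
# convergence properties commonly used for RKHS/GBLUP samplers.

#' Specification of a GBLUP evaluation model
#'
#' @param variant `"A-SEQ"`, `"A-QTN"` (additive kernel from all or
#'   causal sites) or `"E-SEQ"`, `"E-QTN"` (adds dominance and Hadamard
#'   epistatic kernels).
#' @param n_iter total MCMC iterations (default 10000).
#' @param burn_in burn-in iterations discarded from posterior summaries
#'   (default 2000).
#' @param prior_df degrees of freedom of every scaled-inverse-chi-square
#'   variance prior (default 5, rather uninformative).
#' @param prior_R2 prior proportion of phenotypic variance attributed to
#'   the genetic terms jointly; split equally among them, the remainder
#'   going to the residual (default 0.5).
#' @param seed optional integer seed for the chain.
#' @return list of class `episel_model_spec`.
#' @export
model_spec <- function(variant = c("A-SEQ", "A-QTN", "E-SEQ", "E-QTN"),
                       n_iter = 10000L, burn_in = 2000L, prior_df = 5,
                       prior_R2 = 0.5, seed = NULL) {
  variant <- match.arg(variant)
  n_iter <- check_count(n_iter, "n_iter")
  burn_in <- check_count(burn_in, "burn_in", min = 0L)
  if (burn_in >= n_iter) stop_invalid("burn_in must be < n_iter")
  prior_df <- check_positive(prior_df, "prior_df")
  prior_R2 <- check_prob(prior_R2, "prior_R2", open_lo = TRUE,
                         open_hi = TRUE)
  structure(list(variant = variant, n_iter = n_iter, burn_in = burn_in,
                 prior_df = prior_df, prior_R2 = prior_R2, seed = seed),
            class = "episel_model_spec")
}

#' Eigendecompose a (ridge-stabilised) kernel matrix
#'
#' Adds `ridge` to the diagonal, symmetrises, and truncates eigenvalues
#' below `tol` times the largest (their count is reported in the
#' result).
#'
#' @param K symmetric PSD matrix.
#' @param tol relative truncation threshold.
#' @param ridge diagonal stabiliser added before decomposition.
#' @return list of class `episel_eigen` with `vectors` (`n x m`),
#'   `values` (length `m`) and `n_dropped`.
#' @export
eigendecompose <- function(K, tol = 1e-10, ridge = 1e-8) {
  if (any(!is.finite(K))) stop_invalid("non-finite entries in kernel")
  K <- (K + t(K)) / 2
  diag(K) <- diag(K) + ridge
  e <- eigen(K, symmetric = TRUE)
  keep <- e$values > tol * max(e$values)
  structure(list(vectors = e$vectors[, keep, drop = FALSE],
                 values = e$values[keep], n_dropped = sum(!keep)),
            class = "episel_eigen")
}

#' Eigen factor of the additive GRM straight from dosages
#'
#' For additive-only models the eigenvectors/values of
#' `G = W W' / sum(2pq)` are obtained from the thin SVD of the centered,
#' scaled dosage matrix `W / sqrt(sum(2pq))` without ever forming the
#' `n x n` kernel; identical to `eigendecompose(additive_grm(...))` up
#' to the ridge, but much cheaper when markers are fewer than
#' individuals.
#'
#' @param dosages `n x k` dosage matrix (polymorphic columns).
#' @param freqs matching allele-1 frequencies.
#' @param tol relative eigenvalue truncation threshold.
#' @return an `episel_eigen`.
#' @export
grm_eigen <- function(dosages, freqs, tol = 1e-10) {
  p <- check_poly_freqs(freqs)
  W <- sweep(dosages, 2L, 2 * p) / sqrt(sum(2 * p * (1 - p)))
  sv <- svd(W, nv = 0)
  lambda <- sv$d^2
  keep <- lambda > tol * max(lambda)
  structure(list(vectors = sv$u[, keep, drop = FALSE],
                 values = lambda[keep], n_dropped = sum(!keep)),
            class = "episel_eigen")
}

#' BGLR-style default prior scale for a variance component
#'
#' `S = Var(y) * R2_share * (df + 2) / mean(diag(K))`, so that the prior
#' mode of the variance, `S / (df + 2)`, equals the share of phenotypic
#' variance assigned to the term divided by the average kernel diagonal.
#'
#' @param var_y phenotypic variance.
#' @param mean_diag mean diagonal of the kernel (1 for the residual).
#' @param df prior degrees of freedom.
#' @param R2_share share of phenotypic variance assigned to the term.
#' @return the scale parameter `S`.
#' @export
default_prior_scale <- function(var_y, mean_diag = 1, df = 5,
                                R2_share = 0.5) {
  if (!is.finite(var_y) || var_y <= 0)
    stop_invalid("phenotypic variance must be positive")
  var_y * R2_share * (df + 2) / mean_diag
}

as_eigen_terms <- function(kernels, spec) {
  if (inherits(kernels, "episel_eigen")) return(list(a = kernels))
  if (is.list(kernels) && all(vapply(kernels, inherits, TRUE,
                                     "episel_eigen")))
    return(kernels)
  if (inherits(kernels, "episel_kernels") ||
      (is.list(kernels) && !is.null(kernels$G))) {
    terms <- list(a = eigendecompose(kernels$G))
    if (grepl("^E", spec$variant)) {
      if (is.null(kernels$D) || is.null(kernels$GxG))
        stop_invalid("E variants require D and GxG kernels")
      terms$d <- eigendecompose(kernels$D)
      terms$p <- eigendecompose(kernels$GxG)
    }
    return(terms)
  }
  if (is.matrix(kernels)) return(list(a = eigendecompose(kernels)))
  stop_invalid("unrecognised kernel input")
}

# effective sample size from the autocorrelation function (initial
# positive sequence); logged as a diagnostic only.
ess <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1]
  pos <- which(rho <= 0)
  if (length(pos)) rho <- rho[seq_len(pos[1] - 1L)]
  max(1, n / (1 + 2 * sum(rho)))
}

#' Fit a GBLUP model by Gibbs sampling
#'
#' Samples, in turn, the eigencoefficients of each kernel term (their
#' full conditional is diagonal normal), the intercept (flat prior),
#' and all variance components from scaled-inverse-chi-square full
#' conditionals with BGLR-style default hyperparameters
#' ([default_prior_scale()]).  Posterior summaries are post-burn-in
#' means without thinning.
#'
#' @param y phenotypes.
#' @param kernels an `episel_kernels` set, a single kernel matrix, an
#'   `episel_eigen`, or a named list of `episel_eigen` terms (names
#'   among `a`, `d`, `p`).
#' @param spec an [model_spec()].
#' @param fixed_variances optional named list (`sigma2_a`, `sigma2_d`,
#'   `sigma2_p`, `sigma2_e`); fixed components are not sampled (used to
#'   validate the sampler against the closed-form BLUP solution).
#' @return list of class `episel_fit`: posterior-mean genetic values
#'   `a_hat` (and `d_hat`, `h_hat` for E variants), posterior means of
#'   the variance components, `intercept`, per-component effective
#'   sample sizes `ess`, and the variance-component chains.
#' @export
gibbs_fit <- function(y, kernels, spec, fixed_variances = NULL) {
  n <- length(y)
  if (any(!is.finite(y))) stop_invalid("non-finite phenotypes")
  terms <- as_eigen_terms(kernels, spec)
  if (any(vapply(terms, function(t) nrow(t$vectors), 1L) != n))
    stop_invalid("phenotype length does not match kernel dimension")
  maybe_seed(spec$seed)
  nt <- length(terms)
  df <- spec$prior_df
  var_y <- var(y)
  share <- spec$prior_R2 / nt
  S_term <- vapply(terms, function(t)
    default_prior_scale(var_y, sum(t$values) / n, df, share), 0)
  S_e <- var_y * (1 - spec$prior_R2) * (df + 2)

  U <- lapply(terms, `[[`, "vectors")
  lam <- lapply(terms, `[[`, "values")
  m <- vapply(lam, length, 1L)
  yt <- lapply(U, function(u) drop(crossprod(u, y)))
  s1 <- lapply(U, function(u) drop(crossprod(u, rep(1, n))))
  sum_y <- sum(y); ssy <- sum(y^2)

  fixed <- function(nm) !is.null(fixed_variances[[nm]])
  vname <- c(a = "sigma2_a", d = "sigma2_d", p = "sigma2_p")[names(terms)]
  s2 <- vapply(seq_len(nt), function(j)
    if (fixed(vname[j])) fixed_variances[[vname[j]]] else var_y * share, 0)
  s2e <- if (fixed("sigma2_e")) fixed_variances$sigma2_e
         else var_y * (1 - spec$prior_R2)
  mu <- mean(y)
  b <- lapply(m, numeric)
  v <- lapply(seq_len(nt), function(j) numeric(n))  # U_j b_j, multi-term

  keep <- spec$n_iter - spec$burn_in
  bsum <- lapply(m, numeric)
  musum <- 0
  chain <- matrix(NA_real_, keep, nt + 1L,
                  dimnames = list(NULL, c(vname, "sigma2_e")))
  single <- nt == 1L

  for (it in seq_len(spec$n_iter)) {
    if (single) {
      prec <- 1 / s2e + 1 / (lam[[1]] * s2[1])
      bmean <- (yt[[1]] - mu * s1[[1]]) / s2e / prec
      b[[1]] <- bmean + rnorm(m[1]) / sqrt(prec)
      mu <- rnorm(1, (sum_y - sum(s1[[1]] * b[[1]])) / n, sqrt(s2e / n))
      cross <- sum((yt[[1]] - mu * s1[[1]]) * b[[1]])
      sse <- ssy - 2 * mu * sum_y + n * mu^2 - 2 * cross + sum(b[[1]]^2)
    } else {
      r <- y - mu - Reduce(`+`, v)
      for (j in seq_len(nt)) {
        rj <- r + v[[j]]
        rt <- drop(crossprod(U[[j]], rj))
        prec <- 1 / s2e + 1 / (lam[[j]] * s2[j])
        b[[j]] <- rt / s2e / prec + rnorm(m[j]) / sqrt(prec)
        v[[j]] <- drop(U[[j]] %*% b[[j]])
        r <- rj - v[[j]]
      }
      tot <- r + mu
      mu <- rnorm(1, mean(tot), sqrt(s2e / n))
      r <- tot - mu
      sse <- sum(r^2)
    }
    for (j in seq_len(nt)) if (!fixed(vname[j]))
      s2[j] <- (sum(b[[j]]^2 / lam[[j]]) + S_term[j]) /
        rchisq(1, df + m[j])
    if (!fixed("sigma2_e"))
      s2e <- (sse + S_e) / rchisq(1, df + n)
    if (any(!is.finite(c(s2, s2e, mu))))
      stop("Gibbs sampler diverged (non-finite draw) at iteration ", it,
           "; variances: ", paste(signif(c(s2, s2e), 3), collapse = ", "))
    if (it > spec$burn_in) {
      kk <- it - spec$burn_in
      for (j in seq_len(nt)) bsum[[j]] <- bsum[[j]] + b[[j]]
      musum <- musum + mu
      chain[kk, ] <- c(s2, s2e)
    }
  }

  post_u <- lapply(seq_len(nt), function(j)
    drop(U[[j]] %*% (bsum[[j]] / keep)))
  names(post_u) <- names(terms)
  vc <- colMeans(chain)
  out <- list(a_hat = post_u$a, d_hat = post_u$d, h_hat = post_u$p,
              intercept = musum / keep,
              sigma2_a = vc[["sigma2_a"]],
              sigma2_d = if ("sigma2_d" %in% colnames(chain))
                vc[["sigma2_d"]] else NA_real_,
              sigma2_p = if ("sigma2_p" %in% colnames(chain))
                vc[["sigma2_p"]] else NA_real_,
              sigma2_e = vc[["sigma2_e"]],
              ess = apply(chain, 2L, ess),
              chain = chain, spec = spec)
  class(out) <- "episel_fit"
  out
}

#' @export
print.episel_fit <- function(x, ...) {
  cat("<episel_fit> ", x$spec$variant, ", ", length(x$a_hat),
      " individuals\n  posterior means: sigma2_a = ", signif(x$sigma2_a, 4),
      if (!is.na(x$sigma2_d)) paste0(", sigma2_d = ", signif(x$sigma2_d, 4)),
      if (!is.na(x$sigma2_p)) paste0(", sigma2_p = ", signif(x$sigma2_p, 4)),
      ", sigma2_e = ", signif(x$sigma2_e, 4), "\n", sep = "")
  invisible(x)
}

#' Genomic prediction for the current selection candidates
#'
#' Pools phenotypes and genotypes of every generation up to and
#' including the present one, rebuilds the kernels from the cumulative
#' data (frequencies recomputed from all individuals entering the
#' kernel unless `freeze_freqs` supplies a fixed reference), fits the
#' model with [gibbs_fit()], and returns the posterior-mean additive
#' values of the last generation as the selection criterion.
#'
#' @param pops list of `episel_pop` (history, oldest first; the last
#'   element holds the candidates). All phenotypes must be present.
#' @param qtn `episel_qtn` set.
#' @param spec [model_spec()].
#' @param freeze_freqs optional frequency vector (length = panel sites)
#'   used instead of cumulative-data frequencies.
#' @return list with `criterion` (additive posterior means of the
#'   candidates), `fit` (the full `episel_fit`) and `n_train`.
#' @export
predict_candidates <- function(pops, qtn, spec, freeze_freqs = NULL) {
  if (!length(pops)) stop_invalid("empty history")
  if (inherits(pops, "episel_pop")) pops <- list(pops)
  dos <- do.call(rbind, lapply(pops, pop_dosages))
  y <- unlist(lapply(pops, `[[`, "y"), use.names = FALSE)
  if (anyNA(y)) stop_invalid("all training individuals need phenotypes")
  freqs <- if (is.null(freeze_freqs)) colMeans(dos) / 2 else freeze_freqs
  mode <- if (grepl("QTN", spec$variant)) "qtn_only" else "all_sites"
  ms <- marker_subset(dos, qtn, mode, freqs)
  kern <- if (grepl("^A", spec$variant)) {
    grm_eigen(ms$dosages, ms$freqs)
  } else {
    G <- additive_grm(ms$dosages, ms$freqs)
    list(G = G, D = dominance_grm(ms$dosages, ms$freqs),
         GxG = hadamard_kernel(G))
  }
  fit <- gibbs_fit(y, kern, spec)
  n_last <- pop_size(pops[[length(pops)]])
  idx <- seq(length(y) - n_last + 1L, length(y))
  list(criterion = fit$a_hat[idx], fit = fit, n_train = length(y))
}
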