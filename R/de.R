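# Covariate-adjusted differential expression on log-CPM with empirical-Bayes
# variance moderation. Per gene, an ordinary least-squares fit of
#   expression ~ group + covariates
# gives the group log2 fold change and residual variance s^2 on df degrees of
# freedom; the s^2 are shrunk towards a pooled prior by fitting a scaled F
# distribution by method of moments (prior df d0 and prior variance s0^2),
# giving posterior variances
#   s~^2 = (d0 * s0^2 + df * s^2) / (d0 + df)
# and moderated t statistics on df + d0 degrees of freedom.

#' Inverse of the trigamma function
#'
#' Newton iteration on `trigamma(x) = y`; used by the method-of-moments
#' F-distribution fit for the variance prior.
#'
#' @param y Positive numeric vector.
#' @return `x` with `trigamma(x) = y`.
#' @keywords internal
trigamma_inverse <- function(y) {
  out <- y
  hi <- y > 1e7
  lo <- y < 1e-6
  out[hi] <- 1 / sqrt(y[hi])
  out[lo] <- 1 / y[lo]
  mid <- which(!hi & !lo)
  if (length(mid)) {
    x <- 0.5 + 1 / y[mid]
    for (iter in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2)
      x <- x + dif
      if (max(-dif / x) < 1e-8) break
    }
    out[mid] <- x
  }
  out
}

#' Empirical-Bayes shrinkage of residual variances
#'
#' Fits `s^2 ~ s0^2 * F(df, d0)` by method of moments on `log(s^2)` and
#' returns posterior (shrunk) variances.
#'
#' @param s2 Residual variances (one per gene).
#' @param df Residual degrees of freedom (scalar).
#' @return List with `var_prior`, `df_prior`, `var_post`.
#' @export
squeeze_variances <- function(s2, df) {
  if (df <= 0) stop("residual degrees of freedom must be positive")
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) stop("need at least two genes with positive residual variance")
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    var_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    # no excess dispersion beyond chi-square sampling noise: the prior is
    # effectively infinite and all variances shrink to the pooled mean
    df_prior <- Inf
    var_prior <- mean(s2[ok])
  }
  var_post <- if (is.finite(df_prior)) {
    (df_prior * var_prior + df * pmax(s2, 0)) / (df_prior + df)
  } else {
    rep(var_prior, length(s2))
  }
  list(var_prior = var_prior, df_prior = df_prior, var_post = var_post)
}

#' Differential expression between a case group and controls
#'
#' @param logcpm An `ExpressionMatrix` with units `"logcpm"`.
#' @param meta Sample metadata (see [validate_metadata()]); only samples in
#'   the two groups are modeled.
#' @param case_group Group label of the cases (e.g. `"LN"`).
#' @param control_group Group label of the controls (default `"HC"`).
#' @param covariates Metadata columns adjusted for (default age, sex,
#'   sequencing batch and RNA integrity number).
#' @param shrink Apply empirical-Bayes variance moderation (default TRUE).
#'   With `shrink = FALSE` the statistics reduce to classical equal-variance
#'   t-tests when no covariates are used.
#' @param alpha FDR cutoff defining the `significant` flag (default 0.05).
#' @return Data frame with columns `gene_id`, `log2fc` (case - control),
#'   `t_stat`, `p`, `fdr`, `significant`.
#' @export
fit_dge <- function(logcpm, meta, case_group, control_group = "HC",
                    covariates = c("age", "sex", "batch", "rin"),
                    shrink = TRUE, alpha = 0.05) {
  stopifnot(inherits(logcpm, "ExpressionMatrix"))
  if (logcpm$units != "logcpm") stop("fit_dge expects log-CPM input")
  meta <- as.data.frame(meta)
  meta <- meta[meta$sample_id %in% sample_ids(logcpm) &
    meta$group %in% c(case_group, control_group), , drop = FALSE]
  if (sum(meta$group == case_group) < 3 || sum(meta$group == control_group) < 3) {
    stop("need at least 3 samples per group")
  }
  for (cv in covariates) {
    if (!cv %in% names(meta)) stop("covariate '", cv, "' missing from metadata")
    if (anyNA(meta[[cv]])) stop("covariate '", cv, "' has missing values")
  }
  constant <- vapply(covariates, function(cv) length(unique(meta[[cv]])) < 2, logical(1))
  if (any(constant)) {
    message(
      "dropping covariate(s) constant in the modeled samples: ",
      paste(covariates[constant], collapse = ", ")
    )
    covariates <- covariates[!constant]
  }
  meta$group <- factor(meta$group, levels = c(control_group, case_group))
  fm <- stats::as.formula(paste(
    "~ group", if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else ""
  ))
  design <- stats::model.matrix(fm, data = meta)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    aliased <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("design matrix is rank deficient; aliased columns: ", paste(aliased, collapse = ", "))
  }
  y <- logcpm$values[, meta$sample_id, drop = FALSE]
  xtxi <- chol2inv(chol(crossprod(design)))
  beta <- y %*% design %*% xtxi # genes x coefficients
  resid <- y - beta %*% t(design)
  df_resid <- nrow(design) - ncol(design)
  s2 <- rowSums(resid^2) / df_resid
  coef_idx <- 2L # the group coefficient sits right after the intercept
  se_unscaled <- sqrt(xtxi[coef_idx, coef_idx])
  lfc <- beta[, coef_idx]

  if (shrink) {
    sq <- squeeze_variances(s2, df_resid)
    var_use <- sq$var_post
    df_total <- df_resid + sq$df_prior
  } else {
    var_use <- s2
    df_total <- df_resid
  }
  se <- se_unscaled * sqrt(var_use)
  t_stat <- ifelse(se > 0, lfc / se, ifelse(abs(lfc) > 0, sign(lfc) * Inf, 0))
  p <- 2 * stats::pt(-abs(t_stat), df = df_total)
  # genes (numerically) constant across all samples carry no evidence
  eps <- 1e-12 * stats::median(abs(y))^2
  degenerate <- s2 <= eps & abs(lfc) <= sqrt(eps)
  p[degenerate] <- 1
  t_stat[degenerate] <- 0
  lfc[degenerate] <- 0
  fdr <- bh_adjust(p)
  data.frame(
    gene_id = gene_ids(logcpm),
    log2fc = unname(lfc),
    t_stat = unname(t_stat),
    p = unname(p),
    fdr = fdr,
    significant = fdr < alpha,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control; thin wrapper kept as the pipeline's single point of
#' multiplicity adjustment.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Fold-change gate on significant genes
#'
#' @param results Output of [fit_dge()].
#' @param min_abs_log2fc Strict threshold on `|log2fc|` (default 0.58, i.e.
#'   fold change < 0.66 or > 1.5).
#' @return Character vector of gene ids passing both gates.
#' @export
gate_fc <- function(results, min_abs_log2fc = 0.58) {
  results$gene_id[results$significant & abs(results$log2fc) > min_abs_log2fc]
}

#' Partition two DEG sets into shared and disease-specific signatures
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @return List with `shared`, `a_specific`, `b_specific`.
#' @export
venn_partition <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  list(
    shared = intersect(set_a, set_b),
    a_specific = setdiff(set_a, set_b),
    b_specific = setdiff(set_b, set_a)
  )
}
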