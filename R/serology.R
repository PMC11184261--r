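# Rank-based association of module dysregulation with serology: Spearman
# correlation for continuous analytes, Mann-Whitney U for binary serology
# groups. P-values are reported unadjusted for multiplicity, mirroring the
# study's stated choice, and flagged as such.

# all permutations of 1..n (n <= 8 in practice), one per row
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    for (j in seq_len(nrow(sub))) {
      out[row, ] <- c(i, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Rho is computed on average ranks. For `n <= exact_max` the two-sided
#' p-value comes from full enumeration of the `n!` permutations of one
#' variable (valid under ties); otherwise from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Paired numeric vectors, `n >= 3`.
#' @param exact_max Largest n for exact enumeration (default 8).
#' @return List with `rho`, `p`, `n`, `method`.
#' @export
spearman_test <- function(x, y, exact_max = 8) {
  if (length(x) != length(y)) stop("x and y must be paired")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_max) {
    perms <- permutations_of(n)
    rho_perm <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    method <- "t_approx"
  }
  list(rho = rho, p = p, n = n, method = method)
}

mw_u_stat <- function(ranks_a, n_a, n_b) {
  sum(ranks_a) - n_a * (n_a + 1) / 2
}

#' Mann-Whitney U test
#'
#' Two-sided. For groups of at most `exact_max` each, the p-value comes from
#' exact enumeration of all assignments of the pooled values to groups
#' (tie-safe; symmetric rejection region around `n_a * n_b / 2`). Otherwise
#' the tie-corrected normal approximation is used (no continuity correction).
#'
#' @param a,b Numeric vectors (both nonempty).
#' @param exact_max Largest per-group size for exact enumeration (default 8).
#' @return List with `U` (for the first group), `p`, `method`.
#' @export
mann_whitney_test <- function(a, b, exact_max = 8) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  n_a <- length(a)
  n_b <- length(b)
  if (n_a == 0 || n_b == 0) stop("both groups must be nonempty")
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- mw_u_stat(r[seq_len(n_a)], n_a, n_b)
  mu <- n_a * n_b / 2
  if (n_a <= exact_max && n_b <= exact_max) {
    combos <- utils::combn(n_a + n_b, n_a)
    u_all <- apply(combos, 2, function(idx) mw_u_stat(r[idx], n_a, n_b))
    p <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else {
    N <- n_a + n_b
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n_a * n_b / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal_approx"
  }
  list(U = U, p = min(p, 1), method = method)
}

#' Associate module scores with a serology panel
#'
#' One row per module x analyte. Continuous mode uses Spearman correlation of
#' the module z-score with the analyte value; binary mode compares module
#' z-scores between positive and negative patients with the Mann-Whitney U
#' test (negative serology is the reference group, so `direction = "up"`
#' means higher dysregulation in the positive group). Significance is flagged
#' at p < 0.05 with NO multiplicity adjustment, and labeled accordingly.
#'
#' @param scores A `ModuleScoreMatrix` (or plain modules x patients matrix).
#' @param serology Long-format data frame with columns `sample_id`,
#'   `analyte`, `value` and (for binary mode) logical `positive`.
#' @param mode `"continuous"` or `"binary"`.
#' @param min_n Minimum paired patients for a row to be reported (default 3).
#' @return Data frame with columns `module_name`, `analyte`, `statistic`,
#'   `p`, `n`, `direction`, `significant_unadjusted`.
#' @export
associate_serology <- function(scores, serology, mode = c("continuous", "binary"),
                               min_n = 3) {
  mode <- match.arg(mode)
  z <- if (inherits(scores, "ModuleScoreMatrix")) scores$z else scores
  if (!length(intersect(colnames(z), serology$sample_id))) {
    stop("no overlapping patients between scores and serology")
  }
  rows <- list()
  for (an in unique(serology$analyte)) {
    sub <- serology[serology$analyte == an, , drop = FALSE]
    sub <- sub[sub$sample_id %in% colnames(z), , drop = FALSE]
    for (m in rownames(z)) {
      zi <- z[m, sub$sample_id]
      if (mode == "continuous") {
        if (length(zi) < min_n) next
        ts <- spearman_test(zi, sub$value)
        rows[[length(rows) + 1L]] <- data.frame(
          module_name = m, analyte = an, statistic = ts$rho, p = ts$p,
          n = ts$n, direction = ifelse(ts$rho >= 0, "positive", "negative"),
          stringsAsFactors = FALSE
        )
      } else {
        pos <- zi[which(sub$positive)]
        neg <- zi[which(!sub$positive)]
        if (length(pos) + length(neg) < min_n || !length(pos) || !length(neg)) next
        mw <- mann_whitney_test(pos, neg)
        rows[[length(rows) + 1L]] <- data.frame(
          module_name = m, analyte = an, statistic = mw$U, p = mw$p,
          n = length(pos) + length(neg),
          direction = ifelse(mean(pos) >= mean(neg), "up", "down"),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) {
    stop("no module/analyte pair had at least ", min_n, " paired patients")
  }
  out <- do.call(rbind, rows)
  out$significant_unadjusted <- out$p < 0.05
  rownames(out) <- NULL
  out
}
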