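# Group inference on suppression scores, implemented from the sums-of-
# squares and step-up formulas (base fitting functions are used only as
# independent oracles in the test suite).

# suppression_table -> n x a x b array (participant x condition x region)
scores_array <- function(scores) {
  parts <- unique(scores$participant)
  conds <- unique(scores$condition)
  regions <- unique(scores$region)
  y <- array(NA_real_, dim = c(length(parts), length(conds),
                               length(regions)),
             dimnames = list(parts, conds, regions))
  idx <- cbind(match(scores$participant, parts),
               match(scores$condition, conds),
               match(scores$region, regions))
  y[idx] <- scores$log_ratio
  if (anyNA(y))
    stop("incomplete design: every participant needs every ",
         "condition x region cell (no imputation is performed)")
  y
}

#' One-sample t-tests of suppression against zero
#'
#' For each condition x region cell: a two-sided one-sample t-test of the
#' participants' log ratios against 0 (the no-change value). A cell with
#' zero variance errors, naming the cell, unless all its values are exactly
#' zero (then t = 0, p = 1 by convention).
#'
#' @param scores a `suppression_table` with >= 3 participants.
#' @return data.frame `condition`, `region`, `mean`, `t`, `df`, `p`.
#' @export
baseline_suppression_tests <- function(scores) {
  y <- scores_array(scores)
  n <- dim(y)[1]
  if (n < 3) stop("need at least 3 participants")
  out <- list()
  for (cd in dimnames(y)[[2]]) for (rg in dimnames(y)[[3]]) {
    x <- y[, cd, rg]
    s <- stats::sd(x)
    if (s == 0) {
      if (all(x == 0)) { tval <- 0; p <- 1 }
      else stop("zero variance in cell ", cd, " x ", rg)
    } else {
      tval <- mean(x) / (s / sqrt(n))
      p <- 2 * stats::pt(-abs(tval), n - 1)
    }
    out[[length(out) + 1]] <- data.frame(
      condition = cd, region = rg, mean = mean(x), t = tval, df = n - 1,
      p = p, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# orthonormalized Helmert contrasts, (k-1) x k
orthonormal_contrasts <- function(k) {
  H <- stats::contr.helmert(k)
  t(H %*% diag(1 / sqrt(colSums(H^2)), ncol(H)))
}

# Mauchly's sphericity test on a subjects x levels matrix of scores
mauchly_w <- function(m) {
  k <- ncol(m)
  n <- nrow(m)
  if (k <= 2) return(list(W = 1, p = NA_real_, eps = 1))
  C <- orthonormal_contrasts(k)
  S <- stats::cov(m)
  T <- C %*% S %*% t(C)
  p <- k - 1
  W <- det(T) / (sum(diag(T)) / p)^p
  # Box's chi-square approximation with the second-order series term
  nn <- n - 1
  d <- 1 - (2 * p^2 + p + 2) / (6 * p * nn)
  chi <- -nn * d * log(W)
  df <- p * (p + 1) / 2 - 1
  w2 <- (p + 2) * (p - 1) * (p - 2) * (2 * p^3 + 6 * p^2 + 3 * p + 2) /
    (288 * p^2 * nn^2 * d^2)
  pval <- stats::pchisq(chi, df, lower.tail = FALSE) +
    w2 * (stats::pchisq(chi, df + 4, lower.tail = FALSE) -
            stats::pchisq(chi, df, lower.tail = FALSE))
  lam <- eigen(T, symmetric = TRUE, only.values = TRUE)$values
  eps <- sum(lam)^2 / (p * sum(lam^2))
  list(W = W, p = pval, chisq = chi, df = df, eps = eps)
}

#' Two-way (4 x 2) repeated-measures ANOVA on suppression scores
#'
#' Full within-subject decomposition of participant x condition x region
#' log ratios: main effects of condition and region and their interaction,
#' each tested against its own effect-by-subject error stratum. Reports F,
#' degrees of freedom, p, and partial eta squared
#' (SS_effect / (SS_effect + SS_error)). Mauchly's sphericity test (chi-
#' square approximation on orthonormal contrasts) is run for the condition
#' effect and the interaction; when its p < 0.05 the Greenhouse-Geisser
#' epsilon is applied to that effect's degrees of freedom and the adjusted
#' p is reported.
#'
#' @param scores a complete, balanced `suppression_table`.
#' @param mauchly_alpha threshold below which the GG correction is applied.
#' @return An object of class `rm_anova_result`: `$table` (one row per
#'   effect: `effect`, `df1`, `df2`, `SS`, `SS_error`, `F`, `p`, `pes`,
#'   `mauchly_W`, `mauchly_p`, `gg_eps`, `gg_applied`) and `$ss` (all
#'   sums of squares, including subjects and total).
#' @export
rm_anova_4x2 <- function(scores, mauchly_alpha = 0.05) {
  y <- scores_array(scores)
  n <- dim(y)[1]; a <- dim(y)[2]; b <- dim(y)[3]
  mu <- mean(y)
  m_s <- apply(y, 1, mean); m_c <- apply(y, 2, mean); m_r <- apply(y, 3, mean)
  m_sc <- apply(y, c(1, 2), mean); m_sr <- apply(y, c(1, 3), mean)
  m_cr <- apply(y, c(2, 3), mean)

  ss_subj <- a * b * sum((m_s - mu)^2)
  ss_c <- n * b * sum((m_c - mu)^2)
  ss_r <- n * a * sum((m_r - mu)^2)
  ss_cr <- n * sum((m_cr - outer(m_c, rep(1, b)) -
                      outer(rep(1, a), m_r) + mu)^2)
  ss_cs <- b * sum((m_sc - outer(m_s, rep(1, a)) -
                      outer(rep(1, n), m_c) + mu)^2)
  ss_rs <- a * sum((m_sr - outer(m_s, rep(1, b)) -
                      outer(rep(1, n), m_r) + mu)^2)
  resid <- y
  for (i in seq_len(n)) for (j in seq_len(a)) for (k in seq_len(b))
    resid[i, j, k] <- y[i, j, k] - m_sc[i, j] - m_sr[i, k] - m_cr[j, k] +
      m_s[i] + m_c[j] + m_r[k] - mu
  ss_crs <- sum(resid^2)
  ss_total <- sum((y - mu)^2)

  mk_row <- function(effect, ss_e, df1, ss_err, df2, mau) {
    Fv <- (ss_e / df1) / (ss_err / df2)
    p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
    gg_applied <- FALSE; eps <- NA_real_
    W <- NA_real_; mau_p <- NA_real_
    if (!is.null(mau)) {
      W <- mau$W; mau_p <- mau$p; eps <- mau$eps
      if (is.finite(mau_p) && mau_p < mauchly_alpha) {
        gg_applied <- TRUE
        p <- stats::pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE)
      }
    }
    data.frame(effect = effect, df1 = df1, df2 = df2, SS = ss_e,
               SS_error = ss_err, F = Fv, p = p,
               pes = ss_e / (ss_e + ss_err), mauchly_W = W,
               mauchly_p = mau_p, gg_eps = eps, gg_applied = gg_applied,
               stringsAsFactors = FALSE)
  }
  mau_c <- if (a > 2) mauchly_w(m_sc) else NULL
  # interaction sphericity: condition contrasts of the region-difference
  # scores (exact for b = 2; for b > 2 the kronecker contrast space)
  d_int <- if (b == 2) y[, , 1] - y[, , 2] else NULL
  mau_i <- if (a > 2 && !is.null(d_int)) mauchly_w(d_int) else NULL

  tab <- rbind(
    mk_row("condition", ss_c, a - 1, ss_cs, (a - 1) * (n - 1), mau_c),
    mk_row("region", ss_r, b - 1, ss_rs, (b - 1) * (n - 1), NULL),
    mk_row("condition:region", ss_cr, (a - 1) * (b - 1), ss_crs,
           (a - 1) * (b - 1) * (n - 1), mau_i))
  structure(list(table = tab,
                 ss = c(subjects = ss_subj, condition = ss_c,
                        region = ss_r, interaction = ss_cr,
                        condition_x_subj = ss_cs, region_x_subj = ss_rs,
                        interaction_x_subj = ss_crs, total = ss_total),
                 n = n, a = a, b = b),
            class = "rm_anova_result")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (%d participants, %d x %d within)\n",
              x$n, x$a, x$b))
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    extra <- if (isTRUE(tab$gg_applied[i]))
      sprintf(" [GG eps = %.3f applied]", tab$gg_eps[i]) else ""
    cat(sprintf("  %-17s F(%g, %g) = %.3f, p = %.4g, pes = %.3f%s\n",
                tab$effect[i], tab$df1[i], tab$df2[i], tab$F[i], tab$p[i],
                tab$pes[i], extra))
  }
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Textbook closed form: for ascending p-values,
#' `p_adj_(i) = min over j >= i of (m * p_(j) / j)`, capped at 1, mapped
#' back to the input order.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1 | !is.finite(pvals)))
    stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  o <- order(pvals, decreasing = TRUE)
  adj <- pmin(1, cummin(m / (m:1) * pvals[o]))
  adj[order(o)]
}

#' Pairwise condition contrasts within a region, FDR-corrected
#'
#' All paired two-sided t-tests between conditions on participant-matched
#' log ratios within one region; Benjamini-Hochberg correction over that
#' region's family of tests.
#'
#' @param scores a `suppression_table`.
#' @param region region label (e.g. `"central"`).
#' @return data.frame `region`, `condition_a`, `condition_b`, `t`, `df`,
#'   `p_raw`, `p_fdr`.
#' @export
pairwise_fdr <- function(scores, region) {
  y <- scores_array(scores)
  if (!region %in% dimnames(y)[[3]]) stop("unknown region: ", region)
  conds <- dimnames(y)[[2]]
  if (length(conds) < 2) stop("need at least 2 conditions")
  pairs <- utils::combn(conds, 2)
  n <- dim(y)[1]
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    d <- y[, pairs[1, j], region] - y[, pairs[2, j], region]
    tval <- mean(d) / (stats::sd(d) / sqrt(n))
    data.frame(region = region, condition_a = pairs[1, j],
               condition_b = pairs[2, j], t = tval, df = n - 1,
               p_raw = 2 * stats::pt(-abs(tval), n - 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_adjust(out$p_raw)
  out
}
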