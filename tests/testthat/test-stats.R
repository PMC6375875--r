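test_that("baseline tests follow the stated conventions", {
  sc <- random_scores(10, sd = 0)
  sc$log_ratio <- 0
  out <- baseline_suppression_tests(sc)
  expect_equal(nrow(out), 8)
  expect_true(all(out$t == 0) && all(out$p == 1))
  # sign flip negates t, keeps p
  sc2 <- random_scores(12, sd = 0.05, seed = 5)
  a <- baseline_suppression_tests(sc2)
  sc2$log_ratio <- -sc2$log_ratio
  b <- baseline_suppression_tests(sc2)
  expect_equal(b$t, -a$t)
  expect_equal(b$p, a$p)
  expect_equal(unique(a$df), 11)
  # t and p agree with the base one-sample t-test oracle
  x <- sc2$log_ratio[sc2$condition == "happy" & sc2$region == "central"]
  tt <- stats::t.test(x)
  expect_equal(b$t[b$condition == "happy" & b$region == "central"],
               unname(tt$statistic), tolerance = 1e-12)
  # zero variance with nonzero mean errors, naming the cell
  sc3 <- random_scores(6, sd = 0)
  sc3$log_ratio <- -0.2
  expect_error(baseline_suppression_tests(sc3), "zero variance")
})

test_that("suppression of -0.1 (sd 0.1) at n = 22 is reliably detected", {
  # exact noncentral-t power at ncp = 0.1 / (0.1 / sqrt(22)) = 4.69
  crit_strict <- stats::qt(1 - 5e-4, 21)
  power_strict <- 1 - stats::pt(crit_strict, 21, ncp = sqrt(22)) +
    stats::pt(-crit_strict, 21, ncp = sqrt(22))
  crit05 <- stats::qt(0.975, 21)
  power05 <- 1 - stats::pt(crit05, 21, ncp = sqrt(22)) +
    stats::pt(-crit05, 21, ncp = sqrt(22))
  expect_gt(power05, 0.99)
  # empirical rejection rates of baseline_suppression_tests match both
  set.seed(42)
  hit_strict <- 0; hit05 <- 0; nrep <- 400
  sc <- random_scores(22, sd = 0)
  for (r in seq_len(nrep)) {
    sc$log_ratio <- stats::rnorm(176, -0.1, 0.1)
    p <- baseline_suppression_tests(sc)$p[1]
    hit_strict <- hit_strict + (p < 0.001)
    hit05 <- hit05 + (p < 0.05)
  }
  expect_lt(abs(hit_strict / nrep - power_strict), 0.06)
  expect_gt(hit05 / nrep, 0.97)
})

test_that("rm ANOVA matches the aov error-strata oracle on random tables", {
  set.seed(77)
  for (rep_i in 1:100) {
    n <- sample(c(8, 12, 22), 1)
    sc <- random_scores(n, sd = 0.1, seed = 1000 + rep_i)
    ours <- rm_anova_4x2(sc)
    df <- as.data.frame(sc)
    df$participant <- factor(df$participant)
    df$condition <- factor(df$condition)
    df$region <- factor(df$region)
    fit <- summary(stats::aov(
      log_ratio ~ condition * region +
        Error(participant / (condition * region)), df))
    o_cond <- fit[["Error: participant:condition"]][[1]]
    o_reg <- fit[["Error: participant:region"]][[1]]
    o_int <- fit[["Error: participant:condition:region"]][[1]]
    expect_equal(ours$table$F[1], o_cond["condition", "F value"],
                 tolerance = 1e-7)
    expect_equal(ours$table$F[2], o_reg["region", "F value"],
                 tolerance = 1e-7)
    expect_equal(ours$table$F[3],
                 o_int["condition:region", "F value"], tolerance = 1e-7)
    # unadjusted p values to 6 decimals
    p_raw <- stats::pf(ours$table$F, ours$table$df1, ours$table$df2,
                       lower.tail = FALSE)
    expect_equal(p_raw[1], o_cond["condition", "Pr(>F)"],
                 tolerance = 1e-7)
    expect_equal(p_raw[3], o_int["condition:region", "Pr(>F)"],
                 tolerance = 1e-7)
  }
})

test_that("rm ANOVA reports the reference-design degrees of freedom at n = 22", {
  sc <- random_scores(22, seed = 3)
  out <- rm_anova_4x2(sc)
  expect_equal(out$table$df1, c(3, 1, 3))
  expect_equal(out$table$df2, c(63, 21, 63))
  expect_true(all(out$table$pes >= 0 & out$table$pes <= 1))
  # partial eta squared definition
  expect_equal(out$table$pes,
               out$table$SS / (out$table$SS + out$table$SS_error))
  # sums of squares are additive
  ss <- out$ss
  expect_equal(sum(ss[c("subjects", "condition", "region", "interaction",
                        "condition_x_subj", "region_x_subj",
                        "interaction_x_subj")]),
               unname(ss["total"]), tolerance = 1e-10)
  # incomplete tables are refused
  expect_error(rm_anova_4x2(sc[-1, ]), "incomplete")
})

test_that("collapsing regions reduces the condition effect to a one-way RM ANOVA", {
  sc <- random_scores(14, seed = 9)
  two_way <- rm_anova_4x2(sc)
  m <- with(as.data.frame(sc),
            tapply(log_ratio, list(participant, condition), mean))
  n <- nrow(m); a <- ncol(m)
  mu <- mean(m); mc <- colMeans(m); ms <- rowMeans(m)
  ss_c <- n * sum((mc - mu)^2)
  ss_err <- sum((m - outer(ms, rep(1, a)) -
                   outer(rep(1, n), mc) + mu)^2)
  f_oneway <- (ss_c / (a - 1)) / (ss_err / ((a - 1) * (n - 1)))
  expect_equal(two_way$table$F[1], f_oneway, tolerance = 1e-10)
})

test_that("Mauchly statistic matches the base mlm oracle", {
  sc <- random_scores(22, seed = 13)
  m <- with(as.data.frame(sc),
            tapply(log_ratio, list(participant, condition), mean))
  ours <- musupp:::mauchly_w(m)
  fit <- stats::lm(m ~ 1)
  oracle <- stats::mauchly.test(fit, X = ~1)
  expect_equal(ours$W, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(ours$p, unname(oracle$p.value), tolerance = 2e-3)
})

test_that("GG correction engages only when sphericity is violated", {
  # strongly non-spherical: one condition carries most of the variance
  set.seed(31)
  n <- 24
  base <- matrix(stats::rnorm(n * 4, sd = 0.02), n)
  base[, 1] <- base[, 1] + stats::rnorm(n, sd = 0.6)
  g <- expand.grid(participant = sprintf("P%02d", 1:n),
                   condition = c("a", "b", "c", "d"),
                   region = c("x", "y"), stringsAsFactors = FALSE)
  g$log_ratio <- base[cbind(match(g$participant, sprintf("P%02d", 1:n)),
                            match(g$condition, c("a", "b", "c", "d")))] +
    stats::rnorm(nrow(g), sd = 0.02)
  class(g) <- c("suppression_table", "data.frame")
  out <- rm_anova_4x2(g)
  expect_lt(out$table$mauchly_p[1], 0.05)
  expect_true(out$table$gg_applied[1])
  eps <- out$table$gg_eps[1]
  expect_equal(out$table$p[1],
               stats::pf(out$table$F[1], 3 * eps, 69 * eps,
                         lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("BH adjustment matches the closed form and base p.adjust", {
  expect_equal(bh_adjust(c(0.005, 0.5)), c(0.01, 0.5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06)),
               rep(0.06, 6))
  expect_equal(bh_adjust(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(5)
  for (rep_i in 1:50) {
    p <- stats::runif(sample(1:20, 1))^2
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
    expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"), tolerance = 1e-12)
    # permutation equivariance
    o <- sample(length(p))
    expect_equal(bh_adjust(p[o])[order(o)], bh_adjust(p))
  }
})

test_that("pairwise contrasts find exactly the planted difference", {
  # neutral shifted down at central only; all other cells share the null
  sc <- random_scores(22, sd = 0.04,
                      shift = list(neutral = c(-0.15, 0)), seed = 21)
  cen <- pairwise_fdr(sc, "central")
  expect_equal(nrow(cen), 6)
  planted <- with(cen, condition_a == "neutral" | condition_b == "neutral")
  expect_true(all(cen$p_fdr[planted] < 0.05))
  expect_true(all(cen$p_fdr[!planted] > 0.05))
  expect_true(all(cen$p_fdr >= cen$p_raw))
  occ <- pairwise_fdr(sc, "occipital")
  expect_true(all(occ$p_fdr > 0.05))
  # paired-t oracle on one contrast
  y <- musupp:::scores_array(sc)
  d <- y[, "neutral", "central"] - y[, "nonbio", "central"]
  tt <- stats::t.test(d)
  row <- cen[cen$condition_a == "neutral" & cen$condition_b == "nonbio" |
               cen$condition_a == "nonbio" & cen$condition_b == "neutral", ]
  expect_equal(abs(row$t), abs(unname(tt$statistic)), tolerance = 1e-12)
  expect_error(pairwise_fdr(sc, "parietal"), "unknown region")
})
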