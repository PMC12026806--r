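mixed_design <- function(seed = 42, n_per_group = 4) {
  set.seed(seed)
  d <- tidyr::expand_grid(unit = sprintf("u%d", seq_len(2 * n_per_group)),
                          epoch = c("base", "drug"))
  d$treatment <- ifelse(d$unit %in% sprintf("u%d", seq_len(n_per_group)),
                        "sal", "rs")
  d$y <- rnorm(nrow(d)) + 2 * (d$epoch == "drug") +
    0.7 * (d$treatment == "rs") * (d$epoch == "drug")
  d
}

test_that("rm-ANOVA matches the independent aov decomposition", {
  d <- mixed_design()
  fit <- tidy(rm_anova(d, "y", "epoch", "unit", "treatment"))
  oracle <- summary(stats::aov(y ~ epoch * treatment + Error(unit / epoch),
                               data = transform(d, unit = factor(unit))))
  within_tab <- oracle[["Error: unit:epoch"]][[1]]
  between_tab <- oracle[["Error: unit"]][[1]]
  rn_w <- trimws(rownames(within_tab))
  rn_b <- trimws(rownames(between_tab))
  expect_equal(fit$statistic[fit$term == "epoch"],
               within_tab[rn_w == "epoch", "F value"], tolerance = 1e-10)
  expect_equal(fit$statistic[fit$term == "epoch:treatment"],
               within_tab[rn_w == "epoch:treatment", "F value"],
               tolerance = 1e-10)
  expect_equal(fit$statistic[fit$term == "treatment"],
               between_tab[rn_b == "treatment", "F value"], tolerance = 1e-10)
  expect_equal(fit$p.value[fit$term == "epoch"],
               within_tab[rn_w == "epoch", "Pr(>F)"], tolerance = 1e-10)
})

test_that("two-level within F equals the squared paired t exactly", {
  d <- mixed_design(7)
  fit <- tidy(rm_anova(d, "y", "epoch", "unit"))
  tt <- stats::t.test(d$y[d$epoch == "drug"], d$y[d$epoch == "base"],
                      paired = TRUE)
  expect_equal(fit$statistic[1], unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(fit$p.value[1], tt$p.value, tolerance = 1e-12)
})

test_that("F is invariant to affine transforms and unit relabeling", {
  d <- mixed_design(11)
  f0 <- tidy(rm_anova(d, "y", "epoch", "unit", "treatment"))$statistic
  d2 <- d
  d2$y <- 3.7 * d2$y - 12
  expect_equal(tidy(rm_anova(d2, "y", "epoch", "unit", "treatment"))$statistic,
               f0, tolerance = 1e-10)
  d3 <- d
  d3$unit <- paste0("animal_", d3$unit)
  expect_equal(tidy(rm_anova(d3, "y", "epoch", "unit", "treatment"))$statistic,
               f0, tolerance = 1e-12)
})

test_that("unbalanced or incomplete designs are rejected with the culprit", {
  d <- mixed_design()
  expect_error(rm_anova(d[-1, ], "y", "epoch", "unit"), "u1")
  d_dup <- rbind(d, d[3, ])
  expect_error(rm_anova(d_dup, "y", "epoch", "unit"), "need 1")
})

test_that("four-level designs support Greenhouse-Geisser correction", {
  set.seed(13)
  d <- tidyr::expand_grid(unit = sprintf("u%d", 1:8),
                          treatment = c("sal", "rs", "sal_spcp", "rs_spcp"))
  d$y <- rnorm(nrow(d)) + 2 * (d$treatment == "sal_spcp")
  plain <- rm_anova(d, "y", "treatment", "unit")
  gg <- rm_anova(d, "y", "treatment", "unit", gg = TRUE)
  expect_equal(glance(plain)$epsilon, 1)
  eps <- glance(gg)$epsilon
  expect_gte(eps, 1 / 3)
  expect_lte(eps, 1)
  expect_equal(tidy(gg)$statistic, tidy(plain)$statistic, tolerance = 1e-12)
  expect_gte(tidy(gg)$p.value[1], tidy(plain)$p.value[1])
})

test_that("bonferroni arithmetic is exact and clipped", {
  expect_equal(bonferroni(0.01, m = 3), 0.03)
  expect_equal(bonferroni(0.5, m = 4), 1)
  expect_equal(bonferroni(c(0.2, 0.4)), c(0.4, 0.8))
  expect_equal(bonferroni(0.7, m = 1), 0.7)
  expect_error(bonferroni(1.2, 2), "\\[0, 1\\]")
})

test_that("t-tests match the closed-form statistic", {
  x <- c(4.1, 5.2, 6.3, 5.8, 4.9)
  y <- c(6.0, 7.1, 6.8, 7.5, 6.2)
  out <- ttest(x, y)
  # independent pooled-variance computation
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  t_manual <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  expect_equal(out$statistic, t_manual, tolerance = 1e-12)
  expect_equal(out$df, 8)
  expect_equal(out$p.value, 2 * pt(abs(t_manual), 8, lower.tail = FALSE),
               tolerance = 1e-12)

  same <- ttest(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  expect_error(ttest(c(1, 2, 3), c(3, 4, 5), paired = TRUE), "zero variance")
  expect_error(ttest(1, c(1, 2)), "at least 2")
})
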