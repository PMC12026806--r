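# The inferential layer: repeated-measures ANOVA (one within-subject
# factor, optional between-subject factor and their interaction),
# Bonferroni correction, and t-tests.

#' Repeated-measures ANOVA
#'
#' Sums-of-squares decomposition for a design with one within-subject
#' factor (e.g. epoch: baseline vs drug), an optional between-subject
#' factor (e.g. treatment), and subjects as the unit of repetition. With a
#' two-level within factor and no between factor, the within F equals the
#' squared paired t statistic exactly. F values are invariant to affine
#' transformation of the dependent variable.
#'
#' Greenhouse-Geisser correction of the within-factor degrees of freedom is
#' available for designs with more than two within levels but is off by
#' default.
#'
#' @param data Long-format data frame.
#' @param dv Name of the dependent-variable column.
#' @param within Name of the within-subject factor column.
#' @param unit Name of the subject identifier column.
#' @param between Optional name of the between-subject factor column.
#' @param gg Apply Greenhouse-Geisser correction (default `FALSE`).
#' @return An `rm_anova` object; `tidy()` gives the term table
#'   (`term`, `ss`, `df`, `ms`, `statistic`, `p.value`), `glance()` a
#'   one-row design summary.
#' @examples
#' d <- tidyr::expand_grid(unit = 1:6, epoch = c("baseline", "drug"))
#' d$y <- rnorm(nrow(d)) + (d$epoch == "drug")
#' tidy(rm_anova(d, dv = "y", within = "epoch", unit = "unit"))
#' @export
rm_anova <- function(data, dv, within, unit, between = NULL, gg = FALSE) {
  y <- data[[dv]]
  w <- factor(data[[within]])
  u <- factor(data[[unit]])
  if (anyNA(y)) abort("missing values in the dependent variable")
  a <- nlevels(w)
  units <- levels(u)
  n_units <- length(units)
  if (a < 2) abort("within factor needs at least 2 levels")
  if (n_units < 2) abort("need at least 2 units")

  # balance check: every unit at every within level exactly once
  tab <- table(u, w)
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)[1, ]
    abort(sprintf("unit '%s' has %d observations at within level '%s' (need 1)",
                  rownames(tab)[bad[1]], tab[bad[1], bad[2]],
                  colnames(tab)[bad[2]]))
  }

  if (!is.null(between)) {
    b <- factor(data[[between]])
    bt <- table(u, b)
    if (any(rowSums(bt > 0) != 1)) {
      abort("between factor must be constant within unit")
    }
    unit_group <- b[match(units, u)]
  } else {
    unit_group <- factor(rep("all", n_units))
  }
  nb <- nlevels(unit_group)

  grand <- mean(y)
  subj_means <- tapply(y, u, mean)[units]
  w_means <- tapply(y, w, mean)
  grp_of <- unit_group
  grp_sizes <- table(grp_of)

  ss_total <- sum((y - grand)^2)
  ss_between_subj_tot <- a * sum((subj_means - grand)^2)

  if (nb > 1) {
    grp_means <- tapply(y, grp_of[match(u, units)], mean)
    ss_b <- a * sum(grp_sizes * (grp_means[names(grp_sizes)] - grand)^2)
  } else {
    ss_b <- 0
  }
  ss_subj <- ss_between_subj_tot - ss_b

  ss_w <- n_units * sum((w_means - grand)^2)

  if (nb > 1) {
    cell_means <- tapply(y, list(grp_of[match(u, units)], w), mean)
    grp_means_v <- tapply(y, grp_of[match(u, units)], mean)
    ss_int <- 0
    for (j in seq_len(nb)) {
      for (k in seq_len(a)) {
        dev <- cell_means[j, k] - grp_means_v[j] - w_means[k] + grand
        ss_int <- ss_int + grp_sizes[j] * dev^2
      }
    }
    ss_int <- as.numeric(ss_int)
  } else {
    ss_int <- 0
  }

  ss_err_w <- ss_total - ss_b - ss_subj - ss_w - ss_int

  df_w <- a - 1
  df_err_w <- (n_units - nb) * (a - 1)
  df_b <- nb - 1
  df_subj <- n_units - nb

  eps <- 1
  if (gg && a > 2) {
    # Greenhouse-Geisser epsilon from the double-centered pooled covariance
    scores <- matrix(NA_real_, n_units, a)
    for (k in seq_len(a)) {
      sel <- w == levels(w)[k]
      scores[, k] <- y[sel][match(units, u[sel])]
    }
    if (nb > 1) {
      for (g in levels(unit_group)) {
        rows <- unit_group == g
        scores[rows, ] <- scale(scores[rows, , drop = FALSE],
                                center = TRUE, scale = FALSE)
      }
      S <- crossprod(scores) / (n_units - nb)
    } else {
      S <- stats::cov(scores)
    }
    Sc <- S - outer(rowMeans(S), rep(1, a)) -
      outer(rep(1, a), colMeans(S)) + mean(S)
    eps <- sum(diag(Sc))^2 / ((a - 1) * sum(Sc^2))
    eps <- min(1, max(eps, 1 / (a - 1)))
  }

  terms <- list()
  ms_err_w <- ss_err_w / df_err_w
  f_w <- (ss_w / df_w) / ms_err_w
  terms$within <- c(ss = ss_w, df = df_w * eps, ms = ss_w / (df_w * eps),
                    f = f_w, p = pf(f_w, df_w * eps, df_err_w * eps,
                                    lower.tail = FALSE))
  if (nb > 1) {
    ms_subj <- ss_subj / df_subj
    f_b <- (ss_b / df_b) / ms_subj
    f_i <- (ss_int / (df_b * df_w)) / ms_err_w
    terms$between <- c(ss = ss_b, df = df_b, ms = ss_b / df_b, f = f_b,
                       p = pf(f_b, df_b, df_subj, lower.tail = FALSE))
    terms$interaction <- c(ss = ss_int, df = df_b * df_w * eps,
                           ms = ss_int / (df_b * df_w * eps), f = f_i,
                           p = pf(f_i, df_b * df_w * eps, df_err_w * eps,
                                  lower.tail = FALSE))
  }
  term_names <- c(within, if (nb > 1) between,
                  if (nb > 1) paste(within, between, sep = ":"))
  tab_out <- tibble::tibble(
    term = term_names,
    ss = unname(vapply(terms, `[[`, 0, "ss")),
    df = unname(vapply(terms, `[[`, 0, "df")),
    ms = unname(vapply(terms, `[[`, 0, "ms")),
    statistic = unname(vapply(terms, `[[`, 0, "f")),
    p.value = unname(vapply(terms, `[[`, 0, "p"))
  )
  structure(list(
    terms = tab_out,
    error = tibble::tibble(
      stratum = c("subjects", "within"),
      ss = c(ss_subj, ss_err_w),
      df = c(df_subj, df_err_w * eps)
    ),
    design = list(dv = dv, within = within, between = between, unit = unit,
                  n_units = n_units, n_within = a, n_between = nb,
                  gg = gg, epsilon = eps)
  ), class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  d <- x$design
  cat(sprintf("Repeated-measures ANOVA: %s ~ %s%s, %d units\n", d$dv,
              d$within, if (!is.null(d$between)) paste0(" x ", d$between) else "",
              d$n_units))
  print(as.data.frame(x$terms), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @rdname rm_anova
#' @param x An `rm_anova` object.
#' @param ... Unused.
#' @export
tidy.rm_anova <- function(x, ...) x$terms

#' @rdname rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(
    n_units = x$design$n_units,
    n_within_levels = x$design$n_within,
    n_between_levels = x$design$n_between,
    epsilon = x$design$epsilon,
    gg = x$design$gg
  )
}

#' Bonferroni correction
#'
#' `p_adj = min(1, m * p)` for each p-value; `m` defaults to the number of
#' p-values supplied.
#'
#' @param pvals Numeric p-values in \[0, 1\].
#' @param m Number of comparisons (default `length(pvals)`).
#' @return Adjusted p-values, clipped at 1.
#' @examples
#' bonferroni(c(0.01, 0.5), m = 3)
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  if (!is_count(m) || m < 1) abort("`m` must be a positive count")
  pmin(1, m * pvals)
}

#' Student's t-test
#'
#' Two-sided t-test, paired or unpaired (equal-variance Student's by
#' default; `var_equal = FALSE` gives Welch). A paired test with
#' zero-variance differences is undefined and raises an error rather than
#' returning a statistic.
#'
#' @param x,y Numeric samples (each of length >= 2; paired requires equal
#'   length).
#' @param paired Paired test (default `FALSE`).
#' @param var_equal Assume equal variances when unpaired (default `TRUE`).
#' @return One-row tibble with `statistic` (t), `df`, `p.value`,
#'   `estimate` (mean difference), `method`.
#' @export
ttest <- function(x, y, paired = FALSE, var_equal = TRUE) {
  if (length(x) < 2 || length(y) < 2) abort("need at least 2 values per group")
  if (paired) {
    if (length(x) != length(y)) abort("paired test requires equal lengths")
    if (sd(x - y) == 0) {
      abort("paired differences have zero variance; t is undefined (flagged)")
    }
  }
  if (!paired && sd(c(x, y)) == 0) {
    return(tibble::tibble(statistic = 0, df = length(x) + length(y) - 2,
                          p.value = 1, estimate = 0,
                          method = "Student's t-test"))
  }
  tt <- stats::t.test(x, y, paired = paired,
                      var.equal = !paired && var_equal)
  tibble::tibble(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p.value = tt$p.value,
    estimate = if (paired) unname(tt$estimate) else
      unname(tt$estimate[1] - tt$estimate[2]),
    method = tt$method
  )
}
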