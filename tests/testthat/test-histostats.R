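ref_counts <- function() {
  tibble::tibble(
    animal_id = rep(c("a1", "a2"), each = 2),
    sex = rep(c("female", "male"), each = 2),
    region = "CA1", marker = "PV",
    section_id = rep(1:2, 2),
    n_marker_pos = c(20, 20, 10, 30),
    n_coexpress = c(10, 10, 2, 12)
  )
}

test_that("per-animal summary pools cells across sections", {
  pa <- per_animal_summary(ref_counts())
  expect_equal(pa$pct_coexpress[pa$animal_id == "a1"], 50)
  expect_equal(pa$pct_coexpress[pa$animal_id == "a2"], 100 * 14 / 40)
  expect_equal(pa$mean_count, c(20, 20))

  # mean-of-sections variant differs when counts are unequal
  pa2 <- per_animal_summary(ref_counts(), percent = "mean_of_sections")
  expect_equal(pa2$pct_coexpress[pa2$animal_id == "a2"],
               mean(c(100 * 2 / 10, 100 * 12 / 30)))

  zero <- ref_counts()
  zero$n_marker_pos <- 0
  zero$n_coexpress <- 0
  pz <- per_animal_summary(zero)
  expect_true(all(is.na(pz$pct_coexpress)))
  expect_true(all(pz$flagged))

  bad <- ref_counts()
  bad$n_coexpress[1] <- 99
  expect_error(per_animal_summary(bad), "exceed")
})

test_that("generated binomial tables recover the planted proportion", {
  tab <- gen_count_table(c(female = 4, male = 4), 4, marker_rate = 120,
                         coexpr_prob = 0.3, regions = "CA1", seed = 11)
  pa <- per_animal_summary(tab)
  expect_true(all(abs(pa$pct_coexpress - 30) < 5))
  expect_true(all(pa$pct_coexpress >= 0 & pa$pct_coexpress <= 100))
})

test_that("pooled group mean equals the weighted mean of sex means", {
  tab <- gen_count_table(c(female = 5, male = 4), 3, marker_rate = 25,
                         coexpr_prob = 0.5, regions = c("CA1", "DG"),
                         seed = 12)
  pa <- per_animal_summary(tab)
  g <- group_summary(pa)
  for (reg in c("CA1", "DG")) {
    sexes <- g[g$region == reg & g$sex != "all", ]
    all_row <- g[g$region == reg & g$sex == "all", ]
    expect_equal(all_row$mean, pooled_mean(sexes$mean, sexes$n),
                 tolerance = 1e-12)
  }
  # single animal: mean is its value, SEM flagged as zero-width
  one <- pa[pa$animal_id == pa$animal_id[1] & pa$region == "CA1", ]
  g1 <- group_summary(one)
  expect_equal(g1$sem[g1$sex == "all"], 0)
})

test_that("pooling the published sex rows reproduces every printed all row", {
  ref <- coexpression_reference()
  for (m in c("PV", "SST")) {
    for (reg in unique(ref$region)) {
      rows <- ref[ref$region == reg & ref$marker == m, ]
      sexes <- rows[rows$sex != "all", ]
      printed <- rows$pct_coexpress[rows$sex == "all"]
      expect_equal(round(pooled_mean(sexes$pct_coexpress, sexes$n)), printed,
                   info = paste(reg, m))
    }
  }
})

test_that("sex comparison behaves at both extremes", {
  pa <- tibble::tibble(
    animal_id = paste0("a", 1:8),
    sex = rep(c("female", "male"), each = 4),
    region = "CA1", marker = "PV",
    pct_coexpress = c(50, 52, 48, 50, 50, 52, 48, 50)
  )
  same <- sex_comparison(pa, "CA1", "PV")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  shifted <- pa
  shifted$pct_coexpress[shifted$sex == "male"] <-
    shifted$pct_coexpress[shifted$sex == "male"] + 5 * sd(c(50, 52, 48, 50))
  sh <- sex_comparison(shifted, "CA1", "PV")
  expect_lt(sh$p, 0.01)
  expect_lt(sh$cohens_d, 0)

  expect_error(sex_comparison(pa[pa$sex == "female", ], "CA1", "PV"),
               "each sex")
})
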