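test_that("mid-rank percentiles match the formula and its symmetries", {
  expect_equal(percentile_rank(1:9, 5), 50)
  expect_equal(percentile_rank(rep(7, 13), 7), 50)         # full tie
  expect_equal(percentile_rank(1:4, 1), 12.5)              # (0 + 0.5)/4 * 100
  expect_equal(percentile_rank(1:4, c(1, 4)), c(12.5, 87.5))
  expect_equal(percentile_rank(1:4, 2, method = "ecdf"), 50)
  expect_error(percentile_rank(numeric(0), 1), "non-empty")
})

test_that("tertile levels use the documented boundary conventions", {
  expect_equal(tertile_level(c(33.999, 34, 66.999, 67, 0, 100)),
               c("low", "medium", "medium", "high", "low", "high"))
})

test_that("n distinct values split into near-equal tertiles", {
  # 9 distinct values: mid-rank percentiles (i - 0.5)/9*100 give exactly 3/3/3
  lv <- tertile_level(percentile_rank(1:9, 1:9))
  expect_equal(as.integer(table(factor(lv, c("low", "medium", "high")))),
               c(3L, 3L, 3L))
  # 1000 distinct values: sizes deviate by at most 1 from the proportions
  # the (34, 67) breaks define: 34% low, 33% medium, 33% high
  x <- withr::with_seed(1, sample(seq(0, 5000, 0.5), 1000))
  sizes <- table(factor(tertile_level(percentile_rank(x, x)),
                        c("low", "medium", "high")))
  expect_true(all(abs(as.integer(sizes) - c(340L, 330L, 330L)) <= 1))
})

test_that("classification handles no-service counties and joins", {
  ids <- sprintf("C%03d", 1:12)
  rec <- compute_density(
    tibble::tibble(county_id = ids,
                   provider_count = c(0L, 0L, 0L, 1:9)),
    tibble::tibble(county_id = ids, ffs_pop = rep(1000, 12)))
  smoking <- tibble::tibble(county_id = ids,
                            smoking_prev_pct = c(25, 11, 18, seq(8, 24, 2)))
  cls <- classify_bivariate(rec, smoking)
  expect_equal(cls$code[cls$county_id %in% ids[1:3]],
               rep("no_service", 3))
  # smoking levels are still computed for no-service counties
  expect_equal(cls$smoking_level[cls$county_id == "C001"], "high")
  # served counties carry one of the nine codes
  expect_true(all(cls$code[!cls$code == "no_service"] %in% bivariate_codes()))
  # 9 served counties with distinct values split 3/3/3 on density
  served_cls <- cls[cls$code != "no_service", ]
  expect_equal(as.integer(table(factor(served_cls$density_level,
                                       c("low", "medium", "high")))),
               c(3L, 3L, 3L))
  # missing smoking drops the county with a warning
  expect_warning(cls2 <- classify_bivariate(rec, smoking[-1, ]), "C001")
  expect_false("C001" %in% cls2$county_id)
  # a single served county sits at percentile 50 -> medium
  rec1 <- compute_density(tibble::tibble(county_id = c("A", "B"),
                                         provider_count = c(3L, 0L)),
                          tibble::tibble(county_id = c("A", "B"),
                                         ffs_pop = c(100, 100)))
  cls1 <- classify_bivariate(rec1, tibble::tibble(county_id = c("A", "B"),
                                                  smoking_prev_pct = c(15, 20)))
  expect_equal(cls1$density_level[cls1$county_id == "A"], "medium")
})

test_that("levels are invariant to monotone transforms and row order", {
  ids <- sprintf("C%03d", 1:30)
  rec <- withr::with_seed(3, compute_density(
    tibble::tibble(county_id = ids, provider_count = rpois(30, 3)),
    tibble::tibble(county_id = ids, ffs_pop = sample(500:3000, 30))))
  smoking <- withr::with_seed(4, tibble::tibble(
    county_id = ids, smoking_prev_pct = runif(30, 8, 30)))
  cls <- classify_bivariate(rec, smoking)
  # strictly increasing transform of smoking leaves levels unchanged
  smoking2 <- smoking
  smoking2$smoking_prev_pct <- exp(smoking2$smoking_prev_pct / 10)
  cls2 <- classify_bivariate(rec, smoking2)
  expect_equal(cls$smoking_level, cls2$smoking_level)
  expect_equal(cls$density_level, cls2$density_level)
  # permuting rows never changes any county's code
  perm <- withr::with_seed(5, sample.int(30))
  cls3 <- classify_bivariate(rec[perm, ], smoking[rev(perm), ])
  merged <- merge(cls, cls3, by = "county_id")
  expect_equal(merged$code.x, merged$code.y)
})

test_that("crosstab counts conserve and cover all cells", {
  ids <- sprintf("C%03d", 1:20)
  rec <- withr::with_seed(6, compute_density(
    tibble::tibble(county_id = ids, provider_count = rbinom(20, 6, 0.4)),
    tibble::tibble(county_id = ids, ffs_pop = sample(500:3000, 20))))
  smoking <- withr::with_seed(7, tibble::tibble(
    county_id = ids, smoking_prev_pct = runif(20, 8, 30)))
  cls <- classify_bivariate(rec, smoking)
  ct <- crosstab(cls)
  expect_equal(sum(ct$n), nrow(cls))
  expect_equal(nrow(ct), 12)  # 3x3 plus a no_service row per smoking level
  # all-no-service input zeroes the 3x3 cells
  rec0 <- compute_density(tibble::tibble(county_id = ids, provider_count = 0L),
                          tibble::tibble(county_id = ids, ffs_pop = rep(100, 20)))
  ct0 <- crosstab(classify_bivariate(rec0, smoking))
  expect_equal(sum(ct0$n[ct0$density_level != "no_service"]), 0)
  expect_equal(sum(ct0$n), 20)
})
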