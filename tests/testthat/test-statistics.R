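test_that("ANOVA matches explicit sums of squares on random fixtures", {
  set.seed(77)
  for (i in 1:25) {
    vals <- random_group_fixture()
    got <- one_way_anova(vals)
    ora <- oracle_anova(vals)
    expect_lt(abs(got$f_stat - ora$f_stat), 1e-8)
    expect_lt(abs(got$p_value - ora$p_value), 1e-8)
    expect_equal(got$df_between, ora$df_between)
    expect_equal(got$df_within, ora$df_within)
  }
})

test_that("hand-computed fixture and degenerate cases behave classically", {
  # {A:(1,2,3), B:(2,3,4), C:(6,7,8)}: SSB = 3*(2-4)^2+3*(3-4)^2+3*(7-4)^2=42
  # SSW = 6; F = (42/2)/(6/6) = 21
  got <- one_way_anova(list(A = 1:3, B = 2:4, C = 6:8))
  expect_lt(abs(got$f_stat - 21), 1e-8)
  expect_equal(c(got$df_between, got$df_within), c(2L, 6L))
  # identical groups -> F = 0
  same <- one_way_anova(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_equal(same$f_stat, 0)
  # two groups: F equals the pooled-variance t statistic squared
  set.seed(8)
  x <- rnorm(12); y <- rnorm(15, 0.5)
  f <- one_way_anova(list(x = x, y = y))$f_stat
  t <- unname(t.test(x, y, var.equal = TRUE)$statistic)
  expect_lt(abs(f - t^2), 1e-10)
  # failures name the offending group
  expect_error(one_way_anova(list(a = 1:3)), "2 groups")
  expect_error(one_way_anova(list(a = 1:3, b = 5)), "b")
})

test_that("Tukey HSD agrees with the studentized-range oracle", {
  set.seed(101)
  for (i in 1:25) {
    vals <- random_group_fixture()
    got <- tukey_hsd(vals)
    ora <- oracle_tukey(vals)
    key_got <- paste(pmin(got$group_a, got$group_b),
                     pmax(got$group_a, got$group_b))
    key_ora <- paste(pmin(ora$a, ora$b), pmax(ora$a, ora$b))
    expect_setequal(key_got, key_ora)
    m <- match(key_got, key_ora)
    expect_true(all(abs(got$p_adj - ora$p[m]) < 1e-8))
  }
})

test_that("Tukey flags behave at the extremes and dominate pairwise t", {
  set.seed(5)
  same <- tukey_hsd(list(a = rnorm(8), b = rnorm(8), c = rnorm(8)),
                    alpha = 0.05)
  # a 10-sigma shifted group is significant against everything at 0.01
  shift <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8) + 10)
  tk <- tukey_hsd(shift, alpha = 0.01)
  with_c <- tk$group_a == "c" | tk$group_b == "c"
  expect_true(all(tk$significant[with_c]))
  # adjusted p never undercuts the unadjusted pooled-variance pairwise
  # (LSD) p computed from the same ANOVA mean square
  for (i in 1:10) {
    vals <- random_group_fixture(k = 4, seed = 200 + i)
    tk <- tukey_hsd(vals)
    n <- length(unlist(vals)); k <- length(vals)
    mse <- sum(vapply(vals, function(v) sum((v - mean(v))^2), 0)) / (n - k)
    for (j in seq_len(nrow(tk))) {
      va <- vals[[tk$group_a[j]]]; vb <- vals[[tk$group_b[j]]]
      se <- sqrt(mse * (1 / length(va) + 1 / length(vb)))
      praw <- 2 * pt(-abs(mean(va) - mean(vb)) / se, n - k)
      expect_gte(tk$p_adj[j] + 1e-12, praw)
    }
  }
})

test_that("Pearson correlation handles exact and null relationships", {
  x <- c(1, 2, 3, 4, 5, 6.5, 8)
  expect_equal(pearson_compartments(x, x)$r, 1)
  expect_equal(pearson_compartments(x, -x)$r, -1)
  set.seed(12)
  base <- rnorm(40)
  rs <- replicate(1000, pearson_compartments(base, sample(base))$r)
  expect_lt(abs(mean(rs)), 0.02)
  expect_error(pearson_compartments(1:2, 1:2), "at least 3")
})

test_that("hierarchical averaging never pools across levels", {
  tab <- cohort_table(
    image_id = c("i1", "i2", "i3", "i4", "i5"),
    patient_id = c("p1", "p1", "p2", "p3", "p3"),
    group = c("BNH", "BNH", "BNH", "AAH", "AAH"),
    metric = "m",
    value = c(1.0, 1.2, 2.0, 3.0, 5.0))
  pat <- aggregate_cohort(tab, "patient")
  expect_equal(sort(pat$value), c(1.1, 2.0, 4.0))
  expect_equal(length(unique(pat$patient_id)), 3)  # count conservation
  grp <- aggregate_cohort(tab, "group")
  # group mean = mean of patient means, not of pooled images
  expect_equal(grp$value[grp$group == "BNH"], mean(c(1.1, 2.0)))
  expect_false(isTRUE(all.equal(grp$value[grp$group == "BNH"],
                                mean(c(1.0, 1.2, 2.0)))))
  # identity at image level; single image per patient is a no-op mean
  expect_identical(aggregate_cohort(tab, "image"), tab)
  expect_equal(pat$value[pat$patient_id == "p2"], 2.0)
})

test_that("cohort tables reject duplicates and unknown labels", {
  expect_error(cohort_table("i1", "p1", "XX", "m", 1), "XX")
  expect_error(cohort_table(c("i1", "i1"), c("p1", "p1"), c("BNH", "BNH"),
                            c("m", "m"), c(1, 2)), "duplicate")
})

test_that("interval narrowing is an inclusive pure subset filter", {
  vals <- list(a = c(1.00, 1.05, 1.06, 1.08, 1.09, 1.20),
               b = c(1.02, 1.05, 1.07, 1.09, 1.15, 1.30))
  res <- fd_frequency_analysis(vals, narrow = c(1.05, 1.09))
  # endpoints inclusive: {1.05, 1.06, 1.08, 1.09} from group a
  expect_equal(res$full_anova$df_within, 10)
  expect_equal(res$narrow_anova$df_within, 5)   # 4 + 3 values kept
  expect_equal(res$narrow_interval, c(1.05, 1.09))
  # histograms count everything
  expect_equal(sum(res$histograms$a$counts), 6)
  # all values inside -> narrowed ANOVA equals the full one
  inside <- list(a = c(1.05, 1.06, 1.07), b = c(1.07, 1.08, 1.09))
  r2 <- fd_frequency_analysis(inside)
  expect_equal(r2$narrow_anova$f_stat, r2$full_anova$f_stat)
  # a group with nothing inside is dropped with a warning naming it
  mixed <- list(a = c(1.06, 1.07, 1.08), b = c(1.06, 1.08, 1.07),
                c = c(1.3, 1.4, 1.5))
  expect_warning(r3 <- fd_frequency_analysis(mixed), "c")
  expect_equal(r3$dropped_groups, "c")
  expect_equal(r3$narrow_anova$df_between, 1)
})
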