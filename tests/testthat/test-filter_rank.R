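test_that("hand-worked filter scores are reproduced exactly", {
  expect_equal(
    chi_square_scores(data.frame(x = c(1, 1, 3, 3)), c(0, 0, 1, 1))$score, 2
  )
  expect_equal(
    anova_f_scores(data.frame(x = c(1, 2, 3, 4)), c(0, 0, 1, 1))$score, 8
  )
  expect_equal(
    mutual_info_scores(data.frame(x = c(0, 0, 1, 1)), c(0, 0, 1, 1))$score,
    log(2)
  )
  expect_equal(
    mutual_info_scores(data.frame(x = c(0, 1, 0, 1)), c(0, 0, 1, 1))$score, 0
  )
})

test_that("degenerate features score as documented", {
  # constant feature, balanced classes: observed equals expected
  expect_equal(
    chi_square_scores(data.frame(x = rep(2, 4)), c(0, 0, 1, 1))$score, 0
  )
  # equal class means: no between-group variance
  expect_equal(
    anova_f_scores(data.frame(x = c(1, 3, 1, 3)), c(0, 0, 1, 1))$score, 0
  )
  # zero within-group variance with separated means: +Inf sentinel
  expect_warning(
    f <- anova_f_scores(data.frame(x = c(1, 1, 2, 2)), c(0, 0, 1, 1))$score,
    "Inf"
  )
  expect_identical(f, Inf)
  expect_warning(
    z <- chi_square_scores(data.frame(x = rep(0, 4)), c(0, 0, 1, 1))$score,
    "zero"
  )
  expect_equal(z, 0)
  expect_error(
    chi_square_scores(data.frame(x = c(-1, 1, 1, 1)), c(0, 0, 1, 1)),
    "nonnegative"
  )
})

test_that("all three scorers agree with brute-force oracles on random small tables", {
  set.seed(404)
  for (case in 1:100) {
    n <- sample(6:20, 1)
    p <- sample(1:5, 1)
    y <- c(0, 0, 1, 1, rbinom(n - 4, 1, 0.5)) # both classes guaranteed
    x_num <- as.data.frame(matrix(abs(rnorm(n * p)) + 0.1, n, p))
    x_nom <- as.data.frame(matrix(sample(0:2, n * p, TRUE), n, p))
    attr(x_nom, "kinds") <- setNames(rep("nominal", p), names(x_nom))

    chi <- chi_square_scores(x_num, y)$score
    f <- anova_f_scores(x_num, y)$score
    mi <- mutual_info_scores(x_nom, y)$score
    for (j in seq_len(p)) {
      expect_equal(chi[j], oracle_chi_square(x_num[[j]], y), tolerance = 1e-10)
      expect_equal(f[j], oracle_f_stat(x_num[[j]], y), tolerance = 1e-8)
      expect_equal(mi[j], max(oracle_discrete_mi(x_nom[[j]], y), 0),
                   tolerance = 1e-10)
    }
  }
})

test_that("numeric mutual information separates dependent from independent features", {
  set.seed(11)
  n <- 400
  y <- rbinom(n, 1, 0.5)
  strong <- rnorm(n, mean = 2 * y)
  noise <- rnorm(n)
  sc <- mutual_info_scores(data.frame(strong = strong, noise = noise), y)
  expect_gt(sc$score[sc$feature == "strong"], 0.2)
  expect_lt(sc$score[sc$feature == "noise"], 0.05)
  expect_true(all(sc$score >= 0))
})

test_that("rank aggregation sums scores and ranks by descending total", {
  chi <- make_scores(c("a", "b", "c"), "chi_square", c(1, 5, 2))
  mi <- make_scores(c("a", "b", "c"), "mutual_information", c(0.5, 0.1, 0.4))
  f <- make_scores(c("a", "b", "c"), "f_statistic", c(2, 1, 9))
  rt <- aggregate_ranks(chi, mi, f)
  expect_equal(rt$total, c(3.5, 6.1, 11.4))
  expect_equal(rt$overall_rank, c(3L, 2L, 1L))
  expect_equal(rt$chi_square_rank, c(3L, 1L, 2L))
  expect_equal(sort(rt$overall_rank), seq_len(nrow(rt)))
  # descending total along ascending overall rank
  expect_equal(order(rt$total, decreasing = TRUE), order(rt$overall_rank))

  single <- aggregate_ranks(
    make_scores("a", "chi_square", 0),
    make_scores("a", "mutual_information", 0),
    make_scores("a", "f_statistic", 0)
  )
  expect_equal(single$overall_rank, 1L)

  expect_error(
    aggregate_ranks(chi, mi, make_scores(c("a", "b"), "f_statistic", c(1, 2))),
    "identical feature set"
  )
})

test_that("the published reference score columns aggregate to the published totals and ranks", {
  cols <- reference_score_columns()
  rt <- aggregate_ranks(cols$chi, cols$mi, cols$f)
  ref <- cols$ref
  consistent <- ref$consistent
  expect_true(all(abs(rt$total - ref$published_total)[consistent] < 1e-3))
  # the two arithmetically inconsistent printed rows are the only rank moves
  expect_equal(rt$feature[rt$overall_rank == 1], "thalach")
  expect_equal(rt$feature[rt$overall_rank == 2], "oldpeak")
  agree <- rt$feature[consistent][
    order(rt$overall_rank[consistent])
  ]
  published_order <- ref$feature[consistent][
    order(ref$published_rank[consistent])
  ]
  expect_equal(agree, published_order)
})

test_that("top-k selection keeps exactly the k best overall ranks", {
  cols <- reference_score_columns()
  rt <- aggregate_ranks(cols$chi, cols$mi, cols$f)
  m1 <- select_top_k(rt, 1)
  expect_equal(names(m1)[m1 == 1], "thalach")
  m3 <- select_top_k(rt, 3)
  expect_equal(sum(m3), 3)
  expect_true(all(c("thalach", "oldpeak") %in% names(m3)[m3 == 1]))
  expect_equal(select_top_k(rt, nrow(rt)), setNames(rep(1L, 13), rt$feature))
  expect_error(select_top_k(rt, 0), "1\\.\\.13")
  expect_error(select_top_k(rt, 14), "1\\.\\.13")
})

test_that("filter_rank shifts negative features for the chi-square stage only", {
  set.seed(3)
  df <- data.frame(a = rnorm(50), b = abs(rnorm(50)))
  y <- rbinom(50, 1, 0.5)
  y[1:2] <- c(0, 1)
  rt <- filter_rank(df, y, seed = 9)
  expect_equal(nrow(rt), 2)
  expect_true(all(is.finite(rt$total)))
  expect_error(filter_rank(df, y, shift_nonnegative = FALSE), "nonnegative")
})
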