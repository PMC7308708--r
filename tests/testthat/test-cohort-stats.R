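test_that("percent change reproduces designed ration and body-mass arithmetic", {
  expect_equal(round(percent_change(24.48, 9.79), 1), -60)
  expect_equal(round(percent_change(90.0, 77.2), 1), -14.2)
  expect_equal(percent_change(5, 5), 0)
  expect_true(is.na(percent_change(0, 5)))
})

test_that("mean of individual changes equals change of means only for shared pre", {
  pre <- rep(10, 4)
  post <- c(8, 9, 11, 12)
  expect_equal(
    mean(percent_change(pre, post)),
    percent_change(mean(pre), mean(post))
  )
  # counterexample with heterogeneous pre values
  pre2 <- c(1, 100)
  post2 <- c(2, 100)
  expect_false(isTRUE(all.equal(
    mean(percent_change(pre2, post2)),
    percent_change(mean(pre2), mean(post2))
  )))
})

test_that("response table pairs conditions and summaries recompute from rows", {
  metrics <- tidyr::expand_grid(
    animal_id = c("F01", "F02", "F03", "M01", "M02", "M03"),
    condition = c("CTL", "CR"),
    variable = "bm"
  ) |>
    dplyr::mutate(
      sex = substr(animal_id, 1, 1),
      value = c(90, 80, 95, 82, 100, 85, 70, 62, 75, 66, 80, 70)
    )
  resp <- response_table(metrics)
  expect_equal(nrow(resp), 6)
  f1 <- dplyr::filter(resp, animal_id == "F01")
  expect_equal(f1$value_ctl, 90)
  expect_equal(f1$value_cr, 80)
  expect_equal(f1$v_pct, percent_change(90, 80))
  rep <- response_summary(resp)
  f_rows <- dplyr::filter(resp, sex == "F")
  expect_equal(rep$ctl_f_mean, mean(f_rows$value_ctl))
  expect_equal(rep$ctl_f_sd, sd(f_rows$value_ctl))
  expect_equal(rep$v_f_mean, mean(f_rows$v_pct))
  expect_true(rep$sig_cr_f %in% c("***", "**", "*", "°", "-"))
})

test_that("Dixon's Q flags gross outliers against the embedded table", {
  d1 <- dixon_q(c(1, 2, 3, 4, 100))
  expect_equal(d1$variant, "r10")
  expect_equal(d1$q, 96 / 99, tolerance = 1e-12)
  expect_equal(d1$q_crit, 0.710)
  expect_true(d1$outlier)
  expect_equal(d1$suspect, 100)

  d2 <- dixon_q(c(1, 2, 3, 4, 5))
  expect_equal(d2$q, 0.25)
  expect_false(d2$outlier)

  # constant sample: undefined Q, no outlier
  d3 <- dixon_q(rep(7, 5))
  expect_true(is.na(d3$q))
  expect_false(d3$outlier)

  # variant switches with sample size
  expect_equal(dixon_q(1:8)$variant, "r11")
  expect_equal(dixon_q(1:12)$variant, "r22")
  expect_error(dixon_q(1:2), "3 <= n")
  expect_error(dixon_q(1:14), "n <= 13")
})

test_that("exact signed-rank matches enumeration and closed-form cases", {
  # six uniformly positive differences: p = 2 / 2^6
  t1 <- exact_signed_rank(c(2, 3, 1, 4, 2, 5), rep(0, 6))
  expect_equal(t1$p.value, 2 / 64)
  # all-zero differences: degenerate p = 1
  t2 <- exact_signed_rank(rep(3, 5), rep(3, 5))
  expect_equal(t2$p.value, 1)
  expect_true(t2$degenerate)
  # bitmask-enumeration oracle, with and without ties
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(3:9, 1)
    d <- sample(-4:4, n, replace = TRUE)
    if (all(d == 0)) d[1] <- 1
    expect_equal(exact_signed_rank(d)$p.value, oracle_signed_rank_p(d))
  }
  # agreement with the distribution-free reference on untied data
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(5:9, 1)
    d <- rnorm(n)
    want <- wilcox.test(d, exact = TRUE)$p.value
    expect_equal(exact_signed_rank(d)$p.value, want, tolerance = 1e-12)
  }
})

test_that("exact rank-sum matches enumeration and closed-form cases", {
  # complete separation of 6 vs 6: p = 2 / choose(12, 6)
  t1 <- exact_rank_sum(1:6, 7:12)
  expect_equal(t1$p.value, 2 / 924)
  # identical groups: p = 1
  expect_equal(exact_rank_sum(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  # recursive-enumeration oracle, with ties
  set.seed(19)
  for (rep in 1:15) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    x <- sample(1:6, n1, replace = TRUE)
    y <- sample(1:6, n2, replace = TRUE)
    expect_equal(exact_rank_sum(x, y)$p.value, oracle_rank_sum_p(x, y))
  }
  # reference implementation on untied data
  set.seed(23)
  for (rep in 1:10) {
    x <- rnorm(5)
    y <- rnorm(6)
    want <- wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(exact_rank_sum(x, y)$p.value, want, tolerance = 1e-12)
  }
})

test_that("correlation network keeps signed strong edges and drops constants", {
  set.seed(29)
  x <- rnorm(12)
  df <- tibble::tibble(
    x = x, y = 2 * x + 1, z = -x, w = rnorm(12), k = rep(1, 12)
  )
  expect_message(edges <- correlation_network(df, threshold = 0.5), "constant")
  key <- paste(edges$var1, edges$var2)
  expect_true("x y" %in% key)
  expect_equal(edges$r[key == "x y"], 1, tolerance = 1e-12)
  expect_equal(edges$r[key == "x z"], -1, tolerance = 1e-12)
  expect_false(any(grepl("k", key)))
  # under independence at n = 12, the edge rate matches the analytic
  # null probability P(|r| >= 0.5) from the t distribution, and most
  # simulated pairs produce no edge
  set.seed(31)
  hits <- vapply(1:1000, function(i) {
    d <- tibble::tibble(a = rnorm(12), b = rnorm(12))
    nrow(correlation_network(d, threshold = 0.5))
  }, numeric(1))
  p_null <- 2 * pt(-0.5 * sqrt(10) / sqrt(1 - 0.25), df = 10)
  mc_se <- sqrt(p_null * (1 - p_null) / 1000)
  expect_lt(abs(mean(hits) - p_null), 4 * mc_se)
  expect_gte(mean(hits == 0), 0.85)
})

test_that("PCA explains, reconstructs and describes as advertised", {
  # two perfectly correlated variables: PC1 carries all retained variance
  d1 <- tibble::tibble(a = 1:10, b = 2 * (1:10) + 3)
  p1 <- pca_describe(d1)
  expect_equal(p1$pct_var[1], 100, tolerance = 1e-9)

  set.seed(37)
  m <- matrix(rnorm(200 * 4), ncol = 4, dimnames = list(NULL, letters[1:4]))
  p2 <- pca_describe(m)
  expect_true(all(abs(p2$pct_var - 25) < 5))
  expect_true(all(diff(p2$pct_var) <= 1e-12))
  expect_equal(sum(p2$pct_var), 100, tolerance = 1e-9)
  # loadings unit-norm, scores orthogonal
  expect_equal(colSums(p2$loadings^2), rep(1, 4), ignore_attr = TRUE)
  g <- crossprod(p2$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  # full reconstruction of the standardized matrix
  z <- scale(m)
  expect_equal(
    unname(p2$scores %*% t(p2$loadings)),
    unname(z),
    tolerance = 1e-8, ignore_attr = TRUE
  )

  # v-statistic is zero when a category mean equals the grand mean
  groups <- rep(c("g1", "g2"), each = 100)
  m3 <- rbind(m[1:100, ], m[1:100, ]) # identical halves
  p3 <- pca_describe(m3, groups = groups)
  expect_lt(max(abs(p3$cat_v$v)), 1e-9)

  # zero-variance column dropped with a notice; missing cells mean-imputed
  m4 <- cbind(m, const = 1)
  m4[3, 1] <- NA
  expect_message(p4 <- pca_describe(m4), "zero-variance")
  expect_false("const" %in% colnames(p4$loadings))
  expect_equal(sum(p4$imputed), 1)
})

test_that("tidiers and significance ladder behave", {
  set.seed(41)
  p <- pca_describe(matrix(rnorm(60), ncol = 3))
  td <- tidy(p)
  expect_true(all(c("variable", "component", "loading", "pct_var") %in% names(td)))
  gl <- glance(p)
  expect_equal(gl$n_vars, 3)
  tt <- tidy(exact_rank_sum(1:4, 5:8))
  expect_true(all(c("statistic", "p.value") %in% names(tt)))
  expect_equal(
    sig_ladder(c(0.0005, 0.005, 0.03, 0.07, 0.5)),
    c("***", "**", "*", "°", "-")
  )
})
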