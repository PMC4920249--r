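make_counted_peaks <- function(n, chrom = "chr1", gap = 1000, len = 200,
                               counts = NULL) {
  tibble::tibble(
    chrom = chrom, start = (seq_len(n) - 1) * gap,
    end = (seq_len(n) - 1) * gap + len,
    count = if (is.null(counts)) rep(100, n) else counts
  )
}

test_that("common_peaks pairs overlapping regions like the all-pairs oracle", {
  a <- make_counted_peaks(5)
  b_disjoint <- dplyr::mutate(make_counted_peaks(5), start = start + 500,
                              end = end + 500)
  expect_equal(nrow(common_peaks(a, b_disjoint)), 0)

  pairs_self <- common_peaks(a, a)
  expect_equal(nrow(pairs_self), 5)
  expect_true(all(pairs_self$m == 0))

  for (seed in 1:5) {
    set.seed(seed + 600)
    pa <- random_intervals(80, chroms = "chr1", max_pos = 4000)
    pb <- random_intervals(80, chroms = "chr1", max_pos = 4000)
    pa$count <- sample(10:500, 80, replace = TRUE)
    pb$count <- sample(10:500, 80, replace = TRUE)
    pairs <- common_peaks(pa, pb)
    expect_equal(nrow(pairs), sum(oracle_count_overlaps(pa, pb)))
    expect_equal(pairs$m, pairs$count_a - pairs$count_b)
    expect_equal(pairs$a, (pairs$count_a + pairs$count_b) / 2)
  }
})

test_that("fit_ma_model recovers exact linear relations", {
  a <- make_counted_peaks(50, counts = sample(50:300, 50, replace = TRUE))
  pairs_eq <- common_peaks(a, a)
  fit <- fit_ma_model(pairs_eq, method = "ols")
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$slope, 0, tolerance = 1e-12)

  b <- dplyr::mutate(a, count = count + 20)
  fit2 <- fit_ma_model(common_peaks(a, b), method = "ols")
  expect_equal(fit2$intercept, -20, tolerance = 1e-9)
  expect_equal(fit2$slope, 0, tolerance = 1e-12)
  # robust fit agrees on the exact relation
  fit2r <- fit_ma_model(common_peaks(a, b), method = "robust")
  expect_equal(fit2r$intercept, -20, tolerance = 1e-6)
})

test_that("ols estimates equal the closed-form normal equations", {
  pairs <- generate_ma_pairs(2000, beta0 = 20, beta1 = 0.1, seed = 7)
  fit <- fit_ma_model(pairs, method = "ols")
  sxx <- sum((pairs$a - mean(pairs$a))^2)
  sxy <- sum((pairs$a - mean(pairs$a)) * (pairs$m - mean(pairs$m)))
  b1 <- sxy / sxx
  b0 <- mean(pairs$m) - b1 * mean(pairs$a)
  expect_equal(fit$slope, b1, tolerance = 1e-9)
  expect_equal(fit$intercept, b0, tolerance = 1e-9)
})

test_that("fit errors are informative", {
  few <- tibble::tibble(m = 1:5, a = 1:5)
  expect_error(fit_ma_model(few), "insufficient common peaks")
  const_a <- tibble::tibble(m = rnorm(20), a = rep(100, 20))
  expect_error(fit_ma_model(const_a), "zero variance")
})

test_that("ma_normalize applies the model and floors at zero", {
  ident <- structure(
    list(intercept = 0, slope = 0, method = "ols", n_common = 10, sigma = 0),
    class = "ma_model"
  )
  b <- make_counted_peaks(5, counts = c(10, 50, 100, 200, 400))
  out <- ma_normalize(b, ident)
  expect_equal(out$adjusted_count, b$count)

  shift <- structure(
    list(intercept = -20, slope = 0, method = "ols", n_common = 10, sigma = 0),
    class = "ma_model"
  )
  one <- make_counted_peaks(1, counts = 100)
  expect_equal(ma_normalize(one, shift)$adjusted_count, 80)
  low <- make_counted_peaks(1, counts = 5)
  expect_equal(ma_normalize(low, shift)$adjusted_count, 0)
})

test_that("post-normalization refit centers the MA trend at zero", {
  pairs <- generate_ma_pairs(2000, beta0 = 20, beta1 = 0.1,
                             count_dispersion = 0.1, seed = 7)
  peaks_b <- make_counted_peaks(2000, counts = pairs$count_b)
  model <- fit_ma_model(pairs, method = "ols")
  adj <- ma_normalize(peaks_b, model,
                      dplyr::mutate(pairs, index_b = dplyr::row_number()))
  refit <- fit_ma_model(
    tibble::tibble(
      m = pairs$count_a - adj$adjusted_count,
      a = (pairs$count_a + adj$adjusted_count) / 2
    ),
    method = "ols"
  )
  expect_lt(abs(refit$slope), 0.01)
  expect_lt(abs(refit$intercept), 1)
})

test_that("self-normalization changes no count", {
  a <- make_counted_peaks(30, counts = sample(10:400, 30, replace = TRUE))
  res <- manorm(a, a, method = "robust")
  expect_equal(res$adjusted$adjusted_count, a$count)
})

test_that("planted bias is recovered within 3 standard errors (ols)", {
  misses <- 0
  for (seed in 1:100) {
    pairs <- generate_ma_pairs(2000, beta0 = 20, beta1 = 0.1, seed = seed)
    fit <- lm(m ~ a, data = pairs)
    se <- sqrt(diag(vcov(fit)))
    if (abs(coef(fit)[1] - 20) > 3 * se[1] ||
          abs(coef(fit)[2] - 0.1) > 3 * se[2]) {
      misses <- misses + 1
    }
  }
  # ~1% of intervals are expected to miss at 3 SE; allow a small margin
  expect_lte(misses, 10)
})

test_that("adjustment preserves count order among regions sharing a", {
  model <- structure(
    list(intercept = 7, slope = 0.3, method = "ols", n_common = 10, sigma = 1),
    class = "ma_model"
  )
  b <- make_counted_peaks(4, counts = c(30, 60, 90, 120))
  pairs <- tibble::tibble(index_b = 1:4, a = 100, m = 0)
  out <- ma_normalize(b, model, pairs)
  expect_equal(order(out$adjusted_count), order(b$count))
  expect_true(all(out$paired))
})

test_that("robust fit resists planted outliers better than plain ols", {
  dev_robust <- numeric(50)
  dev_ols <- numeric(50)
  for (seed in 1:50) {
    pairs <- generate_ma_pairs(500, beta0 = 10, beta1 = 0.05, seed = seed)
    clean <- fit_ma_model(pairs, method = "ols")
    contaminated <- pairs
    set.seed(seed)
    idx <- sample(nrow(pairs), 50) # 10% outliers
    contaminated$m[idx] <- contaminated$m[idx] + 800
    rob <- fit_ma_model(contaminated, method = "robust")
    ols <- fit_ma_model(contaminated, method = "ols")
    dev_robust[seed] <- abs(rob$intercept - clean$intercept) +
      100 * abs(rob$slope - clean$slope)
    dev_ols[seed] <- abs(ols$intercept - clean$intercept) +
      100 * abs(ols$slope - clean$slope)
  }
  expect_lt(median(dev_robust), median(dev_ols))
})

test_that("tidy and glance expose the fitted coefficients", {
  pairs <- generate_ma_pairs(200, seed = 2)
  fit <- fit_ma_model(pairs, method = "ols")
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "a"))
  expect_equal(td$estimate, c(fit$intercept, fit$slope))
  gl <- glance(fit)
  expect_equal(gl$n_common, 200)
  expect_equal(gl$method, "ols")
})
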