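test_that("QC flags pick out gross lane outliers and nothing else", {
  endo <- endo_matrix(rep(c(10, 20, 40), 21), 3, 21)
  x <- make_counts(endo)
  expect_false(any(qc_boxplot_stats(x)$flagged))   # identical lanes

  endo2 <- endo
  endo2[, 21] <- endo2[, 21] * 1e6
  qc <- qc_boxplot_stats(make_counts(endo2))
  expect_identical(qc$sample_id[qc$flagged], "s21")
  expect_equal(sum(qc$flagged), 1L)

  one <- make_counts(endo_matrix(c(5, 9), 2, 1))   # n = 1 lane: no flag possible
  qc1 <- qc_boxplot_stats(one)
  expect_equal(nrow(qc1), 1L)
  expect_false(qc1$flagged)
})

test_that("positive-control scaling matches the hand-computed definition", {
  # lane geometric means sqrt(50*200) = 100 and sqrt(200*800) = 400:
  # reference (100+400)/2 = 250, factors 2.5 and 0.625; endo 40 -> 100
  pos <- matrix(c(50, 200, 200, 800), nrow = 2,
                dimnames = list(c("POS_A", "POS_B"), c("s1", "s2")))
  endo <- endo_matrix(c(40, 10), 1, 2)
  x <- make_counts(endo, pos = pos)
  n <- positive_control_normalize(x)
  expect_equal(unname(n$scale_factors), c(2.5, 0.625))
  expect_equal(unname(n$values["miR-001", ]), c(100, 6.25))
  # post-scaling positive-control geometric means agree to 1e-9 relative
  g <- exp(colMeans(log(n$values[x$probe_class == "Positive", ])))
  expect_equal(g[[1]], g[[2]], tolerance = 1e-9)
})

test_that("identical lanes and single lanes get unit scale factors", {
  endo <- endo_matrix(rep(c(10, 30), 3), 2, 3)
  x <- make_counts(endo)
  n <- positive_control_normalize(x)
  expect_equal(unname(n$scale_factors), rep(1, 3))
  expect_equal(n$values, x$counts * 1.0)

  one <- make_counts(endo_matrix(c(3, 7), 2, 1))
  expect_equal(unname(positive_control_normalize(one)$scale_factors), 1)
})

test_that("positive-control scaling is idempotent", {
  withr::local_seed(7)
  for (i in 1:5) {
    endo <- endo_matrix(rpois(40, 80), 8, 5)
    pos <- matrix(rpois(15, 600) + 1, nrow = 3,
                  dimnames = list(c("POS_A", "POS_B", "POS_C"), colnames(endo)))
    x <- make_counts(endo, pos = pos)
    n1 <- positive_control_normalize(x)
    # re-wrap the scaled values and scale again: factors must all be ~1
    pos2 <- structure(list(counts = n1$values, probe_class = x$probe_class),
                      class = "ncounter_counts")
    n2 <- positive_control_normalize(pos2)
    expect_equal(unname(n2$scale_factors), rep(1, 5), tolerance = 1e-9)
    expect_equal(n2$values, n1$values, tolerance = 1e-9)
  }
})

test_that("a zero positive-control count is a hard error", {
  pos <- matrix(c(0, 100, 50, 100), nrow = 2,
                dimnames = list(c("POS_A", "POS_B"), c("s1", "s2")))
  x <- make_counts(endo_matrix(c(1, 2), 1, 2), pos = pos)
  expect_error(positive_control_normalize(x), "POS_A.*s1")
})

test_that("background thresholds reproduce mean + k*SD on hand fixtures", {
  neg <- matrix(c(10, 20, 30, 5, 5, 5), nrow = 3,
                dimnames = list(c("NEG_01", "NEG_02", "NEG_03"), c("s01", "s02")))
  x <- make_counts(endo_matrix(c(1, 1), 1, 2), neg = neg)
  bg <- compute_background(x, k = 2)
  expect_equal(unname(bg$threshold["s01"]), 40)   # mean 20, sample SD 10
  expect_equal(unname(bg$threshold["s02"]), 5)    # all equal: SD 0
  expect_equal(unname(compute_background(x, k = 0)$threshold),
               unname(bg$mean))
  pooled <- compute_background(x, k = 2, pooled = TRUE)
  expect_equal(length(unique(pooled$threshold)), 1L)
  expect_equal(unname(pooled$threshold["s01"]),
               mean(neg) + 2 * stats::sd(neg))
})

test_that("background needs at least two negative probes", {
  neg <- matrix(5, 1, 2, dimnames = list("NEG_01", c("s01", "s02")))
  x <- make_counts(endo_matrix(c(1, 1), 1, 2), neg = neg)
  expect_error(compute_background(x), "at least 2 Negative")
})

test_that("the prevalence filter is strictly 'more than'", {
  # 10 samples, thresholds all 40 (negatives 20/40/60 -> mean 40, sd 20... use equal)
  neg <- matrix(40, 2, 10, dimnames = list(c("NEG_01", "NEG_02"),
                                           sprintf("s%02d", 1:10)))
  # probe A below 40 in exactly 9/10 samples: retained (0.9 is not > 0.9)
  # probe B below 40 in 10/10: dropped
  endo <- rbind(`miR-A` = c(rep(10, 9), 50),
                `miR-B` = rep(10, 10))
  colnames(endo) <- sprintf("s%02d", 1:10)
  x <- make_counts(endo, neg = neg)
  n <- positive_control_normalize(x)   # default controls: unit factors
  bg <- compute_background(n)
  filt <- filter_low_expressed(n, bg, frac = 0.90)
  expect_identical(rownames(filt$values), "miR-A")
  expect_identical(attr(filt, "dropped"), "miR-B")

  # frac = 0: any probe below threshold in >= 1 sample is dropped
  filt0 <- filter_low_expressed(n, bg, frac = 0)
  expect_equal(nrow(filt0$values), 0L)
  expect_error(filter_low_expressed(n, bg, frac = 1.2), "\\[0, 1\\]")
})

test_that("the filter drops control probes from the analysis set and is monotone in frac", {
  withr::local_seed(31)
  endo <- endo_matrix(rpois(60, 30), 6, 10)
  x <- make_counts(endo)
  n <- positive_control_normalize(x)
  bg <- compute_background(n)
  fracs <- c(0, 0.3, 0.6, 0.9)
  dropped <- lapply(fracs, function(fr)
    attr(filter_low_expressed(n, bg, frac = fr), "dropped"))
  for (i in seq_along(fracs)[-1])
    expect_true(all(dropped[[i]] %in% dropped[[i - 1]]))   # larger frac drops less
  filt <- filter_low_expressed(n, bg, frac = 0.9)
  expect_true(all(filt$probe_class == "Endogenous"))
})

test_that("quantile normalization matches hand computation and is a fixed point", {
  # columns (1,3) and (2,6): rank means (1.5, 4.5)
  m <- matrix(c(1, 3, 2, 6), nrow = 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn), matrix(c(1.5, 4.5, 1.5, 4.5), 2))
  expect_equal(quantile_normalize(qn), qn)   # fixed point on identical columns

  expect_error(quantile_normalize(m[, 1, drop = FALSE]), "at least 2 samples")
})

test_that("quantile normalization ties match the brute-force rank-assignment oracle", {
  withr::local_seed(99)
  for (i in 1:15) {
    np <- sample(3:6, 1); ns <- sample(2:4, 1)
    m <- matrix(sample(1:4, np * ns, replace = TRUE), np, ns,
                dimnames = list(sprintf("p%d", 1:np), sprintf("s%d", 1:ns)))
    expect_equal(quantile_normalize(m), bf_quantile_normalize(m),
                 tolerance = 1e-12)
  }
})

test_that("quantile normalization equalizes column multisets and preserves ranks", {
  withr::local_seed(12)
  m <- matrix(rnorm(200), 40, 5,
              dimnames = list(sprintf("p%d", 1:40), sprintf("s%d", 1:5)))
  qn <- quantile_normalize(m)
  sorted <- apply(qn, 2, sort)
  for (j in 2:5) expect_equal(sorted[, j], sorted[, 1], tolerance = 1e-12)
  for (j in 1:5) expect_identical(order(qn[, j]), order(m[, j]))   # tie-free
})

test_that("tie-free quantile normalization agrees with limma", {
  skip_if_not_installed("limma")
  withr::local_seed(5)
  m <- matrix(rexp(120), 30, 4)
  expect_equal(unname(quantile_normalize(m)),
               unname(limma::normalizeQuantiles(m)), tolerance = 1e-12)
})

test_that("the pipeline applies stages in the fixed order", {
  sim <- simulate_ncounter(sim_config(n_endogenous = 60,
                                      group_sizes = c(OS = 8, Ob = 3), seed = 6))
  fit <- suppressWarnings(ncounter_de(sim$counts, sim$metadata, c("OS", "Ob")))
  expect_identical(fit$norm$stage, "quantile_normalized")
  # the normalized matrix contains only retained endogenous probes
  expect_true(all(grepl("^miR-", rownames(fit$norm$values))))
  expect_equal(nrow(fit$norm$values) + length(fit$dropped), 60)
})
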