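test_that("the expected-false-positive cutoff is 1/m", {
  expect_equal(round(expected_fp_cutoff(519), 4), 0.0019)
  expect_equal(expected_fp_cutoff(1), 1)
  expect_equal(expected_fp_cutoff(4), 0.25)
  expect_error(expected_fp_cutoff(0), "positive integer")
})

test_that("regression p-values equal the closed-form pooled t-test", {
  # 6+6 fixture, reference p computed by the closed-form t formula
  a <- c(5.1, 4.8, 5.5, 5.0, 4.9, 5.3)
  b <- c(4.1, 4.4, 3.9, 4.2, 4.6, 4.0)
  m <- endo_matrix(0, 1, 12)
  m[1, ] <- c(a, b)
  md <- two_group_metadata(6, 6)
  tab <- fit_linear_de(m, md, c("OS", "Ob"), scale = "linear")
  expect_equal(tab$p_value, pooled_t_p(a, b), tolerance = 1e-12)
  expect_equal(tab$slope, mean(a) - mean(b), tolerance = 1e-12)
})

test_that("two-group regression, pooled t-test, ANOVA and lm agree on random fixtures", {
  withr::local_seed(202)
  for (i in 1:20) {
    nA <- sample(2:8, 1); nB <- sample(2:8, 1)
    m <- endo_matrix(rnorm(5 * (nA + nB), 8, 2), 5, nA + nB)
    md <- two_group_metadata(nA, nB)
    tab <- fit_linear_de(m, md, c("OS", "Ob"), scale = "linear")
    tab <- tab[match(rownames(m), tab$probe_id), ]
    g <- factor(md$group, levels = c("Ob", "OS"))
    for (p in seq_len(5)) {
      y <- m[p, ]
      tt <- stats::t.test(y[g == "OS"], y[g == "Ob"], var.equal = TRUE)
      av <- stats::anova(stats::aov(y ~ g))
      fit <- summary(stats::lm(y ~ g))
      rel <- function(x, ref) abs(x - ref) / ref
      expect_lt(rel(tab$p_value[p], tt$p.value), 1e-10)
      expect_lt(rel(tab$p_value[p], av$`Pr(>F)`[1]), 1e-10)
      expect_lt(rel(tab$t[p]^2, av$`F value`[1]), 1e-10)          # F = t^2
      expect_lt(rel(tab$p_value[p], fit$coefficients[2, 4]), 1e-10)
    }
  }
})

test_that("a constant miRNA is flat with p = 1; separated degenerates get p = 0", {
  m <- endo_matrix(0, 2, 6)
  m[1, ] <- 7                      # constant everywhere
  m[2, ] <- c(1, 1, 1, 2, 2, 2)    # zero residual variance, means differ
  md <- two_group_metadata(3, 3)
  expect_warning(tab <- fit_linear_de(m, md, c("OS", "Ob"), scale = "linear"),
                 "zero residual variance")
  r1 <- tab[tab$probe_id == "miR-001", ]
  expect_equal(r1$p_value, 1)
  expect_identical(r1$direction, "flat")
  expect_equal(r1$fold_change, 1)
  r2 <- tab[tab$probe_id == "miR-002", ]
  expect_equal(r2$p_value, 0)
})

test_that("swapping the contrast negates fold changes and keeps p-values", {
  withr::local_seed(7)
  m <- endo_matrix(2^rnorm(40, 6, 1), 8, 5)
  md <- two_group_metadata(3, 2)
  t1 <- fit_linear_de(m, md, c("OS", "Ob"))
  t2 <- fit_linear_de(m, md, c("Ob", "OS"))
  t2 <- t2[match(t1$probe_id, t2$probe_id), ]
  expect_equal(t1$fold_change, -t2$fold_change, tolerance = 1e-12)
  expect_equal(t1$p_value, t2$p_value, tolerance = 1e-12)
  expect_equal(t1$slope, -t2$slope, tolerance = 1e-12)
})

test_that("permuting sample columns changes nothing", {
  withr::local_seed(8)
  m <- endo_matrix(rpois(60, 40), 10, 6)
  md <- two_group_metadata(4, 2)
  t1 <- fit_linear_de(m, md, c("OS", "Ob"))
  perm <- c(3, 6, 1, 5, 2, 4)
  t2 <- fit_linear_de(m[, perm], md[perm, ], c("OS", "Ob"))
  expect_equal(t1, t2, tolerance = 1e-12)
})

test_that("tiny control groups (n = 2 and n = 3) are handled, n = 1 is not", {
  withr::local_seed(9)
  m <- endo_matrix(rpois(300, 100), 10, 30)
  for (nB in 2:3) {
    md <- two_group_metadata(30 - nB, nB)
    tab <- fit_linear_de(m[, seq_len(30)], md, c("OS", "Ob"))
    expect_equal(nrow(tab), 10)
    expect_true(all(is.finite(tab$p_value)))
  }
  md1 <- two_group_metadata(29, 1)
  expect_error(fit_linear_de(m, md1, c("OS", "Ob")), "fewer than 2 samples")
})

test_that("signed fold changes follow the magnitude >= 1 convention", {
  # group geometric means 8 vs 2 -> +4; swapped -> -4
  m <- endo_matrix(0, 1, 4)
  m[1, ] <- c(8, 8, 2, 2)
  md <- two_group_metadata(2, 2)
  fc <- fold_change(m, md, c("OS", "Ob"))
  # fold changes are ratios of geometric-style means on log2(v+1):
  # (8+1)/(2+1) = 3
  expect_equal(unname(fc), 3)
  expect_equal(unname(fold_change(m, md, c("Ob", "OS"))), -3)

  # equal means: fold change exactly +1 (flat)
  m[1, ] <- 5
  expect_equal(unname(fold_change(m, md, c("OS", "Ob"))), 1)

  # a 3.2 log2 difference is a 9.19-fold change
  f <- ncounterDE:::fold_change_from_log2
  expect_equal(f(3.2), 2^3.2, tolerance = 1e-12)
  expect_equal(round(2^3.2, 1), 9.2)
  expect_equal(f(-3.2), -2^3.2, tolerance = 1e-12)
})

test_that("null p-values are uniform (KS check per seed)", {
  for (s in 1:5) {
    sim <- simulate_ncounter(sim_config(n_endogenous = 519, de_fraction = 0,
                                        absent_fraction = 0, seed = s))
    fit <- suppressWarnings(ncounter_de(sim$counts, sim$metadata, c("OS", "Ob")))
    ks <- suppressWarnings(stats::ks.test(fit$table$p_value, "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("signatures partition significant calls by direction", {
  tab <- structure(
    data.frame(probe_id = sprintf("miR-%d", 1:8),
               p_value = c(1e-5, 1e-4, 2e-4, 3e-4, 5e-4, 0.3, 0.5, 0.9),
               fold_change = c(4, -2, 8, -3, 1.5, -9, 2, 1),
               direction = c("up", "down", "up", "down", "up", "down", "up", "flat"),
               significant = c(rep(TRUE, 5), rep(FALSE, 3)),
               stringsAsFactors = FALSE),
    class = c("de_table", "data.frame"))
  sig <- build_signature(tab)
  expect_equal(c(sig$n_up, sig$n_down, sig$n_total), c(3, 2, 5))
  expect_identical(sig$up$probe_id[1], "miR-3")      # sorted by |fc| desc
  expect_equal(sig$n_total, sig$n_up + sig$n_down)

  none <- tab; none$significant <- FALSE
  sig0 <- build_signature(none)
  expect_equal(c(sig0$n_up, sig0$n_down, sig0$n_total), c(0, 0, 0))
})
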