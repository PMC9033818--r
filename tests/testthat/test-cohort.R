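# Cohort statistics: proportions, deltas, chi-square, Kruskal-Wallis.

scored_fixture <- function() {
  # 3 patients, 100/200/100 cells; fractions chosen by construction
  make <- function(pid, n, n_low) {
    z <- rep(0, n)
    z[seq_len(n_low)] <- -4
    data.frame(cell_id = sprintf("%s_c%03d", pid, seq_len(n)),
               patient_id = pid, group = "g1", roi_id = paste0(pid, "_R1"),
               area_px = 100L, z_ndufb8 = z, z_mtco1 = 0, z_tomm20 = 0)
  }
  classify_cells(rbind(make("P1", 100, 25), make("P2", 200, 50),
                       make("P3", 100, 10)))
}

test_that("category percentages are exact and sum to 100", {
  z <- scored_fixture()
  s <- category_proportions(z, "patient_id")
  p1_low <- s[s$patient_id == "P1" & s$marker == "ndufb8" &
                s$category == "low", ]
  expect_equal(p1_low$percentage, 25.0)
  expect_equal(p1_low$count, 25L)
  sums <- tapply(s$percentage,
                 interaction(s$patient_id, s$marker), sum)
  expect_equal(unname(as.numeric(sums)), rep(100, length(sums)),
               tolerance = 1e-9)
  counts <- tapply(s$count, interaction(s$patient_id, s$marker), sum)
  expect_true(all(counts == s$n_cells[match(names(counts),
    interaction(s$patient_id, s$marker))]))
})

test_that("pooled group percentage is the cell-weighted patient mean", {
  z <- scored_fixture()
  by_pat <- category_proportions(z, "patient_id")
  pooled <- category_proportions(z, "group")
  lowp <- by_pat[by_pat$marker == "ndufb8" & by_pat$category == "low", ]
  weighted <- sum(lowp$percentage * lowp$n_cells) / sum(lowp$n_cells)
  got <- pooled$percentage[pooled$marker == "ndufb8" &
                             pooled$category == "low"]
  expect_equal(got, weighted, tolerance = 1e-12)
  expect_equal(got, 100 * 85 / 400, tolerance = 1e-12)
})

test_that("every classified cell lands in exactly one category count", {
  z <- scored_fixture()
  s <- category_proportions(z, "group")
  for (m in unique(s$marker))
    expect_equal(sum(s$count[s$marker == m]), nrow(z))
})

test_that("proportion deltas reproduce printed worked examples", {
  expect_equal(proportion_delta(4.52, 1.38), 3.14)
  expect_equal(proportion_delta(15.68, 0.61), 15.07)
  expect_equal(proportion_delta(7.3, 7.3), 0.00)
  expect_error(proportion_delta(101, 5), "0, 100")
  expect_error(proportion_delta(50, -1), "0, 100")
})

test_that("chi-square matches hand-evaluated and closed-form values", {
  flat <- chisq_proportions(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$chi2_stat, 0)
  expect_equal(flat$p_value, 1)
  skewed <- chisq_proportions(matrix(c(20, 5, 5, 20), 2))
  expect_equal(skewed$chi2_stat, 18.0, tolerance = 1e-12)
  expect_error(chisq_proportions(matrix(c(0, 5, 0, 5), 2)),
               "zero marginal")
  # closed form N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d)) on random 2x2 tables
  set.seed(21)
  for (i in 1:20) {
    t2 <- matrix(rpois(4, 30) + 1, 2)
    a <- t2[1, 1]; b <- t2[1, 2]; c_ <- t2[2, 1]; d <- t2[2, 2]
    closed <- sum(t2) * (a * d - b * c_)^2 /
      ((a + b) * (c_ + d) * (a + c_) * (b + d))
    expect_equal(chisq_proportions(t2)$chi2_stat, closed,
                 tolerance = 1e-9)
  }
  expect_true(chisq_proportions(matrix(c(3, 50, 2, 60), 2))$low_expected)
})

test_that("kruskal-wallis matches hand evaluation and the reference", {
  same <- kruskal_wallis(list(a = c(2, 2), b = c(2, 2, 2)))
  expect_equal(same$chi2_stat, 0)
  hand <- kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(hand$chi2_stat, 27 / 7, tolerance = 1e-12)
  expect_error(kruskal_wallis(list(a = 1:3)), "two")
  # with ties, against the independent reference implementation
  set.seed(31)
  for (i in 1:10) {
    vals <- lapply(1:3, function(k) sample(1:6, 8, replace = TRUE))
    names(vals) <- c("a", "b", "c")
    ref <- stats::kruskal.test(unlist(vals),
                               rep(1:3, each = 8))
    got <- kruskal_wallis(vals)
    expect_equal(got$chi2_stat, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("compare_proportions builds the right 2x2 contrast", {
  make <- function(g, n, n_def) {
    z <- rep(0, n)
    z[seq_len(n_def)] <- -4
    data.frame(cell_id = paste0(g, seq_len(n)), group = g,
               z_ndufb8 = z, z_mtco1 = 0, z_tomm20 = 0)
  }
  z <- classify_cells(rbind(make("A", 100, 20), make("B", 100, 5)))
  res <- compare_proportions(z, "ndufb8", "deficient", "A", "B")
  expect_equal(res$p_a, 20)
  expect_equal(res$p_b, 5)
  expect_equal(res$delta_pp, 15)
  expect_equal(res$chi2_stat,
               chisq_proportions(rbind(c(20, 80), c(5, 95)))$chi2_stat)
})

test_that("chi-square type-I error is calibrated under the null", {
  # both groups drawn from the control model; the count of high-TOMM20
  # cells (z > 2) among n control cells is Binomial(n, pnorm(-2)) by
  # construction, which is what we draw directly
  set.seed(1234)
  n_rep <- 2000L
  n <- 2000L
  p <- pnorm(-2)
  rejections <- 0L
  for (i in seq_len(n_rep)) {
    a <- rbinom(1, n, p)
    b <- rbinom(1, n, p)
    if (a + b == 0 || a + b == 2 * n) next
    res <- chisq_proportions(rbind(c(a, n - a), c(b, n - b)))
    if (res$p_value < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_rep
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("roi_mean_z averages epithelial cells per ROI", {
  z <- scored_fixture()
  z$tissue_class <- "epithelial"
  rm_ <- roi_mean_z(z, extra_cols = "group")
  expect_equal(nrow(rm_), 3L)
  p1 <- rm_[rm_$roi_id == "P1_R1", ]
  expect_equal(p1$mean_z_ndufb8, mean(c(rep(-4, 25), rep(0, 75))))
  expect_equal(p1$n_cells, 100L)
})
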