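# independent brute-force oracles -------------------------------------------

# two-sided permutation p for the Mann-Whitney U statistic (no ties assumed)
perm_mw_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  r <- rank(pooled)
  mu <- na * length(b) / 2
  obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  idx <- utils::combn(length(pooled), na)
  us <- apply(idx, 2, function(ii) sum(r[ii]) - na * (na + 1) / 2)
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# naive filter + selection sort for fold-change enrichment
naive_enrich <- function(tab, thr, floor_) {
  res <- data.frame(gene = character(0), fold_change = numeric(0))
  for (i in seq_len(nrow(tab))) {
    f <- tab$abundance_oc[i] / max(tab$abundance_nd[i], floor_)
    if (f > thr) res <- rbind(res, data.frame(gene = tab$gene[i],
                                              fold_change = f))
  }
  out <- res[0, ]
  while (nrow(res) > 0) {
    best <- which(res$fold_change == max(res$fold_change))
    best <- best[order(res$gene[best])][1]
    out <- rbind(out, res[best, ])
    res <- res[-best, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

test_that("fold-change filter keeps strict exceedances, ranked", {
  tab <- data.frame(gene = c("TRPV4", "SCN11A", "KCNN4", "TFRC", "EDGE"),
                    abundance_nd = c(1, 1, 1, 10, 2),
                    abundance_oc = c(153, 42, 6, 11, 10))
  res <- fold_change_filter(tab, threshold = 5)
  expect_identical(res$gene, c("TRPV4", "SCN11A", "KCNN4"))
  expect_equal(res$fold_change[res$gene == "TRPV4"], 153)
  expect_identical(res$rank, 1:3)
  # fold exactly at the threshold is excluded (strict >)
  expect_false("EDGE" %in% res$gene)
  # zero control abundance falls back to the pseudo-floor, not Inf
  tab2 <- rbind(tab, data.frame(gene = "NEW", abundance_nd = 0,
                                abundance_oc = 100))
  res2 <- fold_change_filter(tab2, threshold = 5)
  expect_equal(res2$fold_change[res2$gene == "NEW"], 100)
  expect_error(fold_change_filter(tab[0, ]), "empty")
  expect_error(fold_change_filter(transform(tab, gene = "x")), "unique")
})

test_that("fold-change filter agrees with a brute-force oracle", {
  withr::with_seed(42, {
    tab <- data.frame(gene = paste0("G", sample(100:999, 100)),
                      abundance_nd = round(runif(100, 0, 20), 2),
                      abundance_oc = round(runif(100, 0, 200), 2))
  })
  floor_ <- min(tab$abundance_nd[tab$abundance_nd > 0])
  res <- fold_change_filter(tab, threshold = 3)
  ref <- naive_enrich(tab, 3, floor_)
  expect_identical(res$gene, ref$gene)
  expect_equal(res$fold_change, ref$fold_change)
  # invariance to a common positive rescaling of both columns
  res2 <- fold_change_filter(transform(tab, abundance_nd = abundance_nd * 7,
                                       abundance_oc = abundance_oc * 7),
                             threshold = 3)
  expect_identical(res2$gene, res$gene)
  expect_equal(res2$fold_change, res$fold_change)
})

test_that("diagnostic concordance reproduces the printed operating point", {
  tab <- data.frame(
    roi_id = 1:87,
    grade = c(rep("DCIS_high", 20),
              rep(c("normal", "benign", "ADH", "DCIS_low",
                    "DCIS_intermediate"), length.out = 62),
              rep("IDC", 5)),
    call = c(rep("Y", 15), rep("N", 5), rep("N", 61), "Y", rep("Y", 5)),
    stringsAsFactors = FALSE
  )
  res <- diagnostic_concordance(tab)
  expect_equal(res$sensitivity, 0.75)
  expect_equal(res$specificity, 61 / 62)
  expect_equal(res$n_pos_used, 20)
  expect_equal(res$n_neg_used, 62)  # IDC excluded
  expect_equal(round(res$ci_half_width_sens, 2), 0.19)
  expect_equal(round(res$ci_half_width_spec, 2), 0.03)
  # row order cannot matter
  shuf <- tab[sample(nrow(tab)), ]
  res2 <- diagnostic_concordance(shuf)
  expect_equal(res2$sensitivity, res$sensitivity)
  expect_equal(res2$specificity, res$specificity)
})

test_that("equivocal handling and degenerate tables behave as documented", {
  tab <- data.frame(roi_id = 1:6,
                    grade = c(rep("DCIS_high", 3), rep("benign", 3)),
                    call = c("Y", "E", "N", "N", "E", "N"))
  ex <- diagnostic_concordance(tab)                      # E dropped
  expect_equal(ex$sensitivity, 0.5)
  expect_equal(ex$n_pos_used, 2)
  an <- diagnostic_concordance(tab, equivocal = "as_negative")
  expect_equal(an$sensitivity, 1 / 3)
  expect_equal(an$specificity, 1)
  perfect <- data.frame(roi_id = 1:4,
                        grade = c("DCIS_high", "DCIS_high", "ADH", "normal"),
                        call = c("Y", "Y", "N", "N"))
  pr <- diagnostic_concordance(perfect)
  expect_equal(pr$sensitivity, 1)
  expect_equal(pr$ci_half_width_sens, 0)
  expect_error(diagnostic_concordance(perfect[1:2, ]), "usable|negative")
})

test_that("the concordance estimator is unbiased at a set operating point", {
  est <- vapply(1:150, function(s) {
    g <- gen_concordance_table(20, 62, 0.75, 61 / 62, seed = s)
    r <- diagnostic_concordance(g$table)
    c(r$sensitivity, r$specificity)
  }, numeric(2))
  expect_lt(abs(mean(est[1, ]) - 0.75), 0.025)
  expect_lt(abs(mean(est[2, ]) - 61 / 62), 0.01)
})

test_that("Wald half-widths reproduce the printed confidence intervals", {
  expect_equal(round(wald_ci_half_width(15 / 20, 20), 2), 0.19)
  expect_equal(round(wald_ci_half_width(61 / 62, 62), 2), 0.03)
  expect_equal(wald_ci_half_width(1, 37), 0)
  expect_error(wald_ci_half_width(1.2, 10))
})

test_that("Mann-Whitney U matches enumeration and handles ties", {
  ident <- mann_whitney_u(1:6, 1:6)
  expect_equal(ident$u, 18)  # n_a n_b / 2
  expect_gt(ident$p_value, 0.9)
  sep <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$p_value, 0.1)
  expect_identical(sep$method, "exact")
  big <- mann_whitney_u(rnorm(30), rnorm(30))  # 900 > 400 -> approximation
  expect_identical(big$method, "normal_approx")
  tied <- mann_whitney_u(c(1, 2, 2), c(2, 3, 4))
  expect_identical(tied$method, "normal_approx")
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty")
})

test_that("exact p equals brute-force permutation p on random instances", {
  withr::with_seed(99, {
    for (i in 1:100) {
      na <- sample(2:6, 1)
      nb <- sample(2:6, 1)
      x <- sample(seq_len(50), na + nb)  # distinct values: no ties
      a <- x[seq_len(na)]
      b <- x[-seq_len(na)]
      res <- mann_whitney_u(a, b)
      expect_identical(res$method, "exact")
      expect_equal(res$p_value, perm_mw_p(a, b), tolerance = 1e-12)
    }
  })
})

test_that("scaling relation matches the closed-form normal equations", {
  expect_equal(scaling_relation(1:5, 2 * (1:5) + 3)$r_squared, 1)
  withr::with_seed(5, {
    x <- rnorm(20)
    y <- 1.3 * x + rnorm(20)
  })
  fit <- scaling_relation(x, y)
  slope_ref <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  int_ref <- mean(y) - slope_ref * mean(x)
  r2_ref <- 1 - sum((y - int_ref - slope_ref * x)^2) /
    sum((y - mean(y))^2)
  expect_equal(fit$slope, slope_ref, tolerance = 1e-10)
  expect_equal(fit$intercept, int_ref, tolerance = 1e-10)
  expect_equal(fit$r_squared, r2_ref, tolerance = 1e-10)
  # R^2 invariant under affine maps of either axis; null case near zero
  fit2 <- scaling_relation(3 * x - 1, -2 * y + 5)
  expect_equal(fit2$r_squared, fit$r_squared, tolerance = 1e-10)
  withr::with_seed(6, {
    null_fit <- scaling_relation(rnorm(500), rnorm(500))
  })
  expect_lt(null_fit$r_squared, 0.05)
  expect_error(scaling_relation(rep(1, 5), 1:5), "constant")
  expect_error(scaling_relation(1:2, 1:2), "3 paired")
})

test_that("PEG dose converts linearly to osmolality", {
  expect_equal(peg_osmolality(2), 74.4)
  expect_equal(peg_osmolality(4), 148.8)
  expect_equal(peg_osmolality(0), 0)
  expect_error(peg_osmolality(-1), "non-negative")
})
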