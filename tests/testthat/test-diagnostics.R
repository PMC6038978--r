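test_that("group summaries follow the linear-interpolation convention", {
  gs <- group_summary(c(1, 2, 3, 4, 5))
  expect_equal(gs$median, 3); expect_equal(gs$q1, 2); expect_equal(gs$q3, 4)
  expect_equal(gs$variance, var(1:5))
  # shift equivariance
  set.seed(2)
  x <- rnorm(25)
  a <- group_summary(x); b <- group_summary(x + 10)
  expect_equal(b$median - a$median, 10)
  expect_equal(b$q1 - a$q1, 10); expect_equal(b$q3 - a$q3, 10)
  expect_equal(b$ci_median - a$ci_median, c(10, 10))
  expect_equal(b$variance, a$variance)
  expect_true(a$min <= a$q1 && a$q1 <= a$median &&
              a$median <= a$q3 && a$q3 <= a$max)
  expect_mibg_error(group_summary(3), "TooFewValues")
})

test_that("overlap interval follows the formal definition", {
  expect_equal(overlap_range(c(1, 2), c(1.5, 3)), c(1.5, 2))
  expect_length(overlap_range(c(1, 2), c(3, 4)), 0)
  expect_equal(overlap_range(c(1, 3), c(2, 4)), c(2, 3))
  expect_mibg_error(overlap_range(numeric(0), 1), "EmptyGroup")
})

test_that("empirical ROC AUC equals the pairwise probability", {
  expect_equal(empirical_roc(c(0.5, 0.7, 1.5, 1.7),
                             c("LBD", "LBD", "non-LBD", "non-LBD"))$auc, 1)
  expect_equal(empirical_roc(c(1, 3, 2, 4),
                             c("LBD", "LBD", "non-LBD", "non-LBD"))$auc,
               0.75)
  expect_equal(empirical_roc(rep(2, 6),
                             rep(c("LBD", "non-LBD"), 3))$auc, 0.5)
  expect_mibg_error(empirical_roc(1:3, rep("LBD", 3)), "OneClassOnly")
  # brute-force pair enumeration oracle on random instances
  set.seed(31)
  for (rep in 1:20) {
    n1 <- sample(2:15, 1); n2 <- sample(2:15, 1)
    s <- c(round(rnorm(n1), 1), round(rnorm(n2, 0.5), 1))
    lab <- c(rep("LBD", n1), rep("non-LBD", n2))
    brute <- 0
    for (i in which(lab == "LBD")) for (j in which(lab == "non-LBD"))
      brute <- brute + (s[j] > s[i]) + 0.5 * (s[j] == s[i])
    expect_equal(empirical_roc(s, lab)$auc, brute / (n1 * n2))
  }
})

test_that("empirical AUC agrees with the pROC reference implementation", {
  set.seed(77)
  s <- c(rnorm(20, 0), rnorm(25, 1.2))
  lab <- c(rep("LBD", 20), rep("non-LBD", 25))
  ours <- empirical_roc(s, lab)$auc
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = factor(lab, levels = c("LBD", "non-LBD")),
    predictor = s, direction = "<")))
  expect_equal(ours, as.numeric(ref))
})

test_that("Youden criterion maximizes J with the midpoint tie-break", {
  roc <- empirical_roc(c(1, 2, 3, 4),
                       c("LBD", "LBD", "non-LBD", "non-LBD"))
  yj <- youden_criterion(roc)
  expect_equal(yj$threshold, 2.5)
  expect_equal(yj$J, 1)
  same <- empirical_roc(rep(c(1, 2), 4),
                        rep(c("LBD", "LBD", "non-LBD", "non-LBD"), 2))
  expect_equal(youden_criterion(same)$J, 0)
  # exhaustive-scan property: no threshold beats the returned J
  set.seed(17)
  for (rep in 1:15) {
    s <- round(c(rnorm(8), rnorm(8, 1)), 1)
    lab <- rep(c("LBD", "non-LBD"), each = 8)
    yj <- youden_criterion(empirical_roc(s, lab))
    grid <- sort(unique(c(s - 0.05, s + 0.05)))
    best <- max(vapply(grid, function(t0) {
      mean(s[lab == "LBD"] < t0) + mean(s[lab != "LBD"] >= t0) - 1
    }, numeric(1)))
    expect_equal(yj$J, best)
  }
})

test_that("diagnostic metrics follow the 2x2 definitions", {
  lab <- c("LBD", "LBD", "non-LBD", "non-LBD")
  m <- diagnostic_metrics(c(0.5, 1.0, 1.5, 2.0), lab, 1.2)
  expect_equal(unlist(m[c("sensitivity", "specificity", "ppv", "npv",
                          "accuracy")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1,
                 accuracy = 1))
  m2 <- diagnostic_metrics(c(0.5, 1.5, 1.0, 2.0), lab, 1.2)
  expect_equal(unlist(m2[c("sensitivity", "specificity", "ppv", "npv",
                           "accuracy")]),
               c(sensitivity = 0.5, specificity = 0.5, ppv = 0.5,
                 npv = 0.5, accuracy = 0.5))
  m3 <- diagnostic_metrics(c(0.5, 1.0, 1.5, 2.0), lab, 0.1)
  expect_true(is.na(m3$ppv))
  expect_equal(m3$undefined, "ppv")
  # conservation identities
  set.seed(8)
  for (rep in 1:10) {
    s <- rnorm(30); lab <- sample(c("LBD", "non-LBD"), 30, TRUE)
    if (length(unique(lab)) < 2) next
    m <- diagnostic_metrics(s, lab, median(s))
    tb <- m$table
    expect_equal(tb["positive", "LBD"] + tb["negative", "LBD"],
                 sum(lab == "LBD"))
    expect_equal(tb["positive", "non-LBD"] + tb["negative", "non-LBD"],
                 sum(lab == "non-LBD"))
    expect_equal(m$accuracy, (tb[1, 1] + tb[2, 2]) / 30)
  }
})

test_that("Mann-Whitney U matches exact enumeration conventions", {
  r1 <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r1$statistic, 0)
  expect_equal(r1$p_value, 1 / 3)
  r2 <- mann_whitney_u(c(1, 3), c(2, 4))
  expect_equal(r2$statistic, 1)
  expect_equal(r2$p_value, 2 / 3)
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_mibg_error(mann_whitney_u(numeric(0), 1:3), "EmptySample")
  # tie-free exact p agrees with the base-R oracle
  set.seed(23)
  for (rep in 1:15) {
    x <- sample(seq(0, 100, 0.5), sample(3:8, 1))
    y <- sample(seq(0.25, 100.25, 0.5), sample(3:8, 1))
    ours <- mann_whitney_u(x, y)
    oracle <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(ours$p_value, oracle$p.value, tolerance = 1e-12)
  }
  # large-sample normal approximation is close to the base-R oracle
  set.seed(5)
  x <- rnorm(30); y <- rnorm(40, 0.4)
  ours <- mann_whitney_u(x, y)
  oracle <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(ours$p_value, oracle$p.value, tolerance = 1e-6)
})

test_that("Fisher exact p follows sum-of-smaller-probabilities", {
  expect_equal(round(fisher_exact_2x2(matrix(c(17, 20, 20, 20), 2,
                                             byrow = TRUE))$p_value, 3),
               0.821)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))$p_value, 2 / 252)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2,
                                       byrow = TRUE))$p_value, 1)
  expect_mibg_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)),
                    "NegativeCount")
  # random tables agree with the base-R oracle
  set.seed(9)
  for (rep in 1:20) {
    tb <- matrix(rpois(4, 6), 2)
    expect_equal(fisher_exact_2x2(tb)$p_value,
                 stats::fisher.test(tb)$p.value, tolerance = 1e-9)
  }
})

test_that("Spearman correlation uses mid-ranks and the t approximation", {
  expect_equal(spearman_rho(1:10, (1:10)^2)$statistic, 1)
  expect_equal(spearman_rho(1:10, -(1:10))$statistic, -1)
  expect_equal(spearman_rho(c(1, 2, 3), c(2, 1, 3))$statistic, 0.5)
  expect_mibg_error(spearman_rho(1:4, 1:5), "LengthMismatch")
  set.seed(14)
  x <- rnorm(40); y <- x + rnorm(40)
  ours <- spearman_rho(x, y)
  oracle <- stats::cor.test(x, y, method = "spearman")
  expect_equal(ours$statistic, unname(oracle$estimate))
})

test_that("paired AUC comparison is symmetric and well calibrated", {
  set.seed(6)
  s <- rnorm(40); lab <- rep(c("LBD", "non-LBD"), 20)
  same <- compare_auc(s, s, lab)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  s2 <- rnorm(40)
  ab <- compare_auc(s, s2, lab); ba <- compare_auc(s2, s, lab)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$statistic, -ba$statistic)
  expect_mibg_error(compare_auc(1:5, 1:4, rep("LBD", 5)), "LengthMismatch")
  # discriminates clearly different AUCs on simulated cohorts
  hits <- 0
  for (rep in 1:100) {
    set.seed(1000 + rep)
    n <- 200
    lab <- rep(c("LBD", "non-LBD"), each = n)
    strong <- c(rnorm(n, 0), rnorm(n, 2.33))      # AUC ~ 0.95
    weak <- c(rnorm(n, 0), rnorm(n, 0.95))        # AUC ~ 0.75
    # LBD low orientation: negate
    p <- compare_auc(-strong, -weak, lab)$p_value
    hits <- hits + (p < 0.01)
  }
  expect_gte(hits, 95)
})
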