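test_that("segregation classification reproduces the monohybrid tests", {
  # both parents heterozygous: 1:2:1 across three classes
  sc <- classify_segregation("AB", "AB", c(96, 181, 76))
  expect_equal(sc$expected_class, "ratio_1_2_1")
  expect_equal(sc$chi2, sum((c(96, 181, 76) - c(88.25, 176.5, 88.25))^2 /
                              c(88.25, 176.5, 88.25)))
  expect_equal(round(sc$chi2, 2), 2.5)
  expect_equal(round(sc$pvalue, 3), 0.287)

  # test-cross: carrier vs non-carrier 1:1
  sc <- classify_segregation("AB", "AA", c(158, 195, 0))
  expect_equal(sc$expected_class, "ratio_1_1")
  expect_equal(round(sc$chi2, 2), 3.88)

  # identical homozygous parents, single progeny class: monomorphic
  sc <- classify_segregation("AA", "AA", c(353, 0, 0))
  expect_equal(sc$expected_class, "monomorphic")

  expect_equal(classify_segregation(NA, "AB", c(10, 10, 10))$expected_class,
               "unscorable")
  expect_equal(classify_segregation("AB", "AB", c(0, 0, 0))$expected_class,
               "unscorable")
  # progeny grossly inconsistent with an AB x AA cross
  expect_equal(classify_segregation("AB", "AA", c(50, 50, 40))$expected_class,
               "unscorable")
})

test_that("goodness-of-fit equals the brute-force oracle on random tables", {
  set.seed(23)
  for (i in 1:25) {
    counts <- rmultinom(1, sample(50:400, 1), c(1, 2, 1) / 4)[, 1]
    sc <- classify_segregation("AB", "AB", counts)
    ct <- suppressWarnings(chisq.test(counts, p = c(1, 2, 1) / 4))
    expect_equal(sc$chi2, unname(ct$statistic))
    expect_equal(sc$pvalue, ct$p.value)
  }
})

test_that("true/false labeling keys on the discovery parent", {
  expect_equal(label_true_false(classify_segregation("AA", "AA", c(300, 1, 0))),
               "false_positive")                       # monomorphic
  expect_equal(label_true_false(classify_segregation("AA", "AB", c(150, 160, 0))),
               "false_positive")                       # segregates, parent hom
  expect_equal(label_true_false(classify_segregation("AB", "AB", c(96, 181, 76))),
               "true_positive")
  expect_equal(label_true_false(classify_segregation("AB", "AA", c(150, 160, 0))),
               "true_positive")
  expect_equal(label_true_false(classify_segregation(NA, "AB", c(1, 1, 1))),
               "unscorable")
  # discovery parent on the other side
  expect_equal(label_true_false(classify_segregation("AA", "AB", c(150, 160, 0)),
                                discovery_parent = 2), "true_positive")
})

test_that("Fisher two-sided p matches the hypergeometric sum oracle", {
  # oracle: sum P(tables) with probability <= observed, margins fixed
  fisher_oracle <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    x <- max(0, k - n):min(k, m)
    pr <- dhyper(x, m, n, k)
    sum(pr[pr <= dhyper(a, m, n, k) * (1 + 1e-7)])
  }
  for (tab in list(c(5, 5, 5, 5), c(12, 3, 4, 9), c(1, 9, 11, 3))) {
    expect_equal(fisher_exact_2x2(tab[1], tab[2], tab[3], tab[4]),
                 fisher_oracle(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-7)
  }
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1.0)
  # invariance under simultaneous row and column swaps
  expect_equal(fisher_exact_2x2(12, 3, 4, 9), fisher_exact_2x2(9, 4, 3, 12))
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "all-zero")
})

test_that("logistic prediction evaluates the fitted coefficients", {
  # group-mean profiles of true- and false-positive SNPs
  r_tp <- tp_logit_predict(34.3, 18.4, 0.39)
  expect_equal(round(log(r_tp$p_false / (1 - r_tp$p_false)), 3), -0.758)
  expect_equal(round(r_tp$p_false, 3), 0.319)
  expect_equal(r_tp$predicted_label, "true_positive")

  r_fp <- tp_logit_predict(33.7, 31.7, 0.34)
  expect_equal(round(log(r_fp$p_false / (1 - r_fp$p_false)), 3), 0.74)
  expect_equal(r_fp$predicted_label, "false_positive")

  null <- tp_model(0, 0, 0, 0)
  expect_equal(tp_logit_predict(10, 10, 0.3, null)$p_false, 0.5)
})

test_that("p_false is monotone in each predictor with the fitted signs", {
  base <- tp_logit_predict(34, 20, 0.35)$p_false
  expect_lt(tp_logit_predict(35, 20, 0.35)$p_false, base)  # MQS down-weights
  expect_gt(tp_logit_predict(34, 25, 0.35)$p_false, base)  # RMD up-weights
  expect_lt(tp_logit_predict(34, 20, 0.45)$p_false, base)  # FVF down-weights
})

test_that("logistic refitting validates input and reports exact accuracy", {
  set.seed(41)
  n <- 400
  df <- data.frame(mqs = rnorm(n, 34, 1.8), rmd = pmax(2, rnorm(n, 25, 12)),
                   fvf = pmin(0.5, pmax(0, rnorm(n, 0.36, 0.1))))
  p <- tp_logit_predict(df$mqs, df$rmd, df$fvf)$p_false
  df$label <- ifelse(runif(n) < p, "false_positive", "true_positive")
  fit <- fit_tp_logit(df)
  pred <- tp_logit_predict(df$mqs, df$rmd, df$fvf, fit$model)
  expect_equal(fit$accuracy$overall, mean(pred$predicted_label == df$label))
  cm <- fit$accuracy$confusion
  expect_equal(sum(cm), n)
  expect_equal(fit$accuracy$overall, sum(diag(cm)) / n)

  expect_error(fit_tp_logit(df[1:20, ]), "at least 50")
  one <- df; one$label <- "true_positive"
  expect_error(fit_tp_logit(one), "both classes")
  sep <- df; sep$label <- ifelse(sep$rmd > 25, "false_positive", "true_positive")
  expect_error(fit_tp_logit(sep), "separation")
})

test_that("validation summary reproduces headline rate arithmetic", {
  labels <- c(rep("false_positive", 200), rep("true_positive", 250),
              rep("unscorable", 50))
  ann <- c(rep("genic", 120), rep("nongenic", 80),      # false positives
           rep("genic", 150), rep("nongenic", 100),     # true positives
           rep("genic", 50))
  vs <- validation_summary(labels, ann, n_designed = 600)
  expect_equal(vs$error_rate_pct, pct(200, 500))
  expect_equal(vs$by_annotation$genic$true_positive_rate_pct, pct(150, 270))
  expect_equal(vs$by_annotation$nongenic$true_positive_rate_pct, pct(100, 180))
  expect_equal(vs$conversion_rate_pct, pct(450, 600))
  expect_equal(vs$fisher_p, fisher_exact_2x2(120, 80, 150, 100))

  empty <- validation_summary(character())
  expect_equal(empty$n_genotyped, 0L)
})

test_that("marker validation agrees with simulated cross truth", {
  cfg <- sim_config(seed = 77, n_progeny = 300, genotyping_error_rate = 0,
                    missing_rate = 0)
  p1 <- c(m1 = "AB", m2 = "AB", m3 = "AA", m4 = "AA", m5 = "BB")
  p2 <- c(m1 = "AB", m2 = "AA", m3 = "AB", m4 = "AA", m5 = "BB")
  gt <- simulate_cross(p1, p2, config = cfg)
  seg <- validate_markers(gt, "P1", "P2")
  expect_equal(seg$expected_class,
               c("ratio_1_2_1", "ratio_1_1", "ratio_1_1", "monomorphic",
                 "monomorphic"))
  # discovery parent P1: het at m1/m2 -> true; m3 segregates from P2 -> false
  expect_equal(seg$label,
               c("true_positive", "true_positive", "false_positive",
                 "false_positive", "false_positive"))
})
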