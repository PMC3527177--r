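# Genotyping-based SNP validation.
#
# SNPs discovered in one heterozygous parent are validated indirectly by
# genotyping an F1 cross: a real SNP must be heterozygous in the discovery
# parent and segregate in the progeny (1:2:1 when both parents are AB,
# 1:1 test-cross when only one is).  A marker monomorphic in parent and
# progeny — or segregating while the discovery parent is homozygous — is a
# false-positive call.

SEG_CLASSES <- c("ratio_1_2_1", "ratio_1_1", "monomorphic", "unscorable")

#' Classify marker segregation in an F1 population
#'
#' Given the two parental genotypes and progeny genotype counts
#' `(nAA, nAB, nBB)`, classifies the marker and runs the matching
#' chi-square goodness-of-fit test:
#' * `AB x AB`: 1:2:1 across the three classes (2 df);
#' * `AB x hom` (either order): 1:1 test-cross over the two observable
#'   classes, carrier (`AB`) vs non-carrier (the homozygous parental
#'   class) (1 df);
#' * identical homozygous parents: `monomorphic` when a single progeny
#'   class dominates;
#' * `AA x BB`: all progeny `AB`, no segregation — `monomorphic`;
#' * missing parental genotypes, zero progeny, or progeny grossly
#'   inconsistent with the parents (> 5% impossible classes, e.g. `BB`
#'   progeny from `AB x AA`): `unscorable`.  A small share of impossible
#'   calls is tolerated as genotyping error and excluded from the test.
#'
#' @param parent1,parent2 parental genotypes (`"AA"`, `"AB"`, `"BB"`, or
#'   `NA`).
#' @param progeny_counts integer vector `c(nAA, nAB, nBB)`.
#' @param alpha significance level carried into the call (default 0.05).
#' @param marker_id optional marker name.
#' @return List of class `segregation_call`: `marker_id`, parental
#'   genotypes, `progeny_counts`, `expected_class`, `chi2`, `pvalue`,
#'   `alpha`.
#' @export
#' @examples
#' classify_segregation("AB", "AB", c(96, 181, 76))   # 1:2:1, chi2 ~ 2.50
classify_segregation <- function(parent1, parent2, progeny_counts,
                                 alpha = 0.05, marker_id = NA_character_) {
  stopifnot(length(progeny_counts) == 3, all(progeny_counts >= 0))
  counts <- as.integer(progeny_counts)
  names(counts) <- GT_TOKENS
  n <- sum(counts)
  call <- function(class, chi2 = NA_real_, p = NA_real_) {
    structure(list(marker_id = marker_id, parent1_gt = parent1,
                   parent2_gt = parent2, progeny_counts = counts,
                   expected_class = class, chi2 = chi2, pvalue = p,
                   alpha = alpha),
              class = "segregation_call")
  }
  if (is.na(parent1) || is.na(parent2) || n == 0) return(call("unscorable"))
  p1 <- match.arg(parent1, GT_TOKENS)
  p2 <- match.arg(parent2, GT_TOKENS)
  het <- c(p1, p2) == "AB"
  if (all(het)) {
    gof <- chisq_gof(counts, c(1, 2, 1) / 4)
    return(call("ratio_1_2_1", gof$chi2, gof$p))
  }
  if (any(het)) {
    hom <- c(p1, p2)[!het]
    carrier <- counts[["AB"]]
    noncar <- counts[[hom]]
    impossible <- n - carrier - noncar
    if (impossible > 0.05 * n) return(call("unscorable"))
    gof <- chisq_gof(c(carrier, noncar), c(1, 1) / 2)
    return(call("ratio_1_1", gof$chi2, gof$p))
  }
  # both parents homozygous
  main <- if (p1 == p2) counts[[p1]] else counts[["AB"]]
  if (main >= 0.95 * n) return(call("monomorphic"))
  call("unscorable")
}

# brute-force goodness of fit: sum (obs - exp)^2 / exp
chisq_gof <- function(obs, probs) {
  expd <- sum(obs) * probs
  chi2 <- sum((obs - expd)^2 / expd)
  list(chi2 = chi2, p = pchisq(chi2, df = length(obs) - 1, lower.tail = FALSE))
}

#' Label a marker true- or false-positive from its segregation
#'
#' A discovered SNP is a real heterozygous site in the discovery parent,
#' so: `false_positive` when the marker is monomorphic, or when it
#' segregates but the discovery parent is homozygous (the polymorphism
#' came from the other parent); `true_positive` when the discovery parent
#' is heterozygous and the progeny segregate; `unscorable` otherwise.
#'
#' @param segregation a `segregation_call`.
#' @param discovery_parent which parent the SNP was discovered in
#'   (`1` or `2`, default 1).
#' @return `"true_positive"`, `"false_positive"` or `"unscorable"`.
#' @export
label_true_false <- function(segregation, discovery_parent = 1) {
  stopifnot(inherits(segregation, "segregation_call"))
  cls <- segregation$expected_class
  if (cls == "unscorable") return("unscorable")
  if (cls == "monomorphic") return("false_positive")
  dp <- if (discovery_parent == 1) segregation$parent1_gt else segregation$parent2_gt
  if (is.na(dp)) return("unscorable")
  if (dp == "AB") "true_positive" else "false_positive"
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value for independence in the table
#' `rbind(c(a, b), c(c, d))`, computed by the minimum-likelihood rule
#' (sum of hypergeometric probabilities of all tables no more probable
#' than the observed one).
#'
#' @param a,b,c,d non-negative integer cell counts (row-wise).
#' @return The two-sided p-value.
#' @export
#' @examples
#' fisher_exact_2x2(378, 202, 3488, 1932)  # ~0.71
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  if (sum(cells) == 0) stop("all-zero contingency table")
  fisher.test(matrix(cells, nrow = 2, byrow = TRUE))$p.value
}

#' Logistic true-positive model
#'
#' Container for the logistic model
#' `log(p / (1 - p)) = b0 + b1*MQS + b2*RMD + b3*FVF`,
#' where `p` is the probability that a SNP is a false positive.  Defaults
#' are the coefficients fitted on the walnut 6K genotyping validation set.
#'
#' @param b0,b1,b2,b3 coefficients on the log-odds scale (intercept, MQS,
#'   RMD, FVF).
#' @return Object of class `tp_model`.
#' @export
tp_model <- function(b0 = 10.3976899, b1 = -0.3077982,
                     b2 = 0.07896269, b3 = -5.2585503) {
  structure(list(b0 = b0, b1 = b1, b2 = b2, b3 = b3,
                 predictors = c("MQS", "RMD", "FVF")),
            class = "tp_model")
}

#' Predict false-positive probability for a SNP
#'
#' Evaluates the logistic model: `p_false = plogis(b0 + b1*mqs + b2*rmd +
#' b3*fvf)`.  A SNP is predicted false-positive when `p_false > 0.5`.
#'
#' @param mqs,rmd,fvf predictor values (vectorised).
#' @param model a [tp_model()] (defaults to the fitted walnut model).
#' @return List with `p_false` and `predicted_label`
#'   (`"true_positive"` / `"false_positive"`).
#' @export
#' @examples
#' tp_logit_predict(34.3, 18.4, 0.39)  # p_false ~ 0.32 -> true
tp_logit_predict <- function(mqs, rmd, fvf, model = tp_model()) {
  stopifnot(inherits(model, "tp_model"))
  lo <- model$b0 + model$b1 * mqs + model$b2 * rmd + model$b3 * fvf
  p <- plogis(lo)
  list(p_false = p,
       predicted_label = ifelse(p > 0.5, "false_positive", "true_positive"))
}

#' Fit the logistic true-positive model
#'
#' Maximum-likelihood logistic regression of false-positive status on
#' MQS, RMD and FVF, via [stats::glm()] with a binomial family.  Also
#' reports training-set prediction accuracy at the 0.5 threshold,
#' overall and per class.
#'
#' @param records data frame with columns `mqs`, `rmd`, `fvf` and `label`
#'   (`"true_positive"` / `"false_positive"`); at least 50 rows and both
#'   classes present.
#' @return List with `model` (a [tp_model()]), `se` (coefficient standard
#'   errors), `fit` (the `glm` object) and `accuracy` (overall,
#'   true-positive and false-positive rates, plus the confusion matrix).
#' @export
fit_tp_logit <- function(records) {
  stopifnot(all(c("mqs", "rmd", "fvf", "label") %in% names(records)))
  if (nrow(records) < 50) stop("need at least 50 labeled records")
  y <- records$label == "false_positive"
  if (length(unique(y)) < 2) stop("both classes must be present")
  fit <- withCallingHandlers(
    glm(y ~ mqs + rmd + fvf, data = records, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        stop("perfect separation: logistic MLE does not exist for these records")
      }
      invokeRestart("muffleWarning")
    })
  cf <- coef(fit)
  model <- tp_model(cf[["(Intercept)"]], cf[["mqs"]], cf[["rmd"]], cf[["fvf"]])
  pred <- tp_logit_predict(records$mqs, records$rmd, records$fvf, model)
  confusion <- table(actual = records$label, predicted = pred$predicted_label)
  correct <- pred$predicted_label == records$label
  acc <- list(
    overall = mean(correct),
    true_positive = mean(correct[records$label == "true_positive"]),
    false_positive = mean(correct[records$label == "false_positive"]),
    confusion = confusion
  )
  list(model = model, se = summary(fit)$coefficients[, "Std. Error"],
       fit = fit, accuracy = acc)
}

#' Summarise validation outcomes
#'
#' Computes the headline validation rates from per-marker labels: the
#' SNP-discovery error rate (% false positives among genotyped markers),
#' the true-positive rate, per-annotation (genic vs non-genic)
#' true-positive rates with a Fisher test of the source x outcome
#' association, and — when assay totals are given — the conversion rate
#' (% of designed assays yielding usable markers).
#'
#' @param labels character vector of `"true_positive"` /
#'   `"false_positive"` / `"unscorable"` per genotyped marker.
#' @param annotation optional parallel vector of `"genic"` /
#'   `"nongenic"` / `"unknown"`.
#' @param n_designed optional number of assays designed (for the
#'   conversion rate).
#' @param n_converted optional number of assays converted to usable
#'   markers (defaults to the number of scorable labels).
#' @return List of class `validation_summary`; percentages are unrounded.
#' @export
validation_summary <- function(labels, annotation = NULL, n_designed = NULL,
                               n_converted = NULL) {
  if (!length(labels)) {
    return(structure(list(n_genotyped = 0L), class = "validation_summary"))
  }
  stopifnot(all(labels %in% c("true_positive", "false_positive", "unscorable")))
  n <- length(labels)
  n_tp <- sum(labels == "true_positive")
  n_fp <- sum(labels == "false_positive")
  out <- list(
    n_genotyped = n, n_true = n_tp, n_false = n_fp,
    n_unscorable = n - n_tp - n_fp,
    error_rate_pct = pct(n_fp, n),
    true_positive_rate_pct = pct(n_tp, n)
  )
  if (!is.null(annotation)) {
    stopifnot(length(annotation) == n)
    scored <- labels != "unscorable"
    by_ann <- lapply(c(genic = "genic", nongenic = "nongenic"), function(a) {
      sel <- scored & annotation == a
      list(n = sum(sel),
           n_true = sum(labels[sel] == "true_positive"),
           true_positive_rate_pct =
             if (sum(sel)) pct(sum(labels[sel] == "true_positive"), sum(sel))
             else NA_real_)
    })
    out$by_annotation <- by_ann
    tab <- c(sum(scored & annotation == "genic" & labels == "false_positive"),
             sum(scored & annotation == "nongenic" & labels == "false_positive"),
             sum(scored & annotation == "genic" & labels == "true_positive"),
             sum(scored & annotation == "nongenic" & labels == "true_positive"))
    if (all(rowSums(matrix(tab, 2, byrow = TRUE)) > 0) && sum(tab) > 0) {
      out$fisher_p <- fisher_exact_2x2(tab[1], tab[2], tab[3], tab[4])
    }
  }
  if (!is.null(n_designed)) {
    n_converted <- n_converted %||% (n_tp + n_fp)
    out$n_designed <- n_designed
    out$n_converted <- n_converted
    out$conversion_rate_pct <- pct(n_converted, n_designed)
  }
  structure(out, class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat("SNP validation summary\n")
  if (!x$n_genotyped) {
    cat("  (no genotyped markers)\n")
    return(invisible(x))
  }
  cat(sprintf("  genotyped markers: %d (true %d / false %d / unscorable %d)\n",
              x$n_genotyped, x$n_true, x$n_false, x$n_unscorable))
  cat(sprintf("  error rate: %.1f%%  true-positive rate: %.1f%%\n",
              x$error_rate_pct, x$true_positive_rate_pct))
  if (!is.null(x$conversion_rate_pct)) {
    cat(sprintf("  conversion rate: %.1f%% (%d/%d)\n", x$conversion_rate_pct,
                x$n_converted, x$n_designed))
  }
  if (!is.null(x$by_annotation)) {
    cat(sprintf("  true-positive rate genic: %.1f%%  non-genic: %.1f%%",
                x$by_annotation$genic$true_positive_rate_pct,
                x$by_annotation$nongenic$true_positive_rate_pct))
    if (!is.null(x$fisher_p)) cat(sprintf("  (Fisher p = %.2g)", x$fisher_p))
    cat("\n")
  }
  invisible(x)
}

#' Validate a genotyped panel against an F1 cross
#'
#' Convenience wrapper: classifies segregation for every marker of a
#' genotype matrix, labels each true/false positive with respect to the
#' discovery parent, and returns the per-marker table.
#'
#' @param genotypes character matrix (samples x markers) from
#'   [read_genotypes()] / [simulate_cross()].
#' @param parent1,parent2 sample ids of the parents in `genotypes`;
#'   `parent1` is the discovery parent.
#' @param alpha significance level for the segregation tests.
#' @return Data frame with one row per marker: parental genotypes,
#'   progeny counts, `expected_class`, `chi2`, `pvalue`, `label`.
#' @export
validate_markers <- function(genotypes, parent1, parent2, alpha = 0.05) {
  stopifnot(parent1 %in% rownames(genotypes), parent2 %in% rownames(genotypes))
  prog <- genotypes[!(rownames(genotypes) %in% c(parent1, parent2)), ,
                    drop = FALSE]
  rows <- lapply(colnames(genotypes), function(mk) {
    calls <- prog[, mk]
    counts <- vapply(GT_TOKENS, function(g) sum(calls == g, na.rm = TRUE), 0L)
    sc <- classify_segregation(genotypes[parent1, mk], genotypes[parent2, mk],
                               counts, alpha = alpha, marker_id = mk)
    data.frame(marker_id = mk, parent1_gt = genotypes[parent1, mk],
               parent2_gt = genotypes[parent2, mk],
               nAA = counts[[1]], nAB = counts[[2]], nBB = counts[[3]],
               expected_class = sc$expected_class, chi2 = sc$chi2,
               pvalue = sc$pvalue, label = label_true_false(sc),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
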