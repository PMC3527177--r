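params_adj <- filter_params("adjusted", max_rmd = 25)

test_that("depth and quality thresholds fail the right candidates", {
  snps <- rbind(cand(rmd = 4), cand(rmd = 26), cand(mqs = 24),
                cand(ref_base_quality = 40, annotation = "genic"),
                cand(ref_base_quality = 44, annotation = "nongenic"),
                cand(ref_base_quality = 44, annotation = "unknown"))
  qf <- quality_filters(snps, params_adj)
  expect_equal(unname(qf[, "min_rmd"]), c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(unname(qf[, "max_rmd"]), c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(unname(qf[, "mqs"]), c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  # genic >= 40 passes; non-genic needs >= 45; unknown held to the stricter bar
  expect_equal(unname(qf[, "ref_base_quality"]),
               c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
})

test_that("FVF filter honours both modes", {
  p_fix <- filter_params("initial")
  expect_true(fvf_filter(cand(fvf = 0.19), p_fix)$fail)
  expect_false(fvf_filter(cand(fvf = 0.2), p_fix)$fail)
  expect_false(fvf_filter(cand(fvf = 0.5, rmd = 100), params_adj)$fail)
  r <- fvf_filter(cand(fvf = 0.2, rmd = 25), params_adj)
  expect_true(r$fail)
  expect_equal(r$t_stat, 2.8)
})

test_that("homopolymer runs in and around the SNP are rejected", {
  refs <- make_ref("h1", "CCTAAAGTTG")
  # inside the AAA run
  expect_true(homopolymer_filter(cand(ref_id = "h1", pos = 5L, ref_base = "A",
                                      allele1 = "A", allele2 = "G"),
                                 refs, params_adj))
  # substitution creates a run: G -> A at the G of ..AAG..
  refs2 <- make_ref("h2", "CCTAAGTTGC")
  expect_true(homopolymer_filter(cand(ref_id = "h2", pos = 6L, ref_base = "G",
                                      allele1 = "G", allele2 = "A"),
                                 refs2, params_adj))
  # no run context
  refs3 <- acgt_ref("h3", 100)
  expect_false(homopolymer_filter(cand(ref_id = "h3", pos = 50L), refs3,
                                  params_adj))
  expect_error(homopolymer_filter(cand(ref_id = "h3", pos = 101L), refs3,
                                  params_adj), "range")
})

test_that("close SNP pairs are both removed", {
  snps <- rbind(cand(pos = 100L), cand(pos = 103L))
  expect_equal(proximity_filter(snps, params_adj), c(TRUE, TRUE))
  snps <- rbind(cand(pos = 100L), cand(pos = 104L))   # > 3 bp apart
  expect_equal(proximity_filter(snps, params_adj), c(FALSE, FALSE))
  expect_equal(proximity_filter(cand(pos = 100L), params_adj), FALSE)
  # pairs on different references never interact
  snps <- rbind(cand(pos = 100L), cand(ref_id = "bes2", pos = 101L))
  expect_equal(proximity_filter(snps, params_adj), c(FALSE, FALSE))
})

test_that("SNPs near the right (3') read end are rejected", {
  refs <- acgt_ref("bes1", 700)
  expect_true(right_edge_filter(cand(pos = 671L), refs, params_adj))   # 29 bp
  expect_false(right_edge_filter(cand(pos = 670L), refs, params_adj))  # 30 bp
  expect_false(right_edge_filter(cand(pos = 1L), refs, params_adj))
})

test_that("cascade attributes one designed failure per candidate", {
  bes2 <- paste0(substr(strrep("ACGT", 50), 1, 100), "AAA",
                 substr(strrep("ACGT", 200), 104, 700))
  refs <- ref_set(acgt_ref("bes1", 700), make_ref("bes2", bes2))
  cands <- rbind(
    cand(pos = 100L),                                    # survivor
    cand(pos = 200L, rmd = 4),                           # min_rmd
    cand(pos = 300L, rmd = 26),                          # max_rmd
    cand(pos = 400L, fvf = 0.2, rmd = 25),               # fvf (t-test)
    cand(pos = 500L, mqs = 29),                          # mqs
    cand(pos = 600L, ref_base_quality = 39),             # ref quality
    cand(ref_id = "bes2", pos = 102L, ref_base = "A"),   # homopolymer
    cand(pos = 680L)                                     # right edge
  )
  res <- run_cascade(cands, refs, params_adj)
  expect_equal(nrow(res$snps), 1L)
  expect_equal(res$snps$pos, 100L)
  flags <- res$candidates$filter_flags
  expect_equal(sum(flags == ""), 1L)
  expect_setequal(flags[flags != ""],
                  c("min_rmd", "max_rmd", "fvf", "mqs", "ref_base_quality",
                    "homopolymer", "right_edge"))
  expect_equal(res$report$input, rep(8L, 8))
  expect_equal(res$report$failed[res$report$filter == "proximity"], 0L)
  expect_true(all(res$report$input == res$report$failed + res$report$passed))
})

test_that("cascade handles empty input and disabled thresholds", {
  refs <- acgt_ref("bes1", 700)
  res <- run_cascade(snpstacks:::empty_candidates(), refs, params_adj)
  expect_equal(nrow(res$snps), 0L)
  expect_true(all(res$report$failed == 0L))

  off <- filter_params("initial", min_rmd = 0, max_rmd = Inf, min_mqs = 0,
                       min_ref_snp_qual_genic = 0,
                       min_ref_snp_qual_nongenic = 0,
                       homopolymer_len = 10000, min_snp_spacing = 0,
                       right_edge_bp = 0, fvf_threshold = 0)
  cands <- rbind(cand(pos = 100L, rmd = 3, fvf = 0.05, mqs = 1,
                      ref_base_quality = 2),
                 cand(pos = 101L), cand(pos = 650L))
  res <- run_cascade(cands, refs, off)
  expect_equal(nrow(res$snps), 3L)
})

test_that("cascade outcome is invariant to candidate order and idempotent", {
  refs <- acgt_ref("bes1", 700)
  set.seed(9)
  cands <- rbind(cand(pos = 100L), cand(pos = 102L), cand(pos = 340L, rmd = 30),
                 cand(pos = 400L), cand(pos = 665L), cand(pos = 500L, mqs = 10))
  res1 <- run_cascade(cands, refs, params_adj)
  res2 <- run_cascade(cands[sample(nrow(cands)), ], refs, params_adj)
  key <- function(d) sort(paste(d$ref_id, d$pos))
  expect_equal(key(res1$snps), key(res2$snps))

  # survivors independently satisfy every predicate
  s <- res1$snps
  expect_true(all(!quality_filters(s, params_adj)))
  expect_true(all(!fvf_filter(s, params_adj)$fail))
  expect_true(all(!homopolymer_filter(s, refs, params_adj)))
  expect_true(all(!proximity_filter(s, params_adj)))
  expect_true(all(!right_edge_filter(s, refs, params_adj)))
})
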