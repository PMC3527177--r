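# The SNP filter cascade.
#
# Candidates surviving every filter are the high-quality SNP set.  All
# filters are evaluated for every candidate (no short-circuiting) so the
# report can attribute every failure; `filter_flags` collects the names of
# all failed filters and survivors are the rows with an empty flag string.

FILTER_ORDER <- c("min_rmd", "max_rmd", "fvf", "mqs", "ref_base_quality",
                  "homopolymer", "proximity", "right_edge")

#' Filter parameter sets
#'
#' Builds the parameter list for [run_cascade()].  Two presets are
#' provided.  `"initial"` is the first-pass criteria: FVF >= 0.2, MQS >=
#' 25, no maximum-depth constraint.  `"adjusted"` (default) is the
#' genotyping-calibrated set: maximum RMD at the extreme-value cutoff
#' (25-equivalent), MQS >= 30, and FVF tested for deviation from 0.5
#' instead of a fixed threshold.  Criteria shared by both presets:
#' minimum RMD 5; reference base quality at the SNP >= 40 (genic) / >= 45
#' (non-genic, also applied to unannotated references); no SNP inside a
#' homopolymer run of >= 3 bp; > 3 bp between contiguous SNPs; > 30 bp
#' from the right (3') end of the reference read.
#'
#' @param preset `"adjusted"` or `"initial"`.
#' @param min_rmd,max_rmd read-depth window (reads). `max_rmd = NA` means
#'   "derive from the fitted depth model" in [discover_snps()]; `Inf`
#'   disables the check.
#' @param min_mqs minimum mapping quality score.
#' @param min_ref_snp_qual_genic,min_ref_snp_qual_nongenic minimum Phred
#'   quality of the reference base at the SNP, by annotation class.
#' @param homopolymer_len run length (bp) defining a homopolymer.
#' @param min_snp_spacing minimum distance (bp) between contiguous SNPs;
#'   4 encodes the "> 3 bp apart" rule.
#' @param right_edge_bp exclusion zone (bp) at the 3' end.
#' @param assay_spacing probe-design spacing (bp) used by
#'   [assay_spacing_filter()] (not part of the discovery cascade).
#' @param fvf_mode `"ttest"` (deviation test) or `"fixed_threshold"`.
#' @param fvf_threshold FVF cutoff used in `fixed_threshold` mode.
#' @param alpha significance level of the FVF deviation test.
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(preset = c("adjusted", "initial"),
                          min_rmd = 5, max_rmd = NULL, min_mqs = NULL,
                          min_ref_snp_qual_genic = 40,
                          min_ref_snp_qual_nongenic = 45,
                          homopolymer_len = 3, min_snp_spacing = 4,
                          right_edge_bp = 30, assay_spacing = 60,
                          fvf_mode = NULL, fvf_threshold = 0.2,
                          alpha = 0.05) {
  preset <- match.arg(preset)
  if (preset == "adjusted") {
    max_rmd <- max_rmd %||% NA_real_      # NA: take from the depth model
    min_mqs <- min_mqs %||% 30
    fvf_mode <- fvf_mode %||% "ttest"
  } else {
    max_rmd <- max_rmd %||% Inf
    min_mqs <- min_mqs %||% 25
    fvf_mode <- fvf_mode %||% "fixed_threshold"
  }
  fvf_mode <- match.arg(fvf_mode, c("ttest", "fixed_threshold"))
  stopifnot(min_rmd >= 0, is.na(max_rmd) || max_rmd >= 0, min_mqs >= 0,
            min_ref_snp_qual_genic >= 0, min_ref_snp_qual_nongenic >= 0,
            homopolymer_len >= 1, min_snp_spacing >= 0, right_edge_bp >= 0,
            assay_spacing >= 0, fvf_threshold >= 0, alpha > 0, alpha < 1)
  structure(list(preset = preset, min_rmd = min_rmd, max_rmd = max_rmd,
                 min_mqs = min_mqs,
                 min_ref_snp_qual_genic = min_ref_snp_qual_genic,
                 min_ref_snp_qual_nongenic = min_ref_snp_qual_nongenic,
                 homopolymer_len = homopolymer_len,
                 min_snp_spacing = min_snp_spacing,
                 right_edge_bp = right_edge_bp, assay_spacing = assay_spacing,
                 fvf_mode = fvf_mode, fvf_threshold = fvf_threshold,
                 alpha = alpha),
            class = "filter_params")
}

#' Depth, mapping-quality and reference-quality filters
#'
#' Returns, for each candidate, which of the per-site quality criteria
#' fail: `min_rmd` (depth below minimum), `max_rmd` (depth above the
#' repeat cutoff), `mqs` (mapping quality below minimum) and
#' `ref_base_quality` (reference Phred at the SNP below the
#' annotation-specific minimum; unannotated candidates are held to the
#' stricter non-genic threshold).
#'
#' @param snps annotated candidate data frame.
#' @param params [filter_params()].
#' @return Logical matrix (candidates x 4 criteria), `TRUE` = fail.
#' @export
quality_filters <- function(snps, params) {
  max_rmd <- if (is.na(params$max_rmd)) Inf else params$max_rmd
  qual_min <- ifelse(snps$annotation == "genic",
                     params$min_ref_snp_qual_genic,
                     params$min_ref_snp_qual_nongenic)
  cbind(min_rmd = snps$rmd < params$min_rmd,
        max_rmd = snps$rmd > max_rmd,
        mqs = snps$mqs < params$min_mqs,
        ref_base_quality = !is.na(snps$ref_base_quality) &
          snps$ref_base_quality < qual_min)
}

#' FVF filter
#'
#' In `fixed_threshold` mode a candidate passes when `fvf >=
#' fvf_threshold`.  In `ttest` mode it passes when
#' [fvf_deviation_test()] finds no significant deviation from 0.5.
#' Candidates with `rmd < 2` fail outright in `ttest` mode (the test is
#' undefined there).
#'
#' @inheritParams quality_filters
#' @return List with `fail` (logical vector) and `t_stat` (numeric, `NA`
#'   in fixed mode).
#' @export
fvf_filter <- function(snps, params) {
  if (!nrow(snps)) return(list(fail = logical(), t_stat = numeric()))
  if (params$fvf_mode == "fixed_threshold") {
    list(fail = snps$fvf < params$fvf_threshold,
         t_stat = rep(NA_real_, nrow(snps)))
  } else {
    ok <- snps$rmd >= 2
    fail <- !ok
    t_stat <- rep(NA_real_, nrow(snps))
    if (any(ok)) {
      res <- fvf_deviation_test(snps$fvf[ok], snps$rmd[ok], params$alpha)
      fail[ok] <- res$significant
      t_stat[ok] <- res$t_stat
    }
    list(fail = fail, t_stat = t_stat)
  }
}

# run-length scan: does position `pos` of `seq_chars` lie inside a run of
# >= len identical bases after substituting `base` at `pos`?
in_homopolymer_run <- function(seq_chars, pos, base, len) {
  s <- seq_chars
  s[pos] <- base
  lo <- pos
  while (lo > 1L && s[lo - 1L] == s[pos]) lo <- lo - 1L
  hi <- pos
  while (hi < length(s) && s[hi + 1L] == s[pos]) hi <- hi + 1L
  (hi - lo + 1L) >= len
}

#' Homopolymer filter
#'
#' A candidate fails when its position lies inside a run of
#' `homopolymer_len` or more identical reference bases, or when
#' substituting either allele at the position creates such a run
#' (homopolymer contexts are enriched for base-calling slippage).
#'
#' @inheritParams quality_filters
#' @param references `reference_set` covering every candidate.
#' @return Logical vector, `TRUE` = fail.
#' @export
homopolymer_filter <- function(snps, references, params) {
  if (!nrow(snps)) return(logical())
  vapply(seq_len(nrow(snps)), function(i) {
    r <- references[[snps$ref_id[i]]]
    if (is.null(r)) stop("reference '", snps$ref_id[i], "' not found")
    chars <- strsplit(r$sequence, "")[[1]]
    pos <- snps$pos[i]
    if (pos < 1L || pos > length(chars)) {
      stop("position out of range at ", snps$ref_id[i], ":", pos)
    }
    in_homopolymer_run(chars, pos, chars[pos], params$homopolymer_len) ||
      in_homopolymer_run(chars, pos, snps$allele1[i], params$homopolymer_len) ||
      in_homopolymer_run(chars, pos, snps$allele2[i], params$homopolymer_len)
  }, NA)
}

#' Proximity filter: remove very close SNPs
#'
#' Both members of any candidate pair on the same reference separated by
#' less than `min_snp_spacing` bp (i.e. not "> 3 bp apart" at the default)
#' are failed — clusters of close variants are characteristic of
#' misalignment.
#'
#' @inheritParams quality_filters
#' @return Logical vector, `TRUE` = fail.
#' @export
proximity_filter <- function(snps, params) {
  if (!nrow(snps)) return(logical())
  flag_close_pairs(snps$ref_id, snps$pos, params$min_snp_spacing)
}

# flag every site with a neighbour on the same reference closer than
# `spacing` bp (distance <= spacing - 1)
flag_close_pairs <- function(ref_id, pos, spacing) {
  fail <- logical(length(pos))
  for (ids in split(seq_along(pos), ref_id)) {
    o <- ids[order(pos[ids])]
    p <- pos[o]
    if (length(p) > 1L) {
      d <- diff(p)
      close_left <- c(FALSE, d < spacing)
      close_right <- c(d < spacing, FALSE)
      fail[o] <- close_left | close_right
    }
  }
  fail
}

#' Right-edge filter
#'
#' Sanger read quality decays toward the 3' end, so candidates within
#' `right_edge_bp` of the right end of the reference read are failed:
#' fail iff `length(reference) - pos < right_edge_bp`.
#'
#' @inheritParams homopolymer_filter
#' @return Logical vector, `TRUE` = fail.
#' @export
right_edge_filter <- function(snps, references, params) {
  if (!nrow(snps)) return(logical())
  lens <- vapply(references, function(r) nchar(r$sequence), 0L)[snps$ref_id]
  if (anyNA(lens)) stop("reference missing for right-edge filter")
  (lens - snps$pos) < params$right_edge_bp
}

#' Run the full SNP filter cascade
#'
#' Applies every filter to every candidate (no short-circuiting),
#' records all failures in `filter_flags` (semicolon-separated, cascade
#' order), and tallies a per-filter report.  Survivors are candidates
#' with no failed filter.
#'
#' @param candidates annotated candidate data frame
#'   ([annotate_candidates()]).
#' @param references `reference_set`.
#' @param params [filter_params()]; if `max_rmd` is `NA` a
#'   `depth_model` must be supplied.
#' @param depth_model optional [fit_evd()] result; its `cutoff` fills in
#'   `max_rmd` when that is `NA`.
#' @return List with `snps` (survivors), `candidates` (all candidates with
#'   flags and t statistics filled in) and `report` (data frame: filter,
#'   input, failed, passed).
#' @export
run_cascade <- function(candidates, references, params = filter_params(),
                        depth_model = NULL) {
  if (is.na(params$max_rmd)) {
    if (is.null(depth_model)) {
      stop("params$max_rmd is NA and no depth_model supplied")
    }
    params$max_rmd <- depth_model$cutoff
  }
  n <- nrow(candidates)
  if (!n) {
    report <- data.frame(filter = FILTER_ORDER, input = 0L, failed = 0L,
                         passed = 0L, stringsAsFactors = FALSE)
    return(list(snps = candidates, candidates = candidates, report = report))
  }
  # evaluation order is irrelevant to the outcome (nothing short-circuits);
  # report rows follow the cascade order
  qf <- quality_filters(candidates, params)
  fv <- fvf_filter(candidates, params)
  candidates$t_stat <- fv$t_stat
  fails <- cbind(min_rmd = qf[, "min_rmd"], max_rmd = qf[, "max_rmd"],
                 fvf = fv$fail, mqs = qf[, "mqs"],
                 ref_base_quality = qf[, "ref_base_quality"],
                 homopolymer = homopolymer_filter(candidates, references, params),
                 proximity = proximity_filter(candidates, params),
                 right_edge = right_edge_filter(candidates, references, params))
  fails <- fails[, FILTER_ORDER, drop = FALSE]
  candidates$filter_flags <- apply(fails, 1, function(f) {
    paste(FILTER_ORDER[f], collapse = ";")
  })
  report <- data.frame(filter = FILTER_ORDER, input = n,
                       failed = as.integer(colSums(fails)),
                       stringsAsFactors = FALSE)
  report$passed <- report$input - report$failed
  list(snps = candidates[candidates$filter_flags == "", , drop = FALSE],
       candidates = candidates, report = report)
}
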