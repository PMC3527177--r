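# Variant-frequency statistics on read stacks and candidate SNP calling.
#
# In a single heterozygous individual a SNP shows up as variation *within*
# the stack of mapped reads at a site: at a truly heterozygous site the two
# alleles are expected at frequency 0.5 each, while sequencing/mapping
# errors produce minor variants.  The variant frequency (VF) and its folded
# form (FVF) discriminate the two.

#' Variant frequency of a pileup column
#'
#' VF is the fraction of reads in the stack whose base differs from the
#' reference base: `(depth - count[ref_base]) / depth`, in `[0, 1]`.
#'
#' @param column one-row pileup data frame (or list) with fields
#'   `ref_base`, `depth` and counts `A`, `C`, `G`, `T`.
#' @return VF, or `NA` when depth is 0 (site must be skipped).
#' @export
#' @examples
#' compute_vf(list(ref_base = "A", depth = 20, A = 18, C = 0, G = 2, T = 0))
compute_vf <- function(column) {
  if (column$depth == 0) return(NA_real_)
  (column$depth - column[[column$ref_base]]) / column$depth
}

#' Fold a variant frequency onto [0, 0.5]
#'
#' `FVF = 1 - VF` when `VF > 0.5`, else `VF`.  At a heterozygous site the
#' expected FVF is 0.5 regardless of which haplotype the reference carries,
#' so stacks with the same minor-variant share get the same FVF.
#'
#' @param vf numeric vector of variant frequencies in `[0, 1]`.
#' @return Folded variant frequencies in `[0, 0.5]`.
#' @export
#' @examples
#' fold_vf(c(0.8, 0.5, 0.0))
fold_vf <- function(vf) {
  stopifnot(all(vf >= 0 & vf <= 1, na.rm = TRUE))
  ifelse(vf > 0.5, 1 - vf, vf)
}

#' t-test for deviation of FVF from the heterozygous expectation 0.5
#'
#' Variant counts at a true heterozygous site follow Binomial(RMD, 0.5),
#' so FVF should not deviate from 0.5 beyond sampling error.  The test
#' statistic is
#' \deqn{t = \frac{|FVF - 0.5| - 0.5/RMD}{0.5\sqrt{1/RMD}}}
#' when `RMD * 0.5 < 30` (continuity-corrected small-sample branch) and
#' \deqn{t = \frac{|FVF - 0.5|}{0.5\sqrt{1/RMD}}}
#' otherwise.  FVF deviates significantly from 0.5 — and the site is
#' discarded as a likely sequencing/mapping error — when
#' `t >= qt(1 - alpha, RMD - 1)` (upper one-tail critical value; the fold
#' makes the test one-sided).
#'
#' @param fvf folded variant frequency in `[0, 0.5]` (vectorised).
#' @param rmd read mapping depth, `>= 2` (vectorised).
#' @param alpha significance level (default 0.05).
#' @return List with components `t_stat` and `significant` (`TRUE` means
#'   "discard as false positive").
#' @export
#' @examples
#' fvf_deviation_test(0.2, 25)   # t = 2.8, significant
fvf_deviation_test <- function(fvf, rmd, alpha = 0.05) {
  stopifnot(all(fvf >= 0 & fvf <= 0.5), alpha > 0, alpha < 1)
  if (any(rmd < 2)) stop("rmd must be >= 2 (t distribution needs rmd - 1 df)")
  se <- 0.5 * sqrt(1 / rmd)
  small <- rmd * 0.5 < 30
  t_stat <- ifelse(small,
                   (abs(fvf - 0.5) - 0.5 / rmd) / se,
                   abs(fvf - 0.5) / se)
  crit <- qt(1 - alpha, df = rmd - 1)
  list(t_stat = t_stat, significant = t_stat >= crit)
}

#' Call candidate SNPs from pileup columns
#'
#' Ranks base counts per column.  A column whose two most frequent bases
#' both have positive counts is a heterozygosity candidate with alleles =
#' the top two bases (ties broken in fixed order A < C < G < T).  VF is
#' computed against the reference base.  When *neither* top allele equals
#' the reference base, the reference base itself is inferred to be a
#' sequencing error (`ref_error_inferred = TRUE`) and FVF is the minor
#' share of the top-two total; otherwise FVF is the folded VF.  Columns
#' with a single observed base (homozygous; no SNP detectable in a
#' single-individual design) or zero depth yield no candidate.
#' Third-ranked bases (triallelic noise) never become alleles but do count
#' toward depth and VF.
#'
#' @param pileup pileup data frame from [read_pileup()] or
#'   [simulate_pileup()].
#' @return Candidate SNP data frame (zero rows when nothing is called)
#'   with per-site statistics and empty `filter_flags`.
#' @seealso [call_site()] for a single column, [annotate_candidates()]
#' @export
call_candidates <- function(pileup) {
  validate_pileup(pileup)
  cnt <- as.matrix(pileup[, BASES])
  mode(cnt) <- "integer"
  n <- nrow(cnt)
  if (!n) return(empty_candidates())
  # top two base counts per column; which.max/order with fixed base order
  ord1 <- max.col(cnt, ties.method = "first")      # first max in A<C<G<T order
  top1 <- cnt[cbind(seq_len(n), ord1)]
  cnt2 <- cnt
  cnt2[cbind(seq_len(n), ord1)] <- -1L
  ord2 <- max.col(cnt2, ties.method = "first")
  top2 <- cnt[cbind(seq_len(n), ord2)]
  keep <- pileup$depth > 0L & top2 > 0L
  if (!any(keep)) return(empty_candidates())
  idx <- which(keep)
  a1 <- BASES[ord1[idx]]
  a2 <- BASES[ord2[idx]]
  refb <- pileup$ref_base[idx]
  depth <- pileup$depth[idx]
  refcnt <- cnt[cbind(idx, match(refb, BASES))]
  vf <- (depth - refcnt) / depth
  ref_err <- a1 != refb & a2 != refb
  fvf <- ifelse(ref_err,
                pmin(top1[idx], top2[idx]) / (top1[idx] + top2[idx]),
                fold_vf(vf))
  data.frame(
    ref_id = pileup$ref_id[idx], pos = pileup$pos[idx], ref_base = refb,
    allele1 = a1, allele2 = a2, vf = vf, fvf = fvf,
    rmd = depth, mqs = pileup$mqs[idx],
    ref_base_quality = NA_integer_, ref_avg_quality = NA_real_,
    annotation = "unknown", ref_error_inferred = ref_err,
    t_stat = NA_real_, filter_flags = "", pfalse = NA_real_,
    infinium_type = NA_character_, design_score = NA_real_,
    stringsAsFactors = FALSE
  )
}

empty_candidates <- function() {
  data.frame(ref_id = character(), pos = integer(), ref_base = character(),
             allele1 = character(), allele2 = character(), vf = numeric(),
             fvf = numeric(), rmd = integer(), mqs = numeric(),
             ref_base_quality = integer(), ref_avg_quality = numeric(),
             annotation = character(), ref_error_inferred = logical(),
             t_stat = numeric(), filter_flags = character(),
             pfalse = numeric(), infinium_type = character(),
             design_score = numeric(), stringsAsFactors = FALSE)
}

#' Call a single pileup column
#'
#' Convenience wrapper around [call_candidates()] for one column.
#'
#' @param column one-row pileup data frame or list with the pileup fields.
#' @return One-row candidate data frame, or `NULL` when the column is
#'   homozygous or has zero depth.
#' @export
call_site <- function(column) {
  df <- as.data.frame(column[c("ref_id", "pos", "ref_base", "depth",
                               BASES, "mqs")], stringsAsFactors = FALSE)
  out <- call_candidates(df)
  if (!nrow(out)) NULL else out
}

#' Attach reference annotation and quality to candidates
#'
#' Populates `annotation` (genic/nongenic/unknown), `ref_base_quality`
#' (Phred at the SNP position) and `ref_avg_quality` (mean reference
#' Phred) from the reference set and annotation map.  Every candidate's
#' reference must exist and its position must lie within the reference.
#'
#' @param snps candidate data frame from [call_candidates()].
#' @param references `reference_set`.
#' @param annotation optional named vector from [read_annotation()]
#'   (ids absent from it stay `unknown`).
#' @return The candidate data frame with the three fields filled in.
#' @export
annotate_candidates <- function(snps, references, annotation = NULL) {
  if (!nrow(snps)) return(snps)
  missing_ref <- setdiff(unique(snps$ref_id), names(references))
  if (length(missing_ref)) {
    stop("candidate references missing from reference set: ",
         paste(head(missing_ref, 5), collapse = ", "))
  }
  lens <- vapply(references, function(r) nchar(r$sequence), 0L)[snps$ref_id]
  if (any(snps$pos > lens)) {
    bad <- which(snps$pos > lens)[1]
    stop("candidate position beyond reference length at ",
         snps$ref_id[bad], ":", snps$pos[bad])
  }
  snps$ref_base_quality <- vapply(seq_len(nrow(snps)), function(i) {
    references[[snps$ref_id[i]]]$base_quality[snps$pos[i]]
  }, 0L)
  snps$ref_avg_quality <-
    vapply(references, `[[`, 0, "avg_quality")[snps$ref_id]
  if (!is.null(annotation)) {
    ann <- unname(annotation[snps$ref_id])
    snps$annotation <- ifelse(is.na(ann), "unknown", ann)
  } else {
    snps$annotation <- vapply(references, `[[`, "", "annotation")[snps$ref_id]
  }
  snps
}
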