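# End-to-end discovery wrapper tying the modules together.

#' Discover SNPs from references + pileup
#'
#' Runs the full discovery pipeline: candidate calling from the pileup,
#' annotation against the references, extreme-value depth modelling over
#' all covered sites, and the SNP filter cascade.  When
#' `params$max_rmd` is `NA` (the adjusted preset default) the
#' maximum-depth cutoff is taken from the fitted depth model
#' (`floor(mean + k * sd)`).
#'
#' @param references `reference_set`.
#' @param pileup pileup data frame.
#' @param annotation optional named annotation vector
#'   ([read_annotation()]); when `NULL` the references' own annotation is
#'   used.
#' @param params [filter_params()].
#' @param depth_model optional pre-fitted [fit_evd()] model; fitted from
#'   the pileup depths when `NULL`.
#' @param k cutoff multiplier passed to [fit_evd()].
#' @param moment_source moment source passed to [fit_evd()].
#' @return List with `snps` (survivors), `candidates` (all, flagged),
#'   `report` (per-filter counts), `depth_model`, `params`.
#' @export
discover_snps <- function(references, pileup, annotation = NULL,
                          params = filter_params(), depth_model = NULL,
                          k = 0.5, moment_source = "fitted") {
  candidates <- call_candidates(pileup)
  candidates <- annotate_candidates(candidates, references, annotation)
  if (is.null(depth_model)) {
    depth_model <- fit_evd(pileup$depth[pileup$depth > 0], k = k,
                           moment_source = moment_source)
  }
  res <- run_cascade(candidates, references, params, depth_model)
  res$snps$infinium_type <- if (nrow(res$snps)) {
    ifelse(res$snps$allele1 == res$snps$allele2, NA_character_,
           classify_infinium(res$snps$allele1, res$snps$allele2))
  } else character(0)
  list(snps = res$snps, candidates = res$candidates, report = res$report,
       depth_model = depth_model, params = params)
}
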