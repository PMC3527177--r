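# Infinium assay typing and panel selection.
#
# Infinium I SNPs ([A/T] and [C/G]) need two bead types (one probe per
# allele); Infinium II SNPs (all other biallelic pairs) need one.  BeadChip
# cost scales with bead types, so panels are built from type II SNPs only.

#' Classify a biallelic SNP as Infinium type I or II
#'
#' `{A,T}` and `{C,G}` are type I (two probes); the four remaining pairs
#' (`A/C`, `A/G`, `T/C`, `T/G`) are type II (single probe).  Symmetric in
#' its arguments.
#'
#' @param allele1,allele2 distinct bases (vectorised).
#' @return Character vector of `"I"` / `"II"`.
#' @export
#' @examples
#' classify_infinium("A", "T")  # "I"
#' classify_infinium("T", "C")  # "II"
classify_infinium <- function(allele1, allele2) {
  stopifnot(all(allele1 %in% BASES), all(allele2 %in% BASES))
  if (any(allele1 == allele2)) stop("alleles must be distinct")
  pair <- paste(pmin(allele1, allele2), pmax(allele1, allele2))
  ifelse(pair %in% c("A T", "C G"), "I", "II")
}

#' Probe-spacing filter
#'
#' Infinium probes need clean flanking sequence: any SNP with another
#' detected variant closer than `spacing` bp on the same reference is
#' failed (both members of the pair).
#'
#' @param snps candidate data frame (uses `ref_id`, `pos`).
#' @param spacing minimum distance in bp (default 60; sites exactly
#'   `spacing` apart pass).
#' @return Logical vector, `TRUE` = fail.
#' @export
assay_spacing_filter <- function(snps, spacing = 60) {
  if (!nrow(snps)) return(logical())
  flag_close_pairs(snps$ref_id, snps$pos, spacing)
}

#' Select an assay panel of SNPs
#'
#' Builds a genotyping panel under the design rules: (1) at most one SNP
#' per reference (BES); (2) at least one SNP per physical-map (FPC)
#' contig with eligible SNPs, capacity allowing; (3) per-contig counts
#' proportional to contig size (largest-remainder apportionment), with
#' picks spread along the contig by position percentile; (4) at most one
#' reference per gene when a `gene_id` column is present; (5) Infinium II
#' SNPs only, with assay design score at or above the cutoff.
#'
#' @param snps candidate data frame with `infinium_type` and
#'   `design_score` populated (design scores are external input from the
#'   vendor's assay design tool, never computed here).
#' @param contig_map named character vector: reference id -> contig id.
#' @param contig_sizes named numeric vector of contig sizes (any
#'   consistent unit; clone counts or bp).
#' @param budget maximum panel size.
#' @param min_design_score eligibility cutoff (default 0.7).
#' @return List of class `assay_panel`: `selected` (data frame of chosen
#'   SNPs with `contig_id`), `allocation` (named integer vector per
#'   contig), `budget`.
#' @export
select_assay_snps <- function(snps, contig_map, contig_sizes, budget,
                              min_design_score = 0.7) {
  stopifnot(budget >= 1)
  elig <- snps[!is.na(snps$infinium_type) & snps$infinium_type == "II" &
                 !is.na(snps$design_score) &
                 snps$design_score >= min_design_score, , drop = FALSE]
  # rule 1: one SNP per reference (keep the best design score)
  if (nrow(elig)) {
    elig <- elig[order(elig$ref_id, -elig$design_score, elig$pos), ]
    elig <- elig[!duplicated(elig$ref_id), , drop = FALSE]
  }
  # rule 4: one reference per gene, when gene ids are known
  if (nrow(elig) && "gene_id" %in% names(elig)) {
    drop <- !is.na(elig$gene_id) & duplicated(elig$gene_id, incomparables = NA)
    elig <- elig[!drop, , drop = FALSE]
  }
  elig$contig_id <- unname(contig_map[elig$ref_id])
  elig <- elig[!is.na(elig$contig_id), , drop = FALSE]
  if (!nrow(elig)) {
    return(structure(list(selected = elig, allocation = integer(0),
                          budget = budget), class = "assay_panel"))
  }
  supply <- table(elig$contig_id)
  contigs <- names(supply)
  sizes <- contig_sizes[contigs]
  sizes[is.na(sizes)] <- 0
  if (budget < length(contigs)) {
    warning("budget (", budget, ") below number of eligible contigs (",
            length(contigs), "); truncating by contig size rank")
    contigs <- contigs[order(-sizes)][seq_len(budget)]
    supply <- supply[contigs]
    sizes <- sizes[contigs]
  }
  alloc <- apportion(setNames(as.numeric(sizes), contigs),
                     setNames(as.integer(supply), contigs), budget)
  picks <- lapply(contigs, function(cg) {
    rows <- elig[elig$contig_id == cg, , drop = FALSE]
    rows <- rows[order(rows$ref_id, rows$pos), , drop = FALSE]
    k <- alloc[[cg]]
    if (k == 0L) return(rows[0, , drop = FALSE])
    # spread picks along the contig by position percentile
    idx <- unique(pmax(1L, ceiling((seq_len(k) - 0.5) / k * nrow(rows))))
    rows[idx, , drop = FALSE]
  })
  selected <- do.call(rbind, picks)
  rownames(selected) <- NULL
  structure(list(selected = selected,
                 allocation = setNames(vapply(picks, nrow, 0L), contigs),
                 budget = budget),
            class = "assay_panel")
}

# largest-remainder apportionment of `budget` seats to units with weights
# `sizes`, capped at `supply` per unit, with every unit (that has supply)
# guaranteed one seat when the budget allows.
apportion <- function(sizes, supply, budget) {
  units <- names(sizes)
  w <- sizes
  if (sum(w) == 0) w <- rep(1, length(w))
  quota <- budget * w / sum(w)
  alloc <- setNames(pmin(floor(quota), supply), units)
  # hand out remaining seats by largest remainder, respecting supply
  repeat {
    leftover <- budget - sum(alloc)
    room <- supply - alloc
    if (leftover <= 0L || !any(room > 0L)) break
    ord <- order(-(quota - floor(quota)), -sizes)
    progressed <- FALSE
    for (i in ord) {
      if (leftover == 0L) break
      if (room[i] > 0L) {
        alloc[i] <- alloc[i] + 1L
        room[i] <- room[i] - 1L
        leftover <- leftover - 1L
        progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  # rule 2: every contig with supply gets at least one, capacity allowing,
  # taking seats back from the largest allocations
  while (any(alloc == 0L & supply > 0L) && any(alloc > 1L)) {
    need <- which(alloc == 0L & supply > 0L)[1]
    donor <- which.max(alloc)
    alloc[donor] <- alloc[donor] - 1L
    alloc[need] <- 1L
  }
  as.list(alloc)
}

#' @export
print.assay_panel <- function(x, ...) {
  cat("Assay panel: ", nrow(x$selected), " SNPs selected (budget ",
      x$budget, ") across ", length(x$allocation), " contigs\n", sep = "")
  invisible(x)
}
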