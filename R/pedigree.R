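# Coefficient of parentage, marker heterozygosity and pairwise
# dissimilarity.
#
# The coefficient of parentage (COP, Malecot coancestry) between two
# individuals is the probability that alleles drawn at random from each are
# identical by descent.  Cultivar inbreeding coefficients are taken as 0
# (outcrossing species), so self-coancestry is (1 + F)/2 = 0.5.

check_pedigree_acyclic <- function(ped) {
  depth <- pedigree_depths(ped)   # errors on cycles
  invisible(depth)
}

# generation depth of every individual (founders = 0); detects cycles
pedigree_depths <- function(ped) {
  depth <- setNames(rep(NA_real_, nrow(ped)), ped$id)
  visiting <- character(0)
  get_depth <- function(id) {
    if (is.na(id) || !(id %in% ped$id)) return(-1)
    if (!is.na(depth[[id]])) return(depth[[id]])
    if (id %in% visiting) {
      stop("pedigree cycle detected involving '", id, "'")
    }
    visiting <<- c(visiting, id)
    row <- ped[ped$id == id, ]
    d <- 1 + max(get_depth(row$sire), get_depth(row$dam))
    visiting <<- setdiff(visiting, id)
    depth[[id]] <<- d
    d
  }
  for (id in ped$id) get_depth(id)
  depth
}

#' Coefficient of parentage between two individuals
#'
#' Malecot coancestry by the tabular recursion with all inbreeding
#' coefficients fixed at 0: `f(x, x) = 0.5`;
#' `f(x, y) = 0.5 * (f(sire_x, y) + f(dam_x, y))`, descending the
#' individual with the greater pedigree depth (the standard guard against
#' infinite descent); unknown parents and distinct founders contribute 0.
#'
#' @param ped pedigree data frame (`id`, `sire`, `dam`) as from
#'   [read_pedigree()]; must be acyclic.
#' @param x,y individual ids present in `ped` (founders implied by parent
#'   columns are also accepted).
#' @return The coefficient, in `[0, 0.5]`.
#' @export
#' @examples
#' ped <- data.frame(id = c("A", "B", "K"), sire = c(NA, NA, "A"),
#'                   dam = c(NA, NA, "B"))
#' cop(ped, "A", "K")   # parent-offspring: 0.25
cop <- function(ped, x, y) {
  known <- unique(c(ped$id, ped$sire, ped$dam))
  known <- known[!is.na(known)]
  if (!(x %in% known)) stop("unknown individual '", x, "'")
  if (!(y %in% known)) stop("unknown individual '", y, "'")
  depth <- pedigree_depths(ped)
  parents <- function(id) {
    if (!(id %in% ped$id)) return(c(NA_character_, NA_character_))
    row <- ped[ped$id == id, ]
    c(row$sire, row$dam)
  }
  d_of <- function(id) if (id %in% names(depth)) depth[[id]] else 0
  memo <- new.env(parent = emptyenv())
  f <- function(a, b) {
    if (is.na(a) || is.na(b)) return(0)
    key <- paste(sort(c(a, b)), collapse = "\r")
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (a == b) {
      0.5                       # (1 + F)/2 with F = 0
    } else {
      # descend the deeper individual
      if (d_of(a) < d_of(b)) { tmp <- a; a <- b; b <- tmp }
      if (d_of(a) == 0) {
        0                       # two distinct founders
      } else {
        pa <- parents(a)
        0.5 * (f(pa[1], b) + f(pa[2], b))
      }
    }
    memo[[key]] <- val
    val
  }
  f(x, y)
}

#' Pairwise coefficient-of-parentage matrix
#'
#' @param ped pedigree data frame.
#' @param ids individuals to include (default: all ids in `ped`).
#' @return Symmetric numeric matrix with 0.5 on the diagonal.
#' @export
cop_matrix <- function(ped, ids = ped$id) {
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      m[i, j] <- m[j, i] <- cop(ped, ids[i], ids[j])
    }
  }
  m
}

#' Marker heterozygosity of a sample
#'
#' Percentage of heterozygous calls among non-missing calls:
#' `100 * #AB / #non-missing`.
#'
#' @param calls character vector of genotype calls (`AA`/`AB`/`BB`/`NA`).
#' @return Percentage, or `NA` when every call is missing.
#' @export
heterozygosity <- function(calls) {
  scored <- !is.na(calls)
  if (!any(scored)) return(NA_real_)
  pct(sum(calls[scored] == "AB"), sum(scored))
}

#' Allele-sharing dissimilarity between two samples
#'
#' Per-locus allele-sharing distance for codominant diploid markers:
#' `d = 1 - shared_alleles / 2` (AA-AA 0, AA-AB 0.5, AA-BB 1, AB-AB 0),
#' averaged over loci non-missing in both samples.
#'
#' @param sample_i,sample_j genotype call vectors of equal length.
#' @return Dissimilarity in `[0, 1]`, or `NA` with a warning when no
#'   locus is shared.
#' @export
dissimilarity <- function(sample_i, sample_j) {
  stopifnot(length(sample_i) == length(sample_j))
  shared <- !is.na(sample_i) & !is.na(sample_j)
  if (!any(shared)) {
    warning("no shared non-missing loci")
    return(NA_real_)
  }
  d_tab <- matrix(c(0, 0.5, 1,
                    0.5, 0, 0.5,
                    1, 0.5, 0), 3, 3,
                  dimnames = list(GT_TOKENS, GT_TOKENS))
  mean(d_tab[cbind(sample_i[shared], sample_j[shared])])
}

#' Pairwise dissimilarity matrix over a genotype matrix
#'
#' @param gt character matrix (samples x markers).
#' @return Symmetric matrix of allele-sharing dissimilarities.
#' @export
dissimilarity_matrix <- function(gt) {
  ids <- rownames(gt)
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)[-seq_len(i)]) {
      m[i, j] <- m[j, i] <- dissimilarity(gt[i, ], gt[j, ])
    }
  }
  m
}

#' Pearson correlation between two summary vectors
#'
#' Thin wrapper over [stats::cor()] with the contract used here: equal
#' lengths of at least 3 and non-zero variance in both vectors.
#'
#' @param x,y numeric vectors.
#' @return Pearson r.
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance: correlation undefined")
  cor(x, y)
}
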