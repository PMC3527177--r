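# Synthetic-data generator with known truth.
#
# Emulates the statistical structure of the discovery data: long
# Sanger-style references with 3'-decaying quality, Gumbel-distributed
# short-read depth with a repeat class at inflated depth, heterozygous
# sites whose variant reads are Binomial(depth, 0.5), quality-driven base
# errors that skew VF low, and Mendelian F1 segregation from two parents.
# Every stochastic operation derives its stream from `config$seed`, so
# outputs are reproducible bit for bit.

#' Simulation configuration
#'
#' Bundles every generator parameter with its study-scale default:
#' references mimic BAC end sequences (mean 721 bp); depth is
#' Gumbel(location 16, scale 5) reads with a 15% repeat class at 4x
#' depth; heterozygous sites are planted at 0.002/bp; base-call errors
#' follow the local Phred quality via `e = 10^(-Q/10)` with a Sanger
#' profile decaying from Q55 to Q20 over the final 100 bp; site mapping
#' quality is Normal(34, 1.8); crosses produce 428 F1 progeny genotyped
#' with 0.5% error and 2% missingness.
#'
#' @param seed integer seed (mandatory; every generator op derives its
#'   random stream from it).
#' @param n_refs number of reference sequences.
#' @param ref_length_mean,ref_length_sd reference length distribution (bp).
#' @param genic_fraction fraction of references annotated genic.
#' @param repeat_fraction fraction of references that are
#'   repeat-contaminated.
#' @param repeat_depth_multiplier depth inflation on repeat references.
#' @param het_site_rate heterozygous sites per bp.
#' @param depth_mu,depth_beta Gumbel location/scale of per-reference depth
#'   (reads).
#' @param qual_high,qual_low,qual_decay_bp Phred plateau, 3'-end floor and
#'   decay window (bp) of the reference quality profile.
#' @param mqs_mean,mqs_sd site mapping-quality distribution.
#' @param ref_error_rate probability that the reference base at a planted
#'   het site is itself a sequencing error (a third base differing from
#'   both alleles).
#' @param refs_per_contig references per simulated physical-map contig.
#' @param n_progeny F1 progeny per simulated cross.
#' @param genotyping_error_rate,missing_rate per-call error/missingness in
#'   simulated genotyping.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_refs = 300,
                       ref_length_mean = 721, ref_length_sd = 80,
                       genic_fraction = 0.6,
                       repeat_fraction = 0.15,
                       repeat_depth_multiplier = 4,
                       het_site_rate = 0.002,
                       depth_mu = 16, depth_beta = 5,
                       qual_high = 55, qual_low = 20, qual_decay_bp = 100,
                       mqs_mean = 34, mqs_sd = 1.8,
                       ref_error_rate = 0.02,
                       refs_per_contig = 5,
                       n_progeny = 428,
                       genotyping_error_rate = 0.005,
                       missing_rate = 0.02) {
  stopifnot(!missing(seed), is.numeric(seed), length(seed) == 1)
  fracs <- c(genic_fraction, repeat_fraction, het_site_rate, ref_error_rate,
             genotyping_error_rate, missing_rate)
  stopifnot(all(fracs >= 0 & fracs <= 1), depth_beta > 0,
            repeat_depth_multiplier >= 1, n_refs >= 1, n_progeny >= 1)
  structure(as.list(environment()), class = "sim_config")
}

# op-specific streams derived from the one configured seed
seed_for <- function(config, op) {
  offs <- c(references = 0L, pileup = 1L, cross = 2L, pedigree = 3L)
  set.seed((as.integer(config$seed) + offs[[op]]) %% .Machine$integer.max)
}

qual_profile <- function(len, config) {
  q <- rep(config$qual_high, len)
  k <- min(config$qual_decay_bp, len)
  if (k > 0) {
    q[(len - k + 1):len] <-
      round(seq(config$qual_high, config$qual_low, length.out = k))
  }
  as.integer(q)
}

#' Simulate reference sequences with known heterozygous sites
#'
#' Generates a `reference_set` with a Sanger-like 3'-decaying quality
#' profile, genic/non-genic annotation, repeat membership, physical-map
#' contig ids, and a truth table of planted heterozygous sites.
#'
#' Planted sites are placed in assayable contexts: in the high-quality
#' body of the read (outside the 3' decay window), outside homopolymer
#' runs (for both alleles), and at least 61 bp apart.  Sequence context
#' and read-edge artefacts are therefore exercised by the error model and
#' by dedicated unit fixtures, while the truth table isolates the
#' stochastic depth/FVF/MQS filters.  With probability `ref_error_rate` a
#' planted site's reference base is a third base differing from both true
#' alleles (reference sequencing error).
#'
#' @param config a [sim_config()].
#' @return List with `references` (a `reference_set`; each record also
#'   carries `is_repeat`) and `truth` (data frame: `ref_id`, `pos`,
#'   `allele1`, `allele2`, `ref_error`, `repeat_ref`, `annotation`).
#' @export
simulate_references <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seed_for(config, "references")
  n <- config$n_refs
  lens <- pmax(200L, as.integer(round(rnorm(n, config$ref_length_mean,
                                            config$ref_length_sd))))
  ids <- sprintf("ref%04d", seq_len(n))
  genic <- runif(n) < config$genic_fraction
  is_rep <- runif(n) < config$repeat_fraction
  contig <- sprintf("ctg%03d", 1L + (seq_len(n) - 1L) %/% config$refs_per_contig)
  refs <- vector("list", n)
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    len <- lens[i]
    chars <- sample(BASES, len, replace = TRUE)
    qual <- qual_profile(len, config)
    n_het <- rbinom(1, len, config$het_site_rate)
    placed <- integer(0)
    t_a1 <- t_a2 <- character(0)
    t_err <- logical(0)
    if (n_het > 0) {
      lo <- 3L
      hi <- len - max(config$qual_decay_bp, 30L) - 1L
      if (hi >= lo) {
        cand <- sample(seq(lo, hi))
        for (p in cand) {
          if (length(placed) >= n_het) break
          if (length(placed) && min(abs(placed - p)) <= 60L) next
          a1 <- chars[p]
          if (in_homopolymer_run(chars, p, a1, 3L)) next
          alts <- setdiff(BASES, a1)
          ok <- alts[!vapply(alts, function(b)
            in_homopolymer_run(chars, p, b, 3L), NA)]
          if (!length(ok)) next
          a2 <- if (length(ok) == 1L) ok else sample(ok, 1)
          placed <- c(placed, p)
          t_a1 <- c(t_a1, a1)
          t_a2 <- c(t_a2, a2)
          err <- runif(1) < config$ref_error_rate
          if (err) {
            third <- setdiff(BASES, c(a1, a2))
            safe <- third[!vapply(third, function(b)
              in_homopolymer_run(chars, p, b, 3L), NA)]
            if (length(safe)) {
              chars[p] <- if (length(safe) == 1L) safe else sample(safe, 1)
            } else {
              err <- FALSE
            }
          }
          t_err <- c(t_err, err)
        }
      }
    }
    r <- new_reference(ids[i], paste(chars, collapse = ""), qual,
                       annotation = if (genic[i]) "genic" else "nongenic",
                       contig_id = contig[i])
    r$is_repeat <- is_rep[i]
    refs[[i]] <- r
    if (length(placed)) {
      o <- order(placed)
      truth_rows[[i]] <- data.frame(
        ref_id = ids[i], pos = placed[o], allele1 = t_a1[o], allele2 = t_a2[o],
        ref_error = t_err[o], repeat_ref = is_rep[i],
        annotation = if (genic[i]) "genic" else "nongenic",
        stringsAsFactors = FALSE)
    }
  }
  names(refs) <- ids
  truth <- do.call(rbind, truth_rows[!vapply(truth_rows, is.null, NA)])
  if (is.null(truth)) {
    truth <- data.frame(ref_id = character(), pos = integer(),
                        allele1 = character(), allele2 = character(),
                        ref_error = logical(), repeat_ref = logical(),
                        annotation = character(), stringsAsFactors = FALSE)
  }
  list(references = structure(refs, class = "reference_set"), truth = truth)
}

#' Simulate a pileup over simulated references
#'
#' Per reference, a depth level is drawn as `round(Gumbel(mu, beta))`
#' (times the repeat multiplier on repeat references) and jittered
#' per site by +/-10%, so both per-site and per-reference depth summaries
#' are exercisable.  At planted heterozygous sites the variant-allele
#' read count is Binomial(depth, 0.5); at every other site error reads
#' are Binomial(depth, e) with `e = 10^(-Q/10)` from the local reference
#' quality, all assigned to one random non-reference base.  Site mapping
#' quality is Normal(`mqs_mean`, `mqs_sd`) truncated at 0.  Only covered
#' sites (depth > 0) are emitted.
#'
#' @param references `reference_set` from [simulate_references()].
#' @param truth matching truth table.
#' @param config the [sim_config()].
#' @return Pileup data frame (see [read_pileup()]).
#' @export
simulate_pileup <- function(references, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  seed_for(config, "pileup")
  out <- vector("list", length(references))
  for (i in seq_along(references)) {
    r <- references[[i]]
    len <- nchar(r$sequence)
    chars <- strsplit(r$sequence, "")[[1]]
    base_depth <- max(0, round(rgumbel(1, config$depth_mu, config$depth_beta)))
    if (isTRUE(r$is_repeat)) base_depth <- base_depth * config$repeat_depth_multiplier
    depth <- pmax(0L, as.integer(round(base_depth * runif(len, 0.9, 1.1))))
    counts <- matrix(0L, len, 4, dimnames = list(NULL, BASES))
    ref_idx <- match(chars, BASES)
    # sequencing errors everywhere, driven by local Phred
    e <- 10^(-r$base_quality / 10)
    n_err <- rbinom(len, depth, e)
    err_base_off <- sample.int(3L, len, replace = TRUE)  # offset among non-ref bases
    counts[cbind(seq_len(len), ref_idx)] <- depth - n_err
    err_idx <- ((ref_idx - 1L + err_base_off) %% 4L) + 1L
    has_err <- n_err > 0L
    counts[cbind(which(has_err), err_idx[has_err])] <-
      counts[cbind(which(has_err), err_idx[has_err])] + n_err[has_err]
    # planted het sites: overwrite with Binomial(depth, 0.5) allele split
    tr <- truth[truth$ref_id == r$id, , drop = FALSE]
    if (nrow(tr)) {
      for (k in seq_len(nrow(tr))) {
        p <- tr$pos[k]
        d <- depth[p]
        counts[p, ] <- 0L
        if (d > 0L) {
          n2 <- rbinom(1, d, 0.5)
          counts[p, tr$allele1[k]] <- d - n2
          counts[p, tr$allele2[k]] <- counts[p, tr$allele2[k]] + n2
        }
      }
    }
    keep <- depth > 0L
    if (!any(keep)) next
    out[[i]] <- data.frame(
      ref_id = r$id, pos = which(keep), ref_base = chars[keep],
      depth = depth[keep], counts[keep, , drop = FALSE],
      mqs = pmax(0, rnorm(sum(keep), config$mqs_mean, config$mqs_sd)),
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, NA)]
  if (!length(out)) return(empty_pileup())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate an F1 cross
#'
#' Draws one Mendelian gamete per parent per marker, then applies
#' genotyping error (call replaced by one of the other two genotypes)
#' and missingness at the configured rates to the progeny.  Parents are
#' included unperturbed as the first two rows.
#'
#' @param parent1_genotypes,parent2_genotypes named character vectors of
#'   `AA`/`AB`/`BB` over the same markers.
#' @param n_progeny number of F1 individuals (default from `config`).
#' @param config the [sim_config()].
#' @param parent_ids row names for the parents.
#' @return Genotype character matrix (2 + n_progeny rows).
#' @export
simulate_cross <- function(parent1_genotypes, parent2_genotypes,
                           n_progeny = config$n_progeny, config,
                           parent_ids = c("P1", "P2")) {
  stopifnot(inherits(config, "sim_config"),
            length(parent1_genotypes) == length(parent2_genotypes),
            all(parent1_genotypes %in% GT_TOKENS),
            all(parent2_genotypes %in% GT_TOKENS))
  seed_for(config, "cross")
  markers <- names(parent1_genotypes) %||%
    sprintf("mk%04d", seq_along(parent1_genotypes))
  m <- length(markers)
  gamete <- function(gt, n) {
    switch(gt,
           AA = rep("A", n),
           BB = rep("B", n),
           AB = ifelse(runif(n) < 0.5, "A", "B"))
  }
  prog <- matrix(NA_character_, n_progeny, m)
  for (j in seq_len(m)) {
    g1 <- gamete(parent1_genotypes[[j]], n_progeny)
    g2 <- gamete(parent2_genotypes[[j]], n_progeny)
    gt <- paste0(pmin(g1, g2), pmax(g1, g2))
    err <- runif(n_progeny) < config$genotyping_error_rate
    if (any(err)) {
      gt[err] <- vapply(gt[err], function(g)
        sample(setdiff(GT_TOKENS, g), 1), "")
    }
    gt[runif(n_progeny) < config$missing_rate] <- NA_character_
    prog[, j] <- gt
  }
  out <- rbind(matrix(c(parent1_genotypes, parent2_genotypes), 2, m,
                      byrow = TRUE),
               prog)
  rownames(out) <- c(parent_ids, sprintf("F1_%03d", seq_len(n_progeny)))
  colnames(out) <- markers
  out
}

#' Simulate a multi-generation pedigree
#'
#' Founders (generation 0) have unknown parents; each later generation
#' adds `n_founders` individuals whose two distinct parents are drawn at
#' random from all earlier generations.
#'
#' @param n_founders founders (and individuals per later generation).
#' @param n_generations number of generations after the founders.
#' @param config the [sim_config()].
#' @return Pedigree data frame (`id`, `sire`, `dam`) with a `generation`
#'   column.
#' @export
simulate_pedigree <- function(n_founders, n_generations, config) {
  stopifnot(inherits(config, "sim_config"), n_founders >= 2,
            n_generations >= 0)
  seed_for(config, "pedigree")
  ped <- data.frame(id = sprintf("G0_%02d", seq_len(n_founders)),
                    sire = NA_character_, dam = NA_character_,
                    generation = 0L, stringsAsFactors = FALSE)
  for (g in seq_len(n_generations)) {
    pool <- ped$id
    rows <- lapply(seq_len(n_founders), function(k) {
      pr <- sample(pool, 2)
      data.frame(id = sprintf("G%d_%02d", g, k), sire = pr[1], dam = pr[2],
                 generation = g, stringsAsFactors = FALSE)
    })
    ped <- rbind(ped, do.call(rbind, rows))
  }
  check_pedigree_acyclic(ped[, c("id", "sire", "dam")])
  ped
}
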