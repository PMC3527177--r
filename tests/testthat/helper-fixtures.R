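# In-code fixtures shared across the suite.

# one reference with uniform quality unless a vector is given
make_ref <- function(id, sequence, qual = 50) {
  if (length(qual) == 1) qual <- rep(qual, nchar(sequence))
  r <- snpstacks:::new_reference(id, sequence, qual)
  structure(setNames(list(r), id), class = "reference_set")
}

ref_set <- function(...) {
  refs <- c(...)
  structure(refs, class = "reference_set")
}

# one pileup row from base counts
pcol <- function(ref_id = "bes1", pos = 10L, ref_base = "A",
                 A = 0L, C = 0L, G = 0L, T = 0L, mqs = 34) {
  data.frame(ref_id = ref_id, pos = as.integer(pos), ref_base = ref_base,
             depth = as.integer(A + C + G + T),
             A = as.integer(A), C = as.integer(C), G = as.integer(G),
             T = as.integer(T), mqs = mqs, stringsAsFactors = FALSE)
}

# minimal annotated candidate row; defaults pass every adjusted filter
cand <- function(ref_id = "bes1", pos = 100L, ref_base = "A", allele1 = "A",
                 allele2 = "G", vf = 0.5, fvf = 0.5, rmd = 20L, mqs = 34,
                 ref_base_quality = 50L, ref_avg_quality = 50,
                 annotation = "genic", ref_error_inferred = FALSE) {
  data.frame(ref_id = ref_id, pos = as.integer(pos), ref_base = ref_base,
             allele1 = allele1, allele2 = allele2, vf = vf, fvf = fvf,
             rmd = as.integer(rmd), mqs = mqs,
             ref_base_quality = as.integer(ref_base_quality),
             ref_avg_quality = ref_avg_quality, annotation = annotation,
             ref_error_inferred = ref_error_inferred, t_stat = NA_real_,
             filter_flags = "", pfalse = NA_real_,
             infinium_type = NA_character_, design_score = NA_real_,
             stringsAsFactors = FALSE)
}

# a long non-homopolymeric reference: periodic ACGT
acgt_ref <- function(id = "bes1", len = 700, qual = 50) {
  make_ref(id, paste(rep(c("A", "C", "G", "T"), length.out = len),
                     collapse = ""), qual)
}
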