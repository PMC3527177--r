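# Readers/writers for the external formats the pipeline touches.
# Conventions used throughout the package:
#   * coordinates are 1-based and inclusive (pileup/VCF convention);
#   * read stacks are strand-collapsed: base counts refer to the reference
#     forward strand;
#   * Phred base qualities are integers in [0, 93].

PHRED_MAX <- 93L

#' Reference sequences with per-base Phred quality
#'
#' Reads a FASTA file and its companion QUAL file (FASTA-style headers,
#' whitespace-separated Phred integers) into a reference set: a named list
#' with one record per sequence holding `id`, `sequence` (uppercase DNA),
#' `base_quality` (integer vector, same length), `annotation` (one of
#' `"genic"`, `"nongenic"`, `"unknown"`), optional `contig_id`, and
#' `avg_quality` (mean Phred).
#'
#' FASTA and QUAL records must match one-to-one by id and per-record
#' lengths must agree; a mismatch is an error naming the offending record.
#'
#' @param fasta_path path to a FASTA file.
#' @param qual_path path to the matching QUAL file.
#' @return An object of class `reference_set`: named list of records.
#' @seealso [write_references()], [read_annotation()]
#' @export
read_references <- function(fasta_path, qual_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- names(seqs)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  quals <- read_qual(qual_path)
  missing_q <- setdiff(ids, names(quals))
  if (length(missing_q)) {
    stop("record(s) present in FASTA but absent in QUAL: ",
         paste(missing_q, collapse = ", "))
  }
  extra_q <- setdiff(names(quals), ids)
  if (length(extra_q)) {
    stop("record(s) present in QUAL but absent in FASTA: ",
         paste(extra_q, collapse = ", "))
  }
  refs <- lapply(ids, function(id) {
    sq <- toupper(as.character(seqs[[id]]))
    q <- quals[[id]]
    if (nchar(sq) != length(q)) {
      stop("length mismatch for record '", id, "': sequence ", nchar(sq),
           " bp vs ", length(q), " quality values")
    }
    new_reference(id, sq, q)
  })
  names(refs) <- ids
  structure(refs, class = "reference_set")
}

new_reference <- function(id, sequence, base_quality,
                          annotation = "unknown", contig_id = NA_character_) {
  base_quality <- as.integer(base_quality)
  if (any(base_quality < 0L | base_quality > PHRED_MAX)) {
    stop("Phred quality out of [0, ", PHRED_MAX, "] in record '", id, "'")
  }
  list(id = id, sequence = sequence, base_quality = base_quality,
       annotation = annotation, contig_id = contig_id,
       avg_quality = mean(base_quality))
}

# QUAL is a FASTA-shaped file whose body lines are whitespace-separated
# Phred integers.  No established R reader returns them as integers, so the
# few lines of parsing live here.
read_qual <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no records in QUAL file '", path, "'")
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  ends <- c(hdr[-1] - 1L, length(lines))
  quals <- lapply(seq_along(hdr), function(i) {
    body <- lines[seq(hdr[i] + 1L, ends[i])]
    body <- body[nzchar(trimws(body))]
    vals <- suppressWarnings(as.integer(unlist(strsplit(trimws(body), "\\s+"))))
    if (anyNA(vals)) stop("non-integer quality value in record '", ids[i], "'")
    vals
  })
  names(quals) <- ids
  quals
}

#' Write a reference set back to FASTA + QUAL
#'
#' @param refs a `reference_set` from [read_references()] or
#'   [simulate_references()].
#' @param fasta_path,qual_path output paths.
#' @return Invisibly, `refs`.
#' @export
write_references <- function(refs, fasta_path, qual_path) {
  dss <- Biostrings::DNAStringSet(vapply(refs, `[[`, "", "sequence"))
  names(dss) <- vapply(refs, `[[`, "", "id")
  Biostrings::writeXStringSet(dss, fasta_path)
  con <- file(qual_path, "w")
  on.exit(close(con))
  for (r in refs) {
    writeLines(paste0(">", r$id), con)
    writeLines(paste(r$base_quality, collapse = " "), con)
  }
  invisible(refs)
}

#' Read per-site read-stack summaries (pileup)
#'
#' Parses per-site read-stack summaries into a data frame of pileup
#' columns with fields `ref_id`, `pos` (1-based), `ref_base`, `depth`
#' (read mapping depth, RMD), per-base counts `A`, `C`, `G`, `T`, and the
#' site-level mapping quality score `mqs`.
#'
#' Two dialects are supported.  The canonical `"tsv"` dialect has seven
#' columns: ref_id, pos, ref_base, depth, packed counts `"A,C,G,T"`, mqs.
#' The `"mpileup"` dialect is a best-effort parser for the samtools text
#' pileup (6 columns; base string decoded against the reference base, mqs
#' taken as the RMS of the read base qualities column re-used as a
#' site-level score when no mapping-quality column is present).
#'
#' Every row is validated: base counts must sum to `depth`, otherwise an
#' error names the offending `ref_id:pos`.
#'
#' @param path input file.
#' @param dialect `"tsv"` (canonical, default) or `"mpileup"`.
#' @return A `data.frame` of pileup columns.
#' @export
read_pileup <- function(path, dialect = c("tsv", "mpileup")) {
  dialect <- match.arg(dialect)
  if (file.size(path) == 0) return(empty_pileup())
  if (dialect == "tsv") {
    df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                     col.names = c("ref_id", "pos", "ref_base", "depth",
                                   "counts", "mqs"),
                     colClasses = c("character", "integer", "character",
                                    "integer", "character", "numeric"))
    cnt <- do.call(rbind, lapply(strsplit(df$counts, ","), as.integer))
    if (ncol(cnt) != 4L) stop("packed counts must have 4 comma-separated fields")
    colnames(cnt) <- BASES
    out <- data.frame(ref_id = df$ref_id, pos = df$pos, ref_base = df$ref_base,
                      depth = df$depth, cnt, mqs = df$mqs,
                      stringsAsFactors = FALSE)
  } else {
    out <- parse_mpileup(path)
  }
  validate_pileup(out)
  out
}

empty_pileup <- function() {
  data.frame(ref_id = character(), pos = integer(), ref_base = character(),
             depth = integer(), A = integer(), C = integer(), G = integer(),
             T = integer(), mqs = numeric(), stringsAsFactors = FALSE)
}

validate_pileup <- function(df) {
  stopifnot(all(c("ref_id", "pos", "ref_base", "depth", BASES, "mqs") %in% names(df)))
  if (any(df$pos < 1L)) stop("pileup positions must be >= 1")
  if (any(df$depth < 0L)) stop("negative depth in pileup")
  if (any(df$mqs < 0)) stop("negative mapping quality in pileup")
  tot <- df$A + df$C + df$G + df$T
  bad <- which(tot != df$depth)
  if (length(bad)) {
    stop("base counts do not sum to depth at ",
         df$ref_id[bad[1]], ":", df$pos[bad[1]],
         " (", tot[bad[1]], " vs ", df$depth[bad[1]], ")")
  }
  invisible(df)
}

# Best-effort decoder for the samtools text pileup base string: handles
# match (. ,), substitutions, read starts (^X), ends ($), indels (+n/-n
# followed by n bases) and deletion placeholders (*), strand-collapsed.
parse_mpileup <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t")[[1]]
    if (length(f) < 5L) stop("mpileup line with fewer than 5 fields")
    ref_base <- toupper(f[3])
    bases <- decode_mpileup_bases(f[5], ref_base)
    depth <- as.integer(f[4])
    # indel/deletion placeholders mean the decoded stack can be smaller
    # than the reported depth; the decoded stack is authoritative here
    depth <- sum(bases)
    mqs <- if (length(f) >= 7L) {
      q <- utf8ToInt(f[7]) - 33
      sqrt(mean(q^2))
    } else if (length(f) >= 6L) {
      q <- utf8ToInt(f[6]) - 33
      sqrt(mean(q^2))
    } else NA_real_
    data.frame(ref_id = f[1], pos = as.integer(f[2]), ref_base = ref_base,
               depth = depth, A = bases[["A"]], C = bases[["C"]],
               G = bases[["G"]], T = bases[["T"]], mqs = mqs,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

decode_mpileup_bases <- function(s, ref_base) {
  chars <- strsplit(s, "")[[1]]
  counts <- setNames(integer(4), BASES)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      i <- i + 2L            # caret + mapping quality char
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch %in% c("+", "-")) {
      j <- i + 1L
      while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len
    } else if (ch %in% c(".", ",")) {
      counts[ref_base] <- counts[ref_base] + 1L
      i <- i + 1L
    } else if (toupper(ch) %in% BASES) {
      counts[toupper(ch)] <- counts[toupper(ch)] + 1L
      i <- i + 1L
    } else {
      i <- i + 1L            # '*', '<', '>' and other placeholders
    }
  }
  counts
}

#' Write a pileup data frame in the canonical TSV dialect
#'
#' @param pileup data frame as returned by [read_pileup()].
#' @param path output path.
#' @return Invisibly, `pileup`.
#' @export
write_pileup <- function(pileup, path) {
  validate_pileup(pileup)
  out <- data.frame(pileup$ref_id, pileup$pos, pileup$ref_base, pileup$depth,
                    paste(pileup$A, pileup$C, pileup$G, pileup$T, sep = ","),
                    pileup$mqs)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(pileup)
}

#' Read a genic/non-genic annotation table
#'
#' Two-column TSV mapping reference id to `genic` or `nongenic`.  Any
#' other token is an error; duplicated ids with conflicting labels are an
#' error.  References absent from the table simply stay `unknown`.
#'
#' @param path input file.
#' @return Named character vector (values `"genic"`/`"nongenic"`).
#' @export
read_annotation <- function(path) {
  if (file.size(path) == 0) return(setNames(character(), character()))
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("ref_id", "annotation"),
                   colClasses = c("character", "character"))
  bad <- setdiff(unique(df$annotation), c("genic", "nongenic"))
  if (length(bad)) {
    stop("annotation token(s) outside {genic, nongenic}: ",
         paste(bad, collapse = ", "))
  }
  if (anyDuplicated(df$ref_id)) {
    tab <- tapply(df$annotation, df$ref_id, function(x) length(unique(x)))
    conflict <- names(tab)[tab > 1]
    if (length(conflict)) {
      stop("conflicting annotation for: ", paste(conflict, collapse = ", "))
    }
    df <- df[!duplicated(df$ref_id), ]
  }
  setNames(df$annotation, df$ref_id)
}

#' Write an annotation table
#' @param annotation named character vector as from [read_annotation()].
#' @param path output path.
#' @return Invisibly, `annotation`.
#' @export
write_annotation <- function(annotation, path) {
  write.table(data.frame(names(annotation), unname(annotation)), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(annotation)
}

#' Write candidate SNPs as minimal VCF 4.2
#'
#' One row per candidate; `CHROM` is the reference id, `POS` 1-based.
#' INFO carries the pipeline statistics (`VF`, `FVF`, `RMD`, `MQS`,
#' `REFQ`, `ANN`, and when present `ITYPE`, `PFALSE`).  The FILTER column
#' holds `PASS` or the name of the first failing filter in cascade order.
#'
#' @param snps candidate SNP data frame (see [call_candidates()]).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(snps, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=snpstacks",
    "##INFO=<ID=VF,Number=1,Type=Float,Description=\"Variant frequency\">",
    "##INFO=<ID=FVF,Number=1,Type=Float,Description=\"Folded variant frequency\">",
    "##INFO=<ID=RMD,Number=1,Type=Integer,Description=\"Read mapping depth\">",
    "##INFO=<ID=MQS,Number=1,Type=Float,Description=\"Mapping quality score\">",
    "##INFO=<ID=REFQ,Number=1,Type=Integer,Description=\"Reference base Phred quality at site\">",
    "##INFO=<ID=ANN,Number=1,Type=String,Description=\"Reference annotation (genic/nongenic/unknown)\">",
    "##INFO=<ID=ITYPE,Number=1,Type=String,Description=\"Infinium assay type (I/II)\">",
    "##INFO=<ID=PFALSE,Number=1,Type=Float,Description=\"Predicted probability of being a false-positive SNP\">",
    "##INFO=<ID=REFERR,Number=0,Type=Flag,Description=\"Reference base inferred to be a sequencing error\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  lines <- hdr
  if (nrow(snps)) {
    num <- function(x) sub("\\.?0+$", "", sprintf("%.6f", x))
    alt <- ifelse(snps$ref_error_inferred,
                  paste(snps$allele1, snps$allele2, sep = ","),
                  ifelse(snps$allele1 == snps$ref_base,
                         snps$allele2, snps$allele1))
    info <- paste0("VF=", num(snps$vf), ";FVF=", num(snps$fvf),
                   ";RMD=", snps$rmd, ";MQS=", num(snps$mqs),
                   ";REFQ=", snps$ref_base_quality,
                   ";ANN=", snps$annotation)
    if ("infinium_type" %in% names(snps)) {
      has <- !is.na(snps$infinium_type)
      info[has] <- paste0(info[has], ";ITYPE=", snps$infinium_type[has])
    }
    if ("pfalse" %in% names(snps)) {
      has <- !is.na(snps$pfalse)
      info[has] <- paste0(info[has], ";PFALSE=", num(snps$pfalse[has]))
    }
    info[snps$ref_error_inferred] <- paste0(info[snps$ref_error_inferred], ";REFERR")
    filt <- vapply(strsplit(snps$filter_flags, ";"), function(f) {
      if (!length(f) || !nzchar(f[1])) "PASS" else f[1]
    }, "")
    lines <- c(lines, paste(snps$ref_id, snps$pos,
                            paste0(snps$ref_id, "_", snps$pos),
                            snps$ref_base, alt, snps$ref_base_quality,
                            filt, info, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read back the minimal VCF written by [write_vcf()]
#'
#' Restores the core pipeline fields from INFO; intended for round-trip
#' checks and downstream consumption of this package's own output, not as
#' a general VCF parser.
#'
#' @param path VCF file.
#' @return Data frame with one row per record.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines)]
  if (!length(body)) {
    return(data.frame(ref_id = character(), pos = integer(),
                      ref_base = character(), alt = character(),
                      filter = character(), vf = numeric(), fvf = numeric(),
                      rmd = integer(), mqs = numeric(),
                      ref_base_quality = integer(), annotation = character(),
                      stringsAsFactors = FALSE))
  }
  f <- do.call(rbind, strsplit(body, "\t"))
  info_get <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    ifelse(lengths(regmatches(info, gregexpr(paste0("(^|;)", key, "="), info))) > 0,
           sub(paste0(".*", key, "="), "", m), NA_character_)
  }
  info <- f[, 8]
  data.frame(ref_id = f[, 1], pos = as.integer(f[, 2]), ref_base = f[, 4],
             alt = f[, 5], filter = f[, 7],
             vf = as.numeric(info_get(info, "VF")),
             fvf = as.numeric(info_get(info, "FVF")),
             rmd = as.integer(info_get(info, "RMD")),
             mqs = as.numeric(info_get(info, "MQS")),
             ref_base_quality = as.integer(info_get(info, "REFQ")),
             annotation = info_get(info, "ANN"),
             stringsAsFactors = FALSE)
}

GT_TOKENS <- c("AA", "AB", "BB")

#' Read a genotype matrix
#'
#' TSV with samples in rows and markers in columns; first column holds
#' sample ids, header holds marker ids.  Calls must be `AA`, `AB`, `BB`
#' or `NA` (missing).
#'
#' @param path input file.
#' @return Character matrix (rownames = samples, colnames = markers).
#' @export
read_genotypes <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, row.names = 1,
                   stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character", na.strings = "NA")
  m <- as.matrix(df)
  bad <- setdiff(unique(m[!is.na(m)]), GT_TOKENS)
  if (length(bad)) stop("genotype token(s) outside {AA, AB, BB, NA}: ",
                        paste(bad, collapse = ", "))
  m
}

#' Write a genotype matrix
#' @param gt character matrix from [read_genotypes()] or [simulate_cross()].
#' @param path output path.
#' @return Invisibly, `gt`.
#' @export
write_genotypes <- function(gt, path) {
  df <- data.frame(sample = rownames(gt), gt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(gt)
}

#' Read a pedigree table
#'
#' Three-column TSV: individual id, sire id, dam id, with `UNKNOWN` for a
#' missing parent.  The pedigree must be acyclic (no individual is its own
#' ancestor); a cycle is an error.
#'
#' @param path input file.
#' @return Data frame with columns `id`, `sire`, `dam` (`NA` = unknown).
#' @export
read_pedigree <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("id", "sire", "dam"),
                   colClasses = "character")
  df$sire[df$sire == "UNKNOWN"] <- NA_character_
  df$dam[df$dam == "UNKNOWN"] <- NA_character_
  if (anyDuplicated(df$id)) stop("duplicate individual id in pedigree")
  check_pedigree_acyclic(df)
  df
}

#' Write a pedigree table
#' @param ped data frame with columns `id`, `sire`, `dam`.
#' @param path output path.
#' @return Invisibly, `ped`.
#' @export
write_pedigree <- function(ped, path) {
  out <- ped
  out$sire[is.na(out$sire)] <- "UNKNOWN"
  out$dam[is.na(out$dam)] <- "UNKNOWN"
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(ped)
}
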