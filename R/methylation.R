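## Core methylation calling: align trace calls to the in-silico converted
## reference and estimate per-CpG methylation as the bounded C/(C+T)
## peak-amplitude ratio, with coverage flags and conversion QC.

#' In-silico bisulfite conversion of a reference sequence
#'
#' Replaces every C by T; all other characters are unchanged. This is the
#' fully converted, fully unmethylated expectation that bisulfite reads are
#' aligned against.
#'
#' @param reference character scalar over A/C/G/T/N.
#' @return Character scalar of the same length with no C.
#' @export
#' @examples
#' convert_reference("ACGT")  # "ATGT"
convert_reference <- function(reference) {
  if (!grepl("^[ACGTN]*$", toupper(reference)))
    stop("reference contains characters outside A/C/G/T/N")
  gsub("C", "T", toupper(reference), fixed = TRUE)
}

#' Bundle a reference with its converted form, TSS and CpG catalog
#'
#' @param reference character scalar DNA sequence.
#' @param tss_abs_pos 1-based position of the TSS (+1).
#' @param catalog CpG catalog data.frame (`cpg_id`, `abs_pos`, `tss_rel`,
#'   optionally `region_id`); every `abs_pos` must point at the C of a CG
#'   dinucleotide in `reference`.
#' @return An object of class `reference_context`.
#' @export
reference_context <- function(reference, tss_abs_pos, catalog) {
  reference <- toupper(reference)
  bases <- strsplit(reference, "")[[1]]
  if (any(catalog$abs_pos < 1 | catalog$abs_pos >= length(bases)))
    stop("catalog positions outside the reference")
  at <- bases[catalog$abs_pos]
  nxt <- bases[catalog$abs_pos + 1L]
  if (any(at != "C" | nxt != "G"))
    stop("catalog positions must point at the C of a CG dinucleotide")
  if (is.unsorted(catalog$abs_pos, strictly = TRUE))
    stop("catalog must be ordered 5'->3'")
  structure(list(reference = reference,
                 converted = convert_reference(reference),
                 tss_abs_pos = as.integer(tss_abs_pos),
                 catalog = catalog),
            class = "reference_context")
}

#' @export
print.reference_context <- function(x, ...) {
  cat(sprintf("reference_context: %d bp, TSS at %d, %d catalog CpGs\n",
              nchar(x$reference), x$tss_abs_pos, nrow(x$catalog)))
  invisible(x)
}

## -- alignment ---------------------------------------------------------------

#' Align a primary base-call sequence to the converted reference
#'
#' Global alignment of the read against a local stretch of the converted
#' reference (the read is an amplicon of the full promoter), with affine gaps:
#' match +2, mismatch -1, and a gap of length L costing 5 + L. Returns the
#' monotone read-to-reference coordinate map over aligned (non-gap) columns.
#'
#' @param primary character scalar, the primary base calls (length >= 50).
#' @param reference_ctx a [reference_context()].
#' @param min_identity minimum fraction of matching aligned columns (default
#'   0.8); below it the alignment fails with an error.
#' @param min_length minimum read length accepted (default 50, the shortest
#'   stretch worth aligning against a promoter amplicon).
#' @return A list with `map` (data.frame `read_pos`, `ref_pos`), `identity`,
#'   and `score`.
#' @export
align_read <- function(primary, reference_ctx, min_identity = 0.8,
                       min_length = 50) {
  stopifnot(inherits(reference_ctx, "reference_context"))
  if (nchar(primary) < min_length)
    stop("read too short to align (need >= ", min_length, " bases)")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(primary),
    subject = Biostrings::DNAString(reference_ctx$converted),
    type = "global-local", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ref_start <- Biostrings::start(Biostrings::subject(aln))
  read_i <- 0L
  ref_i <- ref_start - 1L
  read_pos <- ref_pos <- integer(0)
  matches <- 0L
  aligned_cols <- 0L
  for (k in seq_along(p)) {
    if (p[k] != "-") read_i <- read_i + 1L
    if (s[k] != "-") ref_i <- ref_i + 1L
    if (p[k] != "-" && s[k] != "-") {
      aligned_cols <- aligned_cols + 1L
      if (p[k] == s[k]) matches <- matches + 1L
      read_pos <- c(read_pos, read_i)
      ref_pos <- c(ref_pos, ref_i)
    }
  }
  identity <- if (aligned_cols > 0) matches / aligned_cols else 0
  if (identity < min_identity)
    stop(sprintf(
      "alignment failure: identity %.3f below min_identity %.3f", identity,
      min_identity))
  list(map = data.frame(read_pos = read_pos, ref_pos = ref_pos),
       identity = identity, score = Biostrings::score(aln))
}

## -- methylation calling -----------------------------------------------------

#' Call per-CpG methylation from peak amplitudes
#'
#' For every catalog CpG covered by the coordinate map, the methylation
#' percentage is `100 * I_C / (I_C + I_T)` from the C and T channel
#' amplitudes at the mapped read position -- the standard direct-bisulfite
#' pooled-molecule estimator. Sites that are unmapped, gapped, or whose
#' summed C+T amplitude falls below `min_total_intensity` are flagged
#' `insufficient` with a missing percentage. Reference cytosines outside a
#' CpG context are excluded from the profile but tallied for conversion QC.
#'
#' @param calls a `base_calls` object from [call_bases()].
#' @param map coordinate map from [align_read()] (the `map` element or the
#'   full return value).
#' @param reference_ctx a [reference_context()].
#' @param min_total_intensity amplitude floor for a usable site; default 10\%
#'   of the read's median per-base total amplitude.
#' @param stage optional stage label carried into the profile.
#' @return A `methylation_profile`: data.frame with columns `sample_id`,
#'   `stage`, `cpg_id`, `region_id`, `percent`, `flag` (`ok`/`insufficient`),
#'   `i_c`, `i_t`.
#' @export
call_methylation <- function(calls, map, reference_ctx,
                             min_total_intensity = NULL, stage = NA_character_) {
  stopifnot(inherits(calls, "base_calls"),
            inherits(reference_ctx, "reference_context"))
  if (is.list(map) && !is.data.frame(map)) map <- map$map
  amp <- calls$per_base_intensity
  if (is.null(min_total_intensity))
    min_total_intensity <- 0.1 * median(rowSums(amp))
  catalog <- reference_ctx$catalog
  if (!any(catalog$abs_pos %in% map$ref_pos))
    stop("coordinate map covers no catalog CpG site")
  n <- nrow(catalog)
  percent <- rep(NA_real_, n)
  flag <- rep("insufficient", n)
  i_c <- i_t <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    hit <- which(map$ref_pos == catalog$abs_pos[k])
    if (length(hit) != 1L) next
    rp <- map$read_pos[hit]
    ic <- amp[rp, "C"]; it <- amp[rp, "T"]
    i_c[k] <- ic; i_t[k] <- it
    if (ic + it >= min_total_intensity && ic + it > 0) {
      percent[k] <- 100 * ic / (ic + it)
      flag[k] <- "ok"
    }
  }
  region <- if (is.null(catalog$region_id)) NA_integer_ else catalog$region_id
  prof <- data.frame(sample_id = calls$sample_id, stage = stage,
                     cpg_id = catalog$cpg_id, region_id = region,
                     percent = percent, flag = flag, i_c = i_c, i_t = i_t,
                     stringsAsFactors = FALSE)
  class(prof) <- c("methylation_profile", "data.frame")
  prof
}

#' Conversion-efficiency QC from non-CpG cytosines
#'
#' Bisulfite chemistry should convert essentially every cytosine outside a
#' CpG context, so the mean T fraction `I_T / (I_C + I_T)` over covered
#' non-CpG reference C positions estimates the conversion rate. A rate below
#' 0.95 earns a warning status; fewer than 5 covered positions makes the QC
#' not evaluable.
#'
#' @inheritParams call_methylation
#' @return A list with `rate`, `n_sites`, and `status` in
#'   `c("pass", "warn", "not_evaluable")`.
#' @export
conversion_qc <- function(calls, map, reference_ctx) {
  stopifnot(inherits(calls, "base_calls"),
            inherits(reference_ctx, "reference_context"))
  if (is.list(map) && !is.data.frame(map)) map <- map$map
  bases <- strsplit(reference_ctx$reference, "")[[1]]
  c_pos <- which(bases == "C")
  non_cpg <- setdiff(c_pos, reference_ctx$catalog$abs_pos)
  covered <- map[map$ref_pos %in% non_cpg, , drop = FALSE]
  if (nrow(covered) < 5L)
    return(list(rate = NA_real_, n_sites = nrow(covered),
                status = "not_evaluable"))
  amp <- calls$per_base_intensity
  ic <- amp[covered$read_pos, "C"]
  it <- amp[covered$read_pos, "T"]
  use <- (ic + it) > 0
  rate <- mean(it[use] / (ic[use] + it[use]))
  list(rate = rate, n_sites = sum(use),
       status = if (rate < 0.95) "warn" else "pass")
}

#' Merge per-amplicon methylation profiles of one sample
#'
#' The promoter is amplified in separate overlapping PCR reactions; each
#' yields its own profile. Per site: a site covered (flag `ok`) by one
#' amplicon only takes that amplicon's value; a site `ok` in both takes the
#' mean percentage; a site `ok` in neither stays `insufficient`.
#'
#' @param profiles list of `methylation_profile` objects for one sample.
#' @return A single merged `methylation_profile`.
#' @export
merge_amplicons <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  ids <- unique(vapply(profiles, function(p) p$sample_id[1], ""))
  if (length(ids) != 1L)
    stop("profiles belong to different samples: ", paste(ids, collapse = ", "))
  stages <- unique(vapply(profiles, function(p) as.character(p$stage[1]), ""))
  if (length(stages) != 1L)
    stop("profiles carry conflicting stage labels: ",
         paste(stages, collapse = ", "))
  base <- profiles[[1]]
  for (p in profiles[-1]) {
    if (!identical(p$cpg_id, base$cpg_id))
      stop("profiles must share the same catalog")
  }
  n <- nrow(base)
  percent <- rep(NA_real_, n); flag <- rep("insufficient", n)
  i_c <- i_t <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    vals <- vapply(profiles, function(p) p$percent[k], numeric(1))
    oks <- vapply(profiles, function(p) p$flag[k] == "ok", logical(1))
    if (any(oks)) {
      percent[k] <- mean(vals[oks])
      flag[k] <- "ok"
      i_c[k] <- mean(vapply(profiles, function(p) p$i_c[k], numeric(1))[oks])
      i_t[k] <- mean(vapply(profiles, function(p) p$i_t[k], numeric(1))[oks])
    }
  }
  out <- base
  out$percent <- percent; out$flag <- flag; out$i_c <- i_c; out$i_t <- i_t
  out
}

#' Write / read methylation profiles as TSV
#'
#' @param profiles a `methylation_profile` (or several row-bound).
#' @param path file path.
#' @export
write_profiles <- function(profiles, path) {
  write.table(as.data.frame(profiles), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  class(df) <- c("methylation_profile", "data.frame")
  df
}
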