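## PWM scanning with a MATCH-style matrix similarity score (MSS):
## information-weighted position frequencies, min-max normalised to [0, 1],
## with a deficit cut-off (accept sites scoring >= 1 - deficit).

.pwm_finalize <- function(counts, matrix_id, factor_name, pseudocount = 0.8,
                          background = rep(0.25, 4)) {
  stopifnot(nrow(counts) == 4)
  rownames(counts) <- c("A", "C", "G", "T")
  totals <- colSums(counts)
  freqs <- sweep(counts + pseudocount * background,
                 2, totals + pseudocount, "/")
  info <- colSums(freqs * log(4 * freqs))
  col_min <- apply(freqs, 2, min)
  col_max <- apply(freqs, 2, max)
  structure(list(matrix_id = matrix_id, factor_name = factor_name,
                 freqs = freqs, info_weights = info,
                 score_min = sum(info * col_min),
                 score_max = sum(info * col_max),
                 width = ncol(counts)),
            class = "pwm_model")
}

#' @export
print.pwm_model <- function(x, ...) {
  cat(sprintf("pwm_model %s (%s): %d positions\n", x$matrix_id,
              x$factor_name, x$width))
  invisible(x)
}

#' Read JASPAR-format position frequency matrices
#'
#' Parses the JASPAR text format: a `>ID NAME` header followed by four base
#' rows (`A [ 4 19 0 ] ...` or bare numbers). Counts are converted to
#' frequencies with a total pseudocount (default 0.8) split by a uniform
#' background, and the information weights and score extremes of the
#' MATCH-style score are precomputed.
#'
#' @param path path to a JASPAR .jaspar/.pfm text file.
#' @param pseudocount total pseudocount added per column (default 0.8).
#' @return A named list of `pwm_model` objects (names = matrix ids).
#' @export
read_jaspar <- function(path, pseudocount = 0.8) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  headers <- grep("^>", lines)
  if (!length(headers)) stop("JASPAR format error: no '>' header found")
  out <- list()
  bounds <- c(headers, length(lines) + 1L)
  for (h in seq_along(headers)) {
    hdr <- sub("^>\\s*", "", lines[headers[h]])
    parts <- strsplit(trimws(hdr), "\\s+")[[1]]
    matrix_id <- parts[1]
    factor_name <- if (length(parts) >= 2) parts[2] else parts[1]
    body <- lines[(headers[h] + 1L):(bounds[h + 1L] - 1L)]
    if (length(body) != 4L)
      stop("JASPAR format error: matrix ", matrix_id,
           " must have exactly 4 base rows, found ", length(body))
    rows <- lapply(body, function(ln) {
      ln2 <- gsub("[][]", " ", ln)
      toks <- strsplit(trimws(ln2), "\\s+")[[1]]
      base <- NA_character_
      if (toks[1] %in% c("A", "C", "G", "T")) {
        base <- toks[1]; toks <- toks[-1]
      }
      vals <- suppressWarnings(as.numeric(toks))
      if (anyNA(vals))
        stop("JASPAR format error: non-numeric counts in matrix ", matrix_id)
      list(base = base, vals = vals)
    })
    lens <- lengths(lapply(rows, `[[`, "vals"))
    if (length(unique(lens)) != 1L)
      stop("JASPAR format error: rows of unequal length in matrix ",
           matrix_id)
    bases <- vapply(rows, `[[`, "", "base")
    counts <- do.call(rbind, lapply(rows, `[[`, "vals"))
    if (!anyNA(bases)) {
      if (!setequal(bases, c("A", "C", "G", "T")))
        stop("JASPAR format error: missing base row in matrix ", matrix_id)
      counts <- counts[match(c("A", "C", "G", "T"), bases), , drop = FALSE]
    }
    if (any(counts < 0))
      stop("JASPAR format error: negative counts in matrix ", matrix_id)
    out[[matrix_id]] <- .pwm_finalize(counts, matrix_id, factor_name,
                                      pseudocount)
  }
  out
}

#' MATCH-style matrix similarity score of one site
#'
#' `current = sum_i I(i) * f(i, site_i)` with information weights
#' `I(i) = sum_b f(i, b) * ln(4 f(i, b))`; the score is min-max normalised to
#' \[0, 1\] using the precomputed extremes, so the consensus site scores 1
#' and the anti-consensus site scores 0. A degenerate matrix whose extremes
#' coincide scores 1 by convention. Sites containing N are skipped
#' (`NA` returned).
#'
#' @param pwm a `pwm_model` from [read_jaspar()].
#' @param site character scalar of length `pwm$width` over A/C/G/T.
#' @return Numeric scalar in \[0, 1\], or `NA` for sites containing N.
#' @export
matrix_similarity_score <- function(pwm, site) {
  stopifnot(inherits(pwm, "pwm_model"))
  s <- strsplit(toupper(site), "")[[1]]
  if (length(s) != pwm$width)
    stop("site length must equal the matrix width")
  if (any(s == "N")) return(NA_real_)
  if (!all(s %in% c("A", "C", "G", "T")))
    stop("site contains characters outside A/C/G/T/N")
  ri <- match(s, rownames(pwm$freqs))
  current <- sum(pwm$info_weights * pwm$freqs[cbind(ri, seq_along(s))])
  denom <- pwm$score_max - pwm$score_min
  if (denom <= 0) return(1)
  (current - pwm$score_min) / denom
}

.revcomp <- function(seq) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(toupper(seq), "")[[1]]),
                               collapse = ""))
}

#' Scan a sequence for PWM hits
#'
#' Scores every window of every matrix on the requested strands and reports
#' hits whose matrix similarity score reaches `1 - deficit`, sorted by
#' `(start, factor_name)`. Minus-strand windows are scored on the reverse
#' complement; `start` always refers to the plus-strand coordinate of the
#' window's first base.
#'
#' @param pwms list of `pwm_model` objects (from [read_jaspar()]).
#' @param seq character scalar DNA sequence.
#' @param deficit score deficit accepted below the maximum (default 0.15,
#'   i.e. hits need MSS >= 0.85).
#' @param strands subset of `c("+", "-")`; default plus strand only.
#' @return data.frame with columns `matrix_id`, `factor_name`, `start`,
#'   `strand`, `mss`, `site`.
#' @export
scan_sequence <- function(pwms, seq, deficit = 0.15, strands = "+") {
  stopifnot(all(strands %in% c("+", "-")), deficit >= 0, deficit <= 1)
  if (inherits(pwms, "pwm_model")) pwms <- list(pwms)
  seq <- toupper(seq)
  L <- nchar(seq)
  rows <- list()
  for (pwm in pwms) {
    w <- pwm$width
    if (w > L) next
    for (start in seq_len(L - w + 1L)) {
      win <- substr(seq, start, start + w - 1L)
      for (strand in strands) {
        site <- if (strand == "+") win else .revcomp(win)
        mss <- matrix_similarity_score(pwm, site)
        if (!is.na(mss) && mss >= 1 - deficit) {
          rows[[length(rows) + 1L]] <- data.frame(
            matrix_id = pwm$matrix_id, factor_name = pwm$factor_name,
            start = start, strand = strand, mss = mss, site = site,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(matrix_id = character(0), factor_name = character(0),
                      start = integer(0), strand = character(0),
                      mss = numeric(0), site = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$start, out$factor_name), , drop = FALSE]
}

#' Read a regulator annotation/expression table
#'
#' TSV with columns `factor`, `activity` (one of `activator`, `repressor`,
#' `both`) and `ntpm` (normalized transcripts per million, >= 0).
#'
#' @param path file path.
#' @return data.frame with those columns.
#' @export
read_regulator_annotation <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("factor", "activity", "ntpm")
  if (!all(need %in% names(df)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  if (!all(df$activity %in% c("activator", "repressor", "both")))
    stop("activity must be one of activator/repressor/both")
  if (any(df$ntpm < 0)) stop("ntpm must be >= 0")
  df
}

#' Classify predicted regulators by activity and expression
#'
#' Collapses hits to distinct factors (multiple sites and matrix versions of
#' one factor count once), tallies them by activity class, and returns the
#' focus list of repressors (activity `repressor` or `both`) expressed at or
#' above `min_ntpm`.
#'
#' @param hits data.frame from [scan_sequence()].
#' @param annotation data.frame from [read_regulator_annotation()].
#' @param min_ntpm expression floor for the repressor focus list (default 0).
#' @return A list with `n_factors`, `counts` (named: activator, repressor,
#'   both), `factors` (per-factor table), `expressed_repressors`
#'   (data.frame), and `unannotated` (character).
#' @export
classify_regulators <- function(hits, annotation, min_ntpm = 0) {
  factors <- unique(hits$factor_name)
  ann <- annotation[match(factors, annotation$factor), , drop = FALSE]
  unannotated <- factors[is.na(ann$factor)]
  known <- ann[!is.na(ann$factor), , drop = FALSE]
  counts <- c(activator = sum(known$activity == "activator"),
              repressor = sum(known$activity == "repressor"),
              both = sum(known$activity == "both"))
  rep_rows <- known[known$activity %in% c("repressor", "both") &
                      known$ntpm >= min_ntpm, , drop = FALSE]
  rep_rows <- rep_rows[order(-rep_rows$ntpm), , drop = FALSE]
  list(n_factors = length(factors), counts = counts, factors = known,
       expressed_repressors = rep_rows, unannotated = unannotated)
}
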