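## Sliding-window CpG island detection with the Gardiner-Garden-Frommer
## composition criteria (GC >= 50%, observed/expected CpG >= 0.6), plus an
## island-vs-islet classification by span length.

#' GC content and observed/expected CpG ratio of one window
#'
#' `gc_percent = 100 * (N_C + N_G) / L`;
#' `obs_exp = (N_CpG * L) / (N_C * N_G)`, defined as 0 when the window has no
#' C or no G. A CG dinucleotide is counted only when both bases lie inside
#' the window.
#'
#' @param seq character scalar DNA sequence.
#' @param start 1-based window start.
#' @param window window length in bp.
#' @return Named numeric vector `c(gc_percent, obs_exp)`.
#' @export
window_stats <- function(seq, start = 1L, window = nchar(seq)) {
  L <- nchar(seq)
  if (window > L) stop("window longer than the sequence")
  if (start < 1 || start + window - 1 > L)
    stop("window falls outside the sequence")
  w <- substr(seq, start, start + window - 1L)
  n_c <- lengths(regmatches(w, gregexpr("C", w, fixed = TRUE)))
  n_g <- lengths(regmatches(w, gregexpr("G", w, fixed = TRUE)))
  n_cpg <- length(.find_cg(w))
  gc <- 100 * (n_c + n_g) / window
  oe <- if (n_c * n_g == 0) 0 else (n_cpg * window) / (n_c * n_g)
  c(gc_percent = gc, obs_exp = oe)
}

#' Detect CpG islands and islets by sliding window
#'
#' Slides a window of `window` bp by 1 along the sequence; a start position
#' passes when both composition thresholds hold. A candidate region is a
#' maximal run of consecutive passing starts, spanning from the first passing
#' start to the last passing start plus `window - 1`. Candidates whose span
#' reaches `minlen` are reported with their mean window statistics, sorted by
#' start. Spans of at least 200 bp are classed `island`; shorter ones
#' (>= 100 bp) are `islet`.
#'
#' @param seq character scalar DNA sequence.
#' @param window sliding-window size in bp (default 100).
#' @param minlen minimum reported span (default 200; use 100 to admit
#'   islets).
#' @param min_oe minimum observed/expected CpG ratio (default 0.6).
#' @param min_gc minimum GC percentage (default 50).
#' @return data.frame with columns `start`, `end` (1-based inclusive),
#'   `length`, `mean_gc`, `mean_obs_exp`, `n_cpg`, `klass`.
#' @export
find_cpg_islands <- function(seq, window = 100L, minlen = 200L,
                             min_oe = 0.6, min_gc = 50) {
  L <- nchar(seq)
  if (window > L) stop("window longer than the sequence")
  bases <- strsplit(toupper(seq), "")[[1]]
  is_c <- bases == "C"
  is_g <- bases == "G"
  is_cg <- c(is_c[-L] & is_g[-1], FALSE)
  cum_c <- cumsum(is_c); cum_g <- cumsum(is_g); cum_cg <- cumsum(is_cg)
  starts <- seq_len(L - window + 1L)
  n_c <- cum_c[starts + window - 1L] - c(0, cum_c)[starts]
  n_g <- cum_g[starts + window - 1L] - c(0, cum_g)[starts]
  # CG counted only when both bases are inside: C at most at window end - 1
  n_cpg <- cum_cg[starts + window - 2L] - c(0, cum_cg)[starts]
  gc <- 100 * (n_c + n_g) / window
  oe <- ifelse(n_c * n_g == 0, 0, n_cpg * window / (n_c * n_g))
  pass <- gc >= min_gc & oe >= min_oe
  if (!any(pass)) return(.empty_island_calls())
  r <- rle(pass)
  ends_run <- cumsum(r$lengths)
  starts_run <- ends_run - r$lengths + 1L
  keep <- which(r$values)
  # candidate spans from maximal runs of passing starts; nearby runs whose
  # window spans overlap are merged into one call so calls never overlap
  cand <- data.frame(a = starts[starts_run[keep]],
                     b = starts[ends_run[keep]] + window - 1L,
                     i0 = starts_run[keep], i1 = ends_run[keep])
  merged <- list()
  cur <- cand[1, ]
  if (nrow(cand) > 1) for (j in 2:nrow(cand)) {
    if (cand$a[j] <= cur$b) {
      cur$b <- max(cur$b, cand$b[j]); cur$i1 <- cand$i1[j]
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- cand[j, ]
    }
  }
  merged[[length(merged) + 1L]] <- cur
  rows <- list()
  for (m in merged) {
    span <- m$b - m$a + 1L
    if (span < minlen) next
    idx <- (m$i0:m$i1)[pass[m$i0:m$i1]]
    n_cg_span <- cum_cg[m$b - 1L] - c(0, cum_cg)[m$a]
    rows[[length(rows) + 1L]] <- data.frame(
      start = m$a, end = m$b, length = span,
      mean_gc = mean(gc[idx]), mean_obs_exp = mean(oe[idx]),
      n_cpg = n_cg_span,
      klass = if (span >= 200L) "island" else "islet",
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(.empty_island_calls())
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

.empty_island_calls <- function() {
  data.frame(start = integer(0), end = integer(0), length = integer(0),
             mean_gc = numeric(0), mean_obs_exp = numeric(0),
             n_cpg = integer(0), klass = character(0),
             stringsAsFactors = FALSE)
}

#' Write island calls as a BED-like TSV
#'
#' Emits both 0-based half-open (`bed_start`, `bed_end`) and 1-based
#' inclusive (`start_1based`, `end_1based`) coordinates.
#'
#' @param calls data.frame from [find_cpg_islands()].
#' @param path output file.
#' @param seqname sequence name for the first column.
#' @export
write_island_bed <- function(calls, path, seqname = "promoter") {
  out <- data.frame(seqname = rep(seqname, nrow(calls)),
                    bed_start = calls$start - 1L, bed_end = calls$end,
                    start_1based = calls$start, end_1based = calls$end,
                    length = calls$length,
                    mean_gc = round(calls$mean_gc, 2),
                    mean_obs_exp = round(calls$mean_obs_exp, 3),
                    n_cpg = calls$n_cpg, klass = calls$klass)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
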