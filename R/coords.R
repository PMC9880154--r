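## TSS-relative coordinates use the molecular-biology convention without a
## position zero: +1 is the first transcribed base, -1 the base immediately
## upstream.  abs coordinates are 1-based along the studied sequence.

#' Convert absolute to TSS-relative coordinates
#'
#' @param abs_pos integer vector of 1-based absolute positions.
#' @param tss_abs_pos 1-based absolute position of the TSS (+1).
#' @return Integer vector of TSS-relative positions (no zero).
#' @export
#' @examples
#' tss_relative(c(841, 842), 842)  # -1, +1
tss_relative <- function(abs_pos, tss_abs_pos) {
  stopifnot(is.numeric(abs_pos), length(tss_abs_pos) == 1L, tss_abs_pos >= 1)
  as.integer(ifelse(abs_pos < tss_abs_pos,
                    abs_pos - tss_abs_pos,
                    abs_pos - tss_abs_pos + 1L))
}

#' Convert TSS-relative to absolute coordinates
#'
#' @param rel_pos integer vector of TSS-relative positions (no zero allowed).
#' @inheritParams tss_relative
#' @return Integer vector of 1-based absolute positions.
#' @export
tss_absolute <- function(rel_pos, tss_abs_pos) {
  if (any(rel_pos == 0))
    stop("TSS-relative coordinates have no position 0")
  as.integer(ifelse(rel_pos < 0,
                    tss_abs_pos + rel_pos,
                    tss_abs_pos + rel_pos - 1L))
}
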