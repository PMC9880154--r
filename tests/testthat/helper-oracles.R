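# Independent oracles used to freeze expected values. Each reimplements the
# quantity from first principles (loops, enumeration, textbook formulas) and
# stays independent of the package code paths it checks.

# direct-count window composition
oracle_window_stats <- function(seq, start, window) {
  chars <- strsplit(seq, "")[[1]][start:(start + window - 1)]
  n_c <- 0; n_g <- 0; n_cpg <- 0
  for (i in seq_along(chars)) {
    if (chars[i] == "C") n_c <- n_c + 1
    if (chars[i] == "G") n_g <- n_g + 1
    if (i < length(chars) && chars[i] == "C" && chars[i + 1] == "G")
      n_cpg <- n_cpg + 1
  }
  gc <- 100 * (n_c + n_g) / window
  oe <- if (n_c * n_g == 0) 0 else n_cpg * window / (n_c * n_g)
  c(gc_percent = gc, obs_exp = oe)
}

# Gotoh DP for pattern-global / subject-local affine alignment:
# match +2, mismatch -1, a gap of length L costs open + L * ext
oracle_align_score <- function(pattern, subject, match = 2, mismatch = -1,
                               open = 5, ext = 1) {
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  n <- length(p); m <- length(s)
  NEG <- -1e9
  H <- matrix(NEG, n + 1, m + 1)  # best ending in match/mismatch state
  E <- matrix(NEG, n + 1, m + 1)  # gap in pattern (subject consumed)
  F <- matrix(NEG, n + 1, m + 1)  # gap in subject (pattern consumed)
  H[1, ] <- 0                     # free subject prefix
  for (i in 2:(n + 1)) {
    F[i, 1] <- -(open + (i - 1) * ext)
    H[i, 1] <- F[i, 1]
  }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sub <- if (p[i - 1] == s[j - 1]) match else mismatch
      E[i, j] <- max(H[i, j - 1] - (open + ext), E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - (open + ext), F[i - 1, j] - ext)
      H[i, j] <- max(H[i - 1, j - 1] + sub, E[i, j], F[i, j])
    }
  }
  max(H[n + 1, ])                 # free subject suffix
}

# information-weighted MATCH score by direct per-site summation, with the
# score extremes found by exhaustive enumeration over all sites
oracle_mss_enumerated <- function(freqs) {
  w <- ncol(freqs)
  info <- numeric(w)
  for (j in 1:w) for (b in rownames(freqs))
    info[j] <- info[j] + freqs[b, j] * log(4 * freqs[b, j])
  raw_score <- function(site) {
    tot <- 0
    for (j in 1:w) tot <- tot + info[j] * freqs[site[j], j]
    tot
  }
  sites <- expand.grid(rep(list(c("A", "C", "G", "T")), w),
                       stringsAsFactors = FALSE)
  raw <- apply(sites, 1, raw_score)
  lo <- min(raw); hi <- max(raw)
  mss <- if (hi > lo) (raw - lo) / (hi - lo) else rep(1, length(raw))
  list(sites = apply(sites, 1, paste, collapse = ""), mss = mss,
       score_min = lo, score_max = hi)
}

oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * pt(-abs(t), df)
  c(t = t, p = p, df = df)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / (sqrt(sum((x - mean(x))^2) / (n - 1)) *
           sqrt(sum((y - mean(y))^2) / (n - 1)))
}

# random DNA helper for property-style tests
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# single-sample trace path: truth -> pool -> trace -> calls -> profile
recover_profile <- function(reference, catalog, fractions, tss_abs_pos,
                            n_molecules = 1e4, noise_sd = 5, seed = 1) {
  ctx <- reference_context(reference, tss_abs_pos, catalog)
  mm <- data.frame(abs_pos = catalog$abs_pos, fraction = fractions)
  pool <- bisulfite_convert_pool(reference, mm, n_molecules, seed = seed)
  trace <- render_trace(pool, noise_sd = noise_sd, seed = seed + 1)
  calls <- call_bases(trace)
  aln <- align_read(calls$primary, ctx)
  call_methylation(calls, aln, ctx)
}
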