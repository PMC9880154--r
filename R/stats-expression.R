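## Statistical layer: site-wise Welch t screening, region-grouped
## repeated-measures ANOVA with Bonferroni post-hoc, delta-delta-Ct relative
## expression with one-way ANOVA/Tukey, and region-expression correlation.

#' Default promoter region table
#'
#' Five contiguous TSS-relative spans partitioning the studied promoter,
#' 5'UTR and start of the coding sequence: region 1 is the distal promoter,
#' region 2 holds the CpG islet, region 3 abuts the TSS, region 4 is the
#' 5'UTR and region 5 the first stretch of coding sequence. Spans are
#' inclusive and use the no-zero TSS-relative convention.
#'
#' @return data.frame with columns `region_id`, `tss_rel_start`,
#'   `tss_rel_end`.
#' @export
default_region_table <- function() {
  data.frame(region_id = 1:5,
             tss_rel_start = c(-841L, -225L, -79L, 1L, 101L),
             tss_rel_end = c(-226L, -80L, -1L, 100L, 239L))
}

#' Read a region table TSV
#' @param path file with columns `region_id`, `tss_rel_start`, `tss_rel_end`.
#' @export
read_region_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("region_id", "tss_rel_start", "tss_rel_end")
  if (!all(need %in% names(df)))
    stop("region table must have columns: ", paste(need, collapse = ", "))
  df
}

.welch_t <- function(x, y) {
  # two-sided Welch t with the degenerate-variance conventions:
  # both variances zero & equal means -> p = 1; unequal means -> p -> 0
  if (length(x) < 2 || length(y) < 2) return(c(t = NA, p = NA, df = NA))
  vx <- var(x); vy <- var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) return(c(t = 0, p = 1, df = NA))
    return(c(t = sign(mean(x) - mean(y)) * Inf, p = 0, df = NA))
  }
  ht <- t.test(x, y)
  c(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Site-wise stage comparisons (Welch t screening)
#'
#' For every catalog CpG with usable coverage in at least two samples per
#' stage, runs a two-sided Welch t-test for every stage pair. P-values are
#' reported unadjusted (a site-level screen), flagged significant at 0.05;
#' sites lacking coverage are listed in the `skipped` attribute.
#'
#' @param profiles row-bound `methylation_profile` data for the whole cohort
#'   (columns `sample_id`, `stage`, `cpg_id`, `percent`, `flag`).
#' @param alpha significance flag threshold (default 0.05).
#' @return data.frame with columns `cpg_id`, `stage_a`, `stage_b`, `t`, `p`,
#'   `significant`, `degenerate`; skipped sites in `attr(, "skipped")`.
#' @export
sitewise_tests <- function(profiles, alpha = 0.05) {
  df <- as.data.frame(profiles)
  df <- df[df$flag == "ok" & !is.na(df$percent), , drop = FALSE]
  stages <- unique(as.data.frame(profiles)$stage)
  pairs <- utils::combn(stages, 2, simplify = FALSE)
  sites <- unique(as.data.frame(profiles)$cpg_id)
  rows <- list(); skipped <- character(0)
  for (site in sites) {
    d <- df[df$cpg_id == site, , drop = FALSE]
    n_per <- table(factor(d$stage, levels = stages))
    if (any(n_per < 2)) { skipped <- c(skipped, site); next }
    for (pr in pairs) {
      x <- d$percent[d$stage == pr[1]]
      y <- d$percent[d$stage == pr[2]]
      wt <- .welch_t(x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        cpg_id = site, stage_a = pr[1], stage_b = pr[2],
        t = wt[["t"]], p = wt[["p"]],
        significant = !is.na(wt[["p"]]) && wt[["p"]] < alpha,
        degenerate = is.infinite(wt[["t"]]),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cpg_id = character(0), stage_a = character(0),
               stage_b = character(0), t = numeric(0), p = numeric(0),
               significant = logical(0), degenerate = logical(0))
  attr(out, "skipped") <- skipped
  out
}

#' Bonferroni adjustment (monotone, capped at 1)
#' @param p numeric vector of raw p-values.
#' @param m number of comparisons (default `length(p)`).
#' @export
bonferroni <- function(p, m = length(p)) pmin(1, p * m)

#' Region-grouped stage comparison (repeated-measures ANOVA)
#'
#' CpG sites are grouped into regions; within an animal, the member sites of
#' a region are the repeated measures. The omnibus test per region treats
#' stage as a between-subject factor, testing the stage mean square against
#' the between-animal (within-stage) mean square. Post-hoc pairwise stage
#' comparisons use animal-level region means (pooled-SD t-tests) with
#' Bonferroni adjustment. A one-way mode that runs a plain one-way ANOVA on
#' the animal-level region means is available via `mode = "oneway"`.
#'
#' @param profiles row-bound cohort `methylation_profile` data (columns
#'   `sample_id`, `stage`, `cpg_id`, `region_id`, `percent`, `flag`).
#' @param region_table optional region table (kept for interface parity; the
#'   profiles' own `region_id` column is authoritative).
#' @param mode `"repeated"` (default) or `"oneway"`.
#' @return A list with `omnibus` (data.frame `region_id`, `f`, `df1`, `df2`,
#'   `p`, `n_sites`, `evaluable`), `posthoc` (data.frame `region_id`,
#'   `stage_a`, `stage_b`, `diff`, `p_raw`, `p_adj`), and `animal_means`.
#' @export
region_anova <- function(profiles, region_table = NULL,
                         mode = c("repeated", "oneway")) {
  mode <- match.arg(mode)
  df <- as.data.frame(profiles)
  df <- df[df$flag == "ok" & !is.na(df$percent), , drop = FALSE]
  stages <- unique(as.data.frame(profiles)$stage)
  omnibus <- list(); posthoc <- list(); means_all <- list()
  for (region in sort(unique(df$region_id))) {
    d <- df[df$region_id == region, , drop = FALSE]
    n_sites <- length(unique(d$cpg_id))
    am <- aggregate(percent ~ sample_id + stage, data = d, FUN = mean)
    am$region_id <- region
    means_all[[length(means_all) + 1L]] <- am
    n_per <- table(factor(am$stage, levels = stages))
    evaluable <- n_sites >= 2 && all(n_per >= 2)
    f <- df1 <- df2 <- p <- NA_real_
    if (evaluable) {
      if (mode == "repeated") {
        d$stage_f <- factor(d$stage, levels = stages)
        d$animal_f <- factor(d$sample_id)
        fit <- aov(percent ~ stage_f + Error(animal_f), data = d)
        tab <- summary(fit)[["Error: animal_f"]][[1]]
        f <- tab["stage_f", "F value"]
        df1 <- tab["stage_f", "Df"]
        df2 <- tab["Residuals", "Df"]
        p <- tab["stage_f", "Pr(>F)"]
      } else {
        fit <- aov(percent ~ factor(stage, levels = stages), data = am)
        tab <- summary(fit)[[1]]
        f <- tab[1, "F value"]; df1 <- tab[1, "Df"]; df2 <- tab[2, "Df"]
        p <- tab[1, "Pr(>F)"]
      }
    }
    omnibus[[length(omnibus) + 1L]] <- data.frame(
      region_id = region, f = f, df1 = df1, df2 = df2, p = p,
      n_sites = n_sites, evaluable = evaluable, stringsAsFactors = FALSE)
    # post-hoc on animal-level region means, Bonferroni over stage pairs
    pairs <- utils::combn(stages, 2, simplify = FALSE)
    pooled_sd <- NA_real_
    grp <- split(am$percent, factor(am$stage, levels = stages))
    dfs <- sum(lengths(grp) - 1L)
    if (dfs > 0)
      pooled_sd <- sqrt(sum(vapply(grp, function(g)
        sum((g - mean(g))^2), numeric(1))) / dfs)
    for (pr in pairs) {
      x <- grp[[pr[1]]]; y <- grp[[pr[2]]]
      if (length(x) < 2 || length(y) < 2 || is.na(pooled_sd)) {
        p_raw <- NA_real_; diffm <- NA_real_
      } else {
        diffm <- mean(x) - mean(y)
        se <- pooled_sd * sqrt(1 / length(x) + 1 / length(y))
        p_raw <- if (se == 0) as.numeric(diffm != 0) * 0 + (diffm == 0)
                 else 2 * pt(-abs(diffm / se), dfs)
      }
      posthoc[[length(posthoc) + 1L]] <- data.frame(
        region_id = region, stage_a = pr[1], stage_b = pr[2],
        diff = diffm, p_raw = p_raw,
        p_adj = bonferroni(p_raw, length(pairs)),
        stringsAsFactors = FALSE)
    }
  }
  list(omnibus = do.call(rbind, omnibus),
       posthoc = do.call(rbind, posthoc),
       animal_means = do.call(rbind, means_all))
}

#' Delta-delta-Ct relative expression
#'
#' Replicate wells are averaged per sample and gene; `dCt = Ct_target -
#' Ct_reference` per sample; `ddCt` is taken against the calibrator stage's
#' mean dCt, and the relative quantity is `2^-ddCt` (calibrator-stage
#' geometric mean = 1 by construction). Stages are compared with a one-way
#' ANOVA on ddCt (log2 relative quantity) followed by Tukey HSD.
#'
#' @param ct_table data.frame with columns `sample_id`, `stage`, `gene`,
#'   `replicate`, `ct`.
#' @param target_gene,reference_gene gene labels in `ct_table`.
#' @param calibrator_stage stage whose mean dCt anchors ddCt; default the
#'   first stage appearing in the table.
#' @return A list with `samples` (per-sample `dct`, `ddct`, `rq`), `stages`
#'   (per-stage geometric-mean `rq` and dispersion), `anova_p`, `tukey`
#'   (pairwise adjusted p), and `dropped` (samples lacking reference wells).
#' @export
ddct_expression <- function(ct_table, target_gene = "target",
                            reference_gene = "reference",
                            calibrator_stage = NULL) {
  df <- as.data.frame(ct_table)
  need <- c("sample_id", "stage", "gene", "ct")
  if (!all(need %in% names(df)))
    stop("ct_table must have columns: ", paste(need, collapse = ", "))
  if (is.null(calibrator_stage)) calibrator_stage <- df$stage[1]
  stages <- unique(df$stage)
  mean_ct <- aggregate(ct ~ sample_id + stage + gene, data = df, FUN = mean)
  samples <- unique(mean_ct[, c("sample_id", "stage")])
  dropped <- character(0)
  rows <- list()
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    tgt <- mean_ct$ct[mean_ct$sample_id == sid & mean_ct$gene == target_gene]
    ref <- mean_ct$ct[mean_ct$sample_id == sid &
                        mean_ct$gene == reference_gene]
    if (length(tgt) != 1L || length(ref) != 1L) {
      dropped <- c(dropped, sid)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sid, stage = samples$stage[i], dct = tgt - ref,
      stringsAsFactors = FALSE)
  }
  if (length(dropped))
    warning("samples dropped for missing wells: ",
            paste(dropped, collapse = ", "))
  res <- do.call(rbind, rows)
  calib_mean <- mean(res$dct[res$stage == calibrator_stage])
  res$ddct <- res$dct - calib_mean
  res$rq <- 2^(-res$ddct)
  stage_sum <- do.call(rbind, lapply(stages, function(st) {
    dd <- res$ddct[res$stage == st]
    data.frame(stage = st, mean_rq = 2^(-mean(dd)), sd_ddct = sd(dd),
               n = length(dd), stringsAsFactors = FALSE)
  }))
  anova_p <- NA_real_
  tukey <- NULL
  if (length(stages) >= 2 && all(table(res$stage) >= 2)) {
    res$stage_f <- factor(res$stage, levels = stages)
    fit <- aov(ddct ~ stage_f, data = res)
    anova_p <- summary(fit)[[1]][1, "Pr(>F)"]
    tk <- TukeyHSD(fit)$stage_f
    tukey <- data.frame(comparison = rownames(tk),
                        diff_ddct = tk[, "diff"], p_adj = tk[, "p adj"],
                        row.names = NULL, stringsAsFactors = FALSE)
  }
  list(samples = res[, c("sample_id", "stage", "dct", "ddct", "rq")],
       stages = stage_sum, anova_p = anova_p, tukey = tukey,
       calibrator_stage = calibrator_stage, dropped = dropped)
}

#' Pearson correlation of region methylation with expression
#'
#' Pairs animal-level region mean methylation with the same animal's relative
#' expression (`rq` from [ddct_expression()]) and computes the Pearson
#' correlation coefficient per region. Fewer than 3 complete pairs makes a
#' region not evaluable (`NA`).
#'
#' @param profiles row-bound cohort `methylation_profile` data.
#' @param expression result of [ddct_expression()] (or its `samples` element).
#' @return data.frame with columns `region_id`, `r`, `n_pairs`.
#' @export
region_expression_correlation <- function(profiles, expression) {
  if (is.list(expression) && !is.data.frame(expression))
    expression <- expression$samples
  df <- as.data.frame(profiles)
  df <- df[df$flag == "ok" & !is.na(df$percent), , drop = FALSE]
  am <- aggregate(percent ~ sample_id + region_id, data = df, FUN = mean)
  out <- lapply(sort(unique(am$region_id)), function(region) {
    d <- am[am$region_id == region, , drop = FALSE]
    m <- merge(d, expression[, c("sample_id", "rq")], by = "sample_id")
    m <- m[complete.cases(m[, c("percent", "rq")]), , drop = FALSE]
    r <- if (nrow(m) < 3) NA_real_ else cor(m$percent, m$rq)
    data.frame(region_id = region, r = r, n_pairs = nrow(m))
  })
  do.call(rbind, out)
}
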