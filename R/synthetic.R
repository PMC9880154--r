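## Synthetic-data module: promoters with a planted CpG islet, cohort designs,
## bisulfite-converted molecule pools, rendered chromatograms and qPCR plates,
## all with known ground truth and bit-reproducible under a seed.

#' Describe a developmental-stage cohort
#'
#' A cohort design fixes the study conditions for the simulators: the ordered
#' developmental stages, the number of animals per stage, the true mean
#' methylation fraction of every promoter region at every stage, the
#' between-animal variability, and the true relative expression of the target
#' gene per stage (calibrator stage = 1).
#'
#' @param stages character vector of ordered stage labels.
#' @param animals_per_stage integer >= 1.
#' @param region_means numeric matrix (rows = stages, columns = region ids as
#'   character) of true methylation fractions in \[0, 1\].
#' @param animal_sd standard deviation (fraction scale) of the per-animal,
#'   per-CpG deviation around the stage-by-region mean.
#' @param expression_fold named numeric vector of true relative expression per
#'   stage; the first stage is the calibrator and must equal 1.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(stages, animals_per_stage, region_means,
                          animal_sd, expression_fold) {
  stopifnot(is.character(stages), length(stages) >= 1,
            animals_per_stage >= 1, is.matrix(region_means),
            animal_sd >= 0)
  if (!identical(rownames(region_means), stages))
    stop("rownames(region_means) must equal the stage labels, in order")
  if (any(region_means < 0 | region_means > 1))
    stop("all region mean methylation fractions must lie in [0, 1]")
  if (!setequal(names(expression_fold), stages))
    stop("expression_fold must name every stage")
  if (abs(expression_fold[[stages[1]]] - 1) > 1e-12)
    stop("expression_fold of the calibrator (first) stage must be 1.0")
  if (any(expression_fold <= 0)) stop("expression_fold values must be > 0")
  structure(list(stages = stages,
                 animals_per_stage = as.integer(animals_per_stage),
                 region_means = region_means,
                 animal_sd = animal_sd,
                 expression_fold = expression_fold[stages]),
            class = "cohort_design")
}

#' Default cohort design emulating the mouse puberty study
#'
#' Three female mice at each of three postnatal stages (PND14 pre-pubertal,
#' PND35 pubertal, PND56 post-pubertal). Region mean methylation fractions
#' follow the reported ranges: the islet-bearing region 2 is the least
#' methylated (42\% rising by 5-6 points across puberty), region 3 sits at
#' 47-49\%, and regions 1, 4, 5 at 62-70\%. Target expression drops by ~70\%
#' at puberty and stays low after it.
#'
#' @param animal_sd between-animal noise (fraction), default 0.04.
#' @return A `cohort_design`.
#' @export
default_cohort_design <- function(animal_sd = 0.04) {
  stages <- c("PND14", "PND35", "PND56")
  rm <- rbind(PND14 = c(0.65, 0.42, 0.47, 0.64, 0.68),
              PND35 = c(0.66, 0.47, 0.48, 0.65, 0.69),
              PND56 = c(0.66, 0.48, 0.49, 0.65, 0.70))
  colnames(rm) <- as.character(1:5)
  cohort_design(stages, 3L, rm, animal_sd,
                c(PND14 = 1.0, PND35 = 0.3, PND56 = 0.3))
}

## -- promoter construction ---------------------------------------------------

.sample_multiset <- function(counts) {
  # counts: named integer vector over bases; returns a shuffled vector
  sample(rep(names(counts), counts))
}

# CpG-free random background at a given GC fraction
.random_cpg_free <- function(len, gc) {
  if (len <= 0) return(character(0))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  s <- sample(names(p), len, replace = TRUE, prob = p)
  cg <- which(s[-len] == "C" & s[-1] == "G")
  if (length(cg)) s[cg + 1L] <- "T"
  s
}

# Build an islet of length len with ~gc GC content and exactly n_cpg CpGs,
# CpG anchors spread evenly; retried until no stray CG arises.
.build_islet <- function(len, gc, n_cpg, max_tries = 500L) {
  n_c <- round(gc * len / 2); n_g <- n_c
  if (n_cpg > min(n_c, n_g)) stop("requested islet composition is infeasible")
  anchors <- round(seq_len(n_cpg) * (len - 1) / (n_cpg + 1))
  for (try in seq_len(max_tries)) {
    s <- character(len)
    s[anchors] <- "C"; s[anchors + 1L] <- "G"
    free <- which(s == "")
    n_at <- length(free) - (n_c - n_cpg) - (n_g - n_cpg)
    pool <- c(A = ceiling(n_at / 2), C = n_c - n_cpg, G = n_g - n_cpg,
              T = floor(n_at / 2))
    s[free] <- .sample_multiset(pool)
    # repair each stray CG (a C outside the anchors followed by G) by
    # swapping that G with an A/T placed where it creates no new CG
    repeat {
      stray <- setdiff(.find_cg(paste(s, collapse = "")), anchors)
      if (!length(stray)) break
      p <- stray[1]
      q_ok <- which(s %in% c("A", "T"))
      q_ok <- setdiff(q_ok, c(anchors, anchors + 1L, p + 1L))
      q_ok <- q_ok[q_ok == 1L | s[pmax(q_ok - 1L, 1L)] != "C"]
      if (!length(q_ok)) break  # give up on this draw
      q <- if (length(q_ok) == 1L) q_ok else sample(q_ok, 1L)
      s[p + 1L] <- s[q]
      s[q] <- "G"
    }
    if (setequal(.find_cg(paste(s, collapse = "")), anchors)) return(s)
  }
  stop("failed to assemble an islet with the requested composition")
}

.find_cg <- function(seq1) {
  m <- gregexpr("CG", seq1, fixed = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Generate a promoter sequence with a planted CpG islet
#'
#' Builds a synthetic promoter: a low-GC, CpG-sparse background with a planted
#' high-GC, CpG-dense islet at a TSS-relative interval, flanked by short
#' CpG-free guard zones so island detection boundaries stay clean. Background
#' CpG dinucleotides are placed at an exact rate; the islet's CpG count is
#' derived from the requested GC content and observed/expected ratio.
#'
#' @param total_len total sequence length in bp.
#' @param islet_span length-2 integer vector, TSS-relative interval (no zero)
#'   of the planted islet, e.g. `c(-200, -80)`.
#' @param islet_gc GC fraction of the islet, must be >= 0.5.
#' @param islet_oe observed/expected CpG ratio of the islet, must be >= 0.6
#'   and at most the theoretical maximum `2 / islet_gc`.
#' @param background_cpg_per_100bp CpG dinucleotides per 100 bp placed in the
#'   background (outside the islet and its guard zones).
#' @param seed integer seed; the same seed reproduces the same sequence.
#' @param tss_abs_pos 1-based position of the TSS (+1); default leaves 239 bp
#'   downstream of the TSS, mirroring the studied 1080 bp promoter layout.
#' @param background_gc GC fraction of the background (default 0.35, below the
#'   island threshold).
#' @param guard width in bp of the CpG-free guard zones flanking the islet.
#' @return A list with elements `sequence` (character scalar), `catalog` (a
#'   data.frame with columns `cpg_id`, `abs_pos`, `tss_rel`, `islet_member`),
#'   `tss_abs_pos`, and `islet_abs_span`.
#' @export
make_promoter_sequence <- function(total_len = 1080L,
                                   islet_span = c(-200L, -80L),
                                   islet_gc = 0.578, islet_oe = 0.70,
                                   background_cpg_per_100bp = 2.3,
                                   seed = 1L,
                                   tss_abs_pos = total_len - 238L,
                                   background_gc = 0.35, guard = 50L) {
  stopifnot(length(islet_span) == 2L, islet_span[1] <= islet_span[2])
  if (islet_gc < 0.5 || islet_gc > 1)
    stop("islet_gc must lie in [0.5, 1]")
  if (islet_oe < 0.6)
    stop("islet_oe must be >= 0.6 (island composition threshold)")
  if (islet_oe > 2 / islet_gc)
    stop("islet_oe exceeds the theoretical maximum 2/islet_gc for this GC")
  if (tss_abs_pos < 2 || tss_abs_pos > total_len)
    stop("tss_abs_pos must fall inside the sequence")
  a <- tss_absolute(islet_span[1], tss_abs_pos)
  b <- tss_absolute(islet_span[2], tss_abs_pos)
  if (a < 1 || b > total_len) stop("islet_span falls outside the sequence")
  len_islet <- b - a + 1L
  if (total_len < len_islet) stop("total_len shorter than the islet span")

  n_c <- round(islet_gc * len_islet / 2)
  n_cpg <- max(1L, round(islet_oe * n_c * n_c / len_islet))
  n_bg <- round(background_cpg_per_100bp * total_len / 100)

  # rejection loop: the postcondition (one window-verifiable islet, a
  # background that meets neither composition threshold) is enforced by
  # construction, regenerating under a derived sub-seed when a draw misses
  seq1 <- NULL
  for (attempt in seq_len(25L)) {
    set.seed(as.integer(seed) + (attempt - 1L) * 7919L)
    islet <- .build_islet(len_islet, islet_gc, n_cpg)
    if (len_islet >= 100L) {
      ok <- vapply(seq_len(len_islet - 99L), function(st) {
        ws <- window_stats(paste(islet, collapse = ""), st, 100L)
        ws[["gc_percent"]] >= 52 && ws[["obs_exp"]] >= 0.65
      }, logical(1))
      if (!all(ok)) next
    }

    s <- character(total_len)
    s[a:b] <- islet
    ga <- max(1L, a - guard); gb <- min(total_len, b + guard)
    if (ga < a) s[ga:(a - 1L)] <- .random_cpg_free(a - ga, 0.25)
    if (gb > b) s[(b + 1L):gb] <- .random_cpg_free(gb - b, 0.25)
    bg_idx <- which(s == "")
    s[bg_idx] <- .random_cpg_free(length(bg_idx), background_gc)

    # background CpGs at the exact requested count, spread evenly (jittered
    # within strata) so the background never approaches island composition
    ok_start <- bg_idx[(bg_idx + 1L) %in% bg_idx]
    if (length(ok_start) < 2L * n_bg)
      stop("background too short for the requested CpG rate")
    placed <- integer(0)
    if (n_bg > 0) {
      chunk <- cut(seq_along(ok_start), n_bg, labels = FALSE)
      placed <- vapply(seq_len(n_bg), function(j) {
        idx <- which(chunk == j)
        third <- idx[seq(ceiling(length(idx) / 3),
                         max(ceiling(length(idx) / 3),
                             floor(2 * length(idx) / 3)))]
        ok_start[if (length(third) == 1L) third else sample(third, 1L)]
      }, integer(1))
    }
    s[placed] <- "C"; s[placed + 1L] <- "G"

    # repair stray CGs created at zone junctions (never touching the islet)
    cand_seq <- paste(s, collapse = "")
    expected <- sort(c(placed,
                       a - 1L + .find_cg(paste(islet, collapse = ""))))
    stray <- setdiff(.find_cg(cand_seq), expected)
    for (p in stray) s[p + 1L] <- "A"
    cand_seq <- paste(s, collapse = "")
    if (!identical(sort(.find_cg(cand_seq)), expected)) next

    # verify the detection contract before accepting the draw
    at100 <- find_cpg_islands(cand_seq, window = 100L, minlen = 100L)
    at200 <- find_cpg_islands(cand_seq, window = 100L, minlen = 200L)
    if (nrow(at100) == 1L && nrow(at200) == 0L &&
        at100$start <= b && at100$end >= a) {
      seq1 <- cand_seq
      break
    }
  }
  if (is.null(seq1))
    stop("could not assemble a promoter meeting the composition contract")
  cg <- .find_cg(seq1)

  catalog <- data.frame(
    cpg_id = paste0("CpG", seq_along(cg)),
    abs_pos = cg,
    tss_rel = tss_relative(cg, tss_abs_pos),
    islet_member = cg >= a & cg <= b,
    stringsAsFactors = FALSE)
  list(sequence = seq1, catalog = catalog, tss_abs_pos = as.integer(tss_abs_pos),
       islet_abs_span = c(a, b))
}

#' Assign catalog CpGs to promoter regions
#'
#' @param catalog data.frame as returned by [make_promoter_sequence()].
#' @param region_table data.frame with columns `region_id`, `tss_rel_start`,
#'   `tss_rel_end` (inclusive TSS-relative spans); default
#'   [default_region_table()].
#' @return The catalog with a `region_id` column added.
#' @export
assign_regions <- function(catalog, region_table = default_region_table()) {
  region <- rep(NA_integer_, nrow(catalog))
  for (i in seq_len(nrow(region_table))) {
    hit <- catalog$tss_rel >= region_table$tss_rel_start[i] &
      catalog$tss_rel <= region_table$tss_rel_end[i]
    region[hit] <- region_table$region_id[i]
  }
  if (anyNA(region))
    stop("some catalog CpGs fall outside every region span: ",
         paste(catalog$cpg_id[is.na(region)], collapse = ", "))
  catalog$region_id <- region
  catalog
}

#' Simulate per-animal true methylation fractions
#'
#' For every animal and catalog CpG, draws a methylation fraction from a
#' normal distribution centred on the stage-by-region mean with standard
#' deviation `design$animal_sd`, truncated to \[0, 1\].
#'
#' @param catalog CpG catalog with a `region_id` column (see
#'   [assign_regions()]).
#' @param design a [cohort_design()].
#' @param seed integer seed.
#' @return data.frame with columns `sample_id`, `stage`, `animal`, `cpg_id`,
#'   `region_id`, `true_fraction`.
#' @export
simulate_methylome <- function(catalog, design, seed = 1L) {
  if (is.null(catalog$region_id))
    stop("catalog lacks region assignments; run assign_regions() first")
  regions <- as.character(catalog$region_id)
  missing <- setdiff(unique(regions), colnames(design$region_means))
  if (length(missing))
    stop("no region mean configured for region(s): ",
         paste(missing, collapse = ", "))
  set.seed(as.integer(seed))
  out <- list()
  for (stage in design$stages) {
    for (animal in seq_len(design$animals_per_stage)) {
      mu <- design$region_means[stage, regions]
      fr <- rnorm(nrow(catalog), mu, design$animal_sd)
      fr <- pmin(1, pmax(0, fr))
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sprintf("%s_%d", stage, animal),
        stage = stage, animal = animal,
        cpg_id = catalog$cpg_id, region_id = catalog$region_id,
        true_fraction = fr, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

## -- bisulfite conversion ----------------------------------------------------

#' Bisulfite-convert a pool of molecules
#'
#' Simulates sodium bisulfite treatment of `n_molecules` copies of the
#' reference: unmethylated cytosines deaminate (read as T) with probability
#' `conversion_rate`; methylated CpG cytosines are protected and stay C.
#' Molecules are independent, so the per-position base counts are binomial;
#' the pool records those counts (the sufficient statistic for trace
#' rendering) rather than materialising every molecule string.
#'
#' @param reference character scalar over A/C/G/T.
#' @param methylation_map data.frame with columns `abs_pos` (1-based position
#'   of a CpG cytosine) and `fraction` (methylated fraction in \[0, 1\]), or a
#'   named numeric vector keyed by position.
#' @param n_molecules number of molecules in the pool (>= 1).
#' @param conversion_rate probability that an unmethylated C converts.
#' @param seed integer seed.
#' @param sample_id identifier carried into downstream objects.
#' @return A `molecule_pool` object: list with `base_counts` (4 x L integer
#'   matrix, rows A/C/G/T), `n_molecules`, `length`, `true_methylation`,
#'   `conversion_rate`, `sample_id`.
#' @export
bisulfite_convert_pool <- function(reference, methylation_map, n_molecules,
                                   conversion_rate = 0.99, seed = 1L,
                                   sample_id = "pool") {
  stopifnot(n_molecules >= 1, conversion_rate >= 0, conversion_rate <= 1)
  bases <- strsplit(toupper(reference), "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T", "N")))
    stop("reference contains characters outside A/C/G/T/N")
  if (is.data.frame(methylation_map)) {
    mm <- setNames(methylation_map$fraction,
                   as.character(methylation_map$abs_pos))
  } else mm <- setNames(as.numeric(methylation_map), names(methylation_map))
  if (any(mm < 0 | mm > 1)) stop("methylation fractions must lie in [0, 1]")
  L <- length(bases)
  set.seed(as.integer(seed))
  counts <- matrix(0L, 4L, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  n <- as.integer(n_molecules)
  for (i in seq_len(L)) {
    b <- bases[i]
    if (b == "C") {
      m <- if (as.character(i) %in% names(mm)) mm[[as.character(i)]] else 0
      p_c <- m + (1 - m) * (1 - conversion_rate)
      nc <- rbinom(1L, n, p_c)
      counts["C", i] <- nc
      counts["T", i] <- n - nc
    } else if (b %in% c("A", "G", "T")) {
      counts[b, i] <- n
    } # N: all counts zero
  }
  structure(list(base_counts = counts, n_molecules = n, length = L,
                 true_methylation = mm, conversion_rate = conversion_rate,
                 sample_id = sample_id),
            class = "molecule_pool")
}

#' @export
print.molecule_pool <- function(x, ...) {
  cat(sprintf("molecule_pool: %d molecules x %d bp (sample %s)\n",
              x$n_molecules, x$length, x$sample_id))
  invisible(x)
}

## -- trace rendering ---------------------------------------------------------

#' Render a four-channel chromatogram from a molecule pool
#'
#' Places one Gaussian peak per base position in each channel, with amplitude
#' proportional to the frequency of that base among the pooled molecules at
#' that position; peak amplitude sums are constant across positions before
#' noise. Additive Gaussian noise (clipped at zero) models baseline jitter.
#'
#' @param pool a `molecule_pool`.
#' @param peak_spacing scans per base (> 0).
#' @param peak_sd Gaussian peak width in scans.
#' @param noise_sd additive intensity noise standard deviation.
#' @param seed integer seed (noise only).
#' @param amplitude total peak amplitude per position before noise.
#' @return A `chromatogram` (see [chromatogram()]).
#' @export
render_trace <- function(pool, peak_spacing = 10L, peak_sd = 2,
                         noise_sd = 0, seed = 1L, amplitude = 1000) {
  if (!inherits(pool, "molecule_pool")) stop("pool must be a molecule_pool")
  if (pool$n_molecules < 1 || pool$length < 1) stop("empty molecule pool")
  if (peak_spacing <= 0) stop("peak_spacing must be > 0")
  L <- pool$length
  n_scan <- as.integer(ceiling((L + 1) * peak_spacing))
  centers <- round(seq_len(L) * peak_spacing)
  freq <- pool$base_counts / pool$n_molecules
  x <- seq_len(n_scan)
  ch <- matrix(0, n_scan, 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
  span <- ceiling(4 * peak_sd)
  shape <- dnorm(-span:span, sd = peak_sd) / dnorm(0, sd = peak_sd)
  for (i in seq_len(L)) {
    idx <- (centers[i] - span):(centers[i] + span)
    keep <- idx >= 1 & idx <= n_scan
    for (b in c("A", "C", "G", "T")) {
      a <- amplitude * freq[b, i]
      if (a > 0) ch[idx[keep], b] <- ch[idx[keep], b] + a * shape[keep]
    }
  }
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    ch <- ch + matrix(rnorm(length(ch), 0, noise_sd), nrow(ch))
    ch[ch < 0] <- 0
  }
  chromatogram(A = ch[, "A"], C = ch[, "C"], G = ch[, "G"], T = ch[, "T"],
               peak_locations = centers, sample_id = pool$sample_id,
               source_format = "synthetic")
}

## -- qPCR simulation ---------------------------------------------------------

#' Simulate a qPCR Ct table for a cohort
#'
#' Each animal is amplified in `replicates` wells for the target gene and the
#' reference (housekeeping) gene. The true per-sample delta-Ct equals the
#' calibrator delta-Ct plus `log2(1 / expression_fold(stage))`; sample-level
#' biological noise and well-level technical noise are both N(0,
#' `ct_noise_sd`).
#'
#' @param design a [cohort_design()].
#' @param replicates wells per sample and gene (default 3, i.e. triplicate).
#' @param ct_noise_sd noise standard deviation in cycles.
#' @param seed integer seed.
#' @param target_gene,reference_gene gene labels used in the table.
#' @param base_ct_reference,base_ct_target true Ct of the reference gene and
#'   calibrator-stage target.
#' @return data.frame with columns `sample_id`, `stage`, `gene`, `replicate`,
#'   `ct`.
#' @export
simulate_qpcr <- function(design, replicates = 3L, ct_noise_sd = 0.15,
                          seed = 1L, target_gene = "target",
                          reference_gene = "reference",
                          base_ct_reference = 18, base_ct_target = 24) {
  stopifnot(replicates >= 1, ct_noise_sd >= 0)
  set.seed(as.integer(seed))
  rows <- list()
  for (stage in design$stages) {
    dct_true <- (base_ct_target - base_ct_reference) +
      log2(1 / design$expression_fold[[stage]])
    for (animal in seq_len(design$animals_per_stage)) {
      sample_id <- sprintf("%s_%d", stage, animal)
      dct_sample <- dct_true + rnorm(1L, 0, ct_noise_sd)
      for (gene in c(target_gene, reference_gene)) {
        mu <- if (gene == target_gene) base_ct_reference + dct_sample
              else base_ct_reference
        ct <- mu + rnorm(replicates, 0, ct_noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sample_id, stage = stage, gene = gene,
          replicate = seq_len(replicates), ct = ct,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

## -- fixture writers ---------------------------------------------------------

#' Write a reference sequence to FASTA
#' @param sequence character scalar DNA sequence.
#' @param path output file.
#' @param name FASTA record name.
#' @export
write_reference_fasta <- function(sequence, path, name = "promoter") {
  dna <- Biostrings::DNAStringSet(sequence)
  names(dna) <- name
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Write / read a CpG catalog TSV
#'
#' Columns: `cpg_id`, `abs_pos_1based`, `tss_rel_pos`, `region_id`.
#' @param catalog data.frame with `cpg_id`, `abs_pos`, `tss_rel`, `region_id`.
#' @param path file path.
#' @export
write_cpg_catalog <- function(catalog, path) {
  out <- data.frame(cpg_id = catalog$cpg_id,
                    abs_pos_1based = catalog$abs_pos,
                    tss_rel_pos = catalog$tss_rel,
                    region_id = catalog$region_id)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cpg_catalog
#' @export
read_cpg_catalog <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("cpg_id", "abs_pos_1based", "tss_rel_pos", "region_id")
  if (!all(need %in% names(df)))
    stop("CpG catalog must have columns: ", paste(need, collapse = ", "))
  data.frame(cpg_id = df$cpg_id, abs_pos = df$abs_pos_1based,
             tss_rel = df$tss_rel_pos, region_id = df$region_id,
             stringsAsFactors = FALSE)
}
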