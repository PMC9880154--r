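toy_context <- function() {
  # 60 bp reference with 3 CpGs at fixed positions
  ref <- paste0("ATTAGGATCC", "GATTCGATTA", "ACGTTAGGCA", "TTACGGATTA",
                "GGATTAACCT", "AGGATTAGGA")
  cgs <- as.integer(gregexpr("CG", ref, fixed = TRUE)[[1]])
  catalog <- data.frame(cpg_id = paste0("CpG", seq_along(cgs)),
                        abs_pos = cgs, tss_rel = cgs - 61L,
                        region_id = 1L)
  reference_context(ref, 61L, catalog)
}

test_that("reference conversion strips every C and nothing else", {
  expect_identical(convert_reference("ACGT"), "ATGT")
  expect_identical(convert_reference("AGGTTA"), "AGGTTA")
  s <- random_dna(200)
  expect_identical(convert_reference(convert_reference(s)),
                   convert_reference(s))
  expect_equal(nchar(convert_reference(s)), 200)
  expect_false(grepl("C", convert_reference(s)))
  expect_error(convert_reference("ACXT"), "characters")
})

test_that("reference context validates its catalog", {
  ref <- "AACGTT"
  good <- data.frame(cpg_id = "CpG1", abs_pos = 3, tss_rel = -4)
  expect_s3_class(reference_context(ref, 7, good), "reference_context")
  bad <- data.frame(cpg_id = "CpG1", abs_pos = 2, tss_rel = -5)
  expect_error(reference_context(ref, 7, bad), "CG dinucleotide")
})

test_that("aligning the converted reference to itself gives the identity map", {
  ctx <- toy_context()
  aln <- align_read(ctx$converted, ctx)
  expect_equal(aln$identity, 1.0)
  expect_equal(aln$map$read_pos, aln$map$ref_pos)
  expect_equal(nrow(aln$map), nchar(ctx$converted))
})

test_that("a read with an internal deletion maps with one reference gap", {
  ctx <- toy_context()
  conv <- ctx$converted
  # delete 5 reference bases from the middle of the read
  read <- paste0(substr(conv, 1, 30), substr(conv, 36, nchar(conv)))
  aln <- align_read(read, ctx)
  gaps <- diff(aln$map$ref_pos) - 1L
  expect_equal(sum(gaps), 5L)
  expect_equal(sum(gaps > 0), 1L)
  expect_true(all(diff(aln$map$read_pos) > 0))
  # score agrees with the independent DP oracle
  expect_equal(aln$score, oracle_align_score(read, conv))
})

test_that("alignment scores match the brute-force DP oracle on short reads", {
  set.seed(42)
  ctx30 <- local({
    ref <- "TTAACGTTAGGATCGATTAGGACGATTAGG"
    cgs <- as.integer(gregexpr("CG", ref, fixed = TRUE)[[1]])
    reference_context(ref, 31L,
                      data.frame(cpg_id = paste0("CpG", seq_along(cgs)),
                                 abs_pos = cgs, tss_rel = cgs - 31L))
  })
  # mutated/indel variants of the converted reference, all length <= 30
  for (k in 1:25) {
    conv <- ctx30$converted
    chars <- strsplit(conv, "")[[1]]
    n_mut <- sample(0:3, 1)
    if (n_mut > 0) {
      at <- sample(seq_along(chars), n_mut)
      chars[at] <- sample(c("A", "G", "T"), n_mut, replace = TRUE)
    }
    if (k %% 3 == 0) chars <- chars[-sample(2:(length(chars) - 1), 1)]
    read <- paste(chars, collapse = "")
    aln <- align_read(read, ctx30, min_identity = 0, min_length = 10)
    expect_equal(aln$score, oracle_align_score(read, ctx30$converted),
                 info = paste("case", k))
  }
})

test_that("an unrelated read fails alignment with an identity error", {
  ctx <- toy_context()
  set.seed(1)
  junk <- random_dna(60)
  expect_error(align_read(junk, ctx), "identity")
  expect_error(align_read("ACGT", ctx), "too short")
})

test_that("methylation percent is the bounded C/(C+T) amplitude ratio", {
  ctx <- toy_context()
  n <- nchar(ctx$reference)
  amp <- matrix(0, n, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  bases <- strsplit(ctx$converted, "")[[1]]
  amp[cbind(seq_len(n), match(bases, c("A", "C", "G", "T")))] <- 100
  sites <- ctx$catalog$abs_pos
  expect_length(sites, 4)
  amp[sites[1], ] <- c(0, 100, 0, 0)    # fully methylated
  amp[sites[2], ] <- c(0, 50, 0, 50)    # half
  amp[sites[3], ] <- c(0, 0, 0, 100)    # unmethylated
  # site 4 keeps the converted-base default (pure T) -> 0%
  calls <- structure(list(primary = ctx$converted,
                          secondary = ctx$converted,
                          per_base_intensity = amp,
                          flagged = rep(FALSE, n), sample_id = "s1"),
                     class = "base_calls")
  map <- data.frame(read_pos = seq_len(n), ref_pos = seq_len(n))
  prof <- call_methylation(calls, map, ctx)
  expect_equal(prof$percent, c(100, 50, 0, 0))
  expect_equal(prof$flag, rep("ok", 4))

  # a low-amplitude site drops below the intensity floor -> insufficient
  amp2 <- amp
  amp2[sites[2], ] <- c(0, 2, 0, 2)
  calls2 <- calls; calls2$per_base_intensity <- amp2
  prof2 <- call_methylation(calls2, map, ctx)
  expect_identical(prof2$flag[2], "insufficient")
  expect_true(is.na(prof2$percent[2]))
  expect_identical(prof2$flag[c(1, 3, 4)], c("ok", "ok", "ok"))

  # gapped (unmapped) site -> insufficient, never an error
  map_gap <- map[map$ref_pos != sites[1], ]
  prof3 <- call_methylation(calls, map_gap, ctx)
  expect_identical(prof3$flag[1], "insufficient")
})

test_that("the ratio estimator is invariant to global trace rescaling", {
  set.seed(21)
  p <- make_promoter_sequence(seed = 21)
  catalog <- assign_regions(p$catalog)
  ctx <- reference_context(p$sequence, p$tss_abs_pos, catalog)
  fr <- runif(nrow(catalog))
  mm <- data.frame(abs_pos = catalog$abs_pos, fraction = fr)
  pool <- bisulfite_convert_pool(p$sequence, mm, 2000, seed = 22)
  tr <- render_trace(pool, noise_sd = 0)
  tr_scaled <- tr
  tr_scaled$channels <- tr$channels * 12.5
  prof_a <- call_methylation(call_bases(tr),
                             align_read(call_bases(tr)$primary, ctx), ctx)
  prof_b <- call_methylation(call_bases(tr_scaled),
                             align_read(call_bases(tr_scaled)$primary, ctx),
                             ctx)
  expect_equal(prof_a$percent, prof_b$percent)
})

test_that("profiles stay within bounds and inside the catalog", {
  for (seed in c(31, 32, 33)) {
    set.seed(seed)
    p <- make_promoter_sequence(seed = seed)
    catalog <- assign_regions(p$catalog)
    prof <- recover_profile(p$sequence, catalog, runif(nrow(catalog)),
                            p$tss_abs_pos, n_molecules = 1000, seed = seed)
    expect_true(all(prof$cpg_id %in% catalog$cpg_id))
    okp <- prof$percent[prof$flag == "ok"]
    expect_true(all(okp >= 0 & okp <= 100))
    expect_true(all(is.na(prof$percent[prof$flag != "ok"])))
  }
})

test_that("conversion QC flags incomplete bisulfite conversion", {
  p <- make_promoter_sequence(seed = 41)
  catalog <- assign_regions(p$catalog)
  ctx <- reference_context(p$sequence, p$tss_abs_pos, catalog)
  mm <- data.frame(abs_pos = catalog$abs_pos, fraction = 0.5)
  run_qc <- function(conv) {
    pool <- bisulfite_convert_pool(p$sequence, mm, 2000,
                                   conversion_rate = conv, seed = 42)
    tr <- render_trace(pool, noise_sd = 2, seed = 43)
    calls <- call_bases(tr)
    conversion_qc(calls, align_read(calls$primary, ctx), ctx)
  }
  full <- run_qc(1.0)
  expect_identical(full$status, "pass")
  expect_gte(full$rate, 0.99)
  partial <- run_qc(0.8)
  expect_identical(partial$status, "warn")
  expect_lt(partial$rate, 0.95)
  # too few covered non-CpG cytosines -> not evaluable
  empty_map <- data.frame(read_pos = integer(0), ref_pos = integer(0))
  calls <- call_bases(render_trace(bisulfite_convert_pool(
    p$sequence, mm, 10, seed = 1), noise_sd = 0))
  expect_identical(conversion_qc(calls, empty_map, ctx)$status,
                   "not_evaluable")
})

test_that("amplicon merging unions, averages, and prefers usable calls", {
  prof1 <- data.frame(sample_id = "s", stage = "PND14",
                      cpg_id = c("CpG1", "CpG2", "CpG3"), region_id = 1,
                      percent = c(60, 80, NA),
                      flag = c("ok", "ok", "insufficient"),
                      i_c = c(60, 80, NA), i_t = c(40, 20, NA))
  prof2 <- prof1
  prof2$percent <- c(70, NA, 40)
  prof2$flag <- c("ok", "insufficient", "ok")
  class(prof1) <- class(prof2) <- c("methylation_profile", "data.frame")
  merged <- merge_amplicons(list(prof1, prof2))
  expect_equal(merged$percent, c(65, 80, 40))  # mean, keep-ok, keep-ok
  expect_equal(merged$flag, c("ok", "ok", "ok"))
  prof3 <- prof2
  prof3$stage <- "PND35"
  expect_error(merge_amplicons(list(prof1, prof3)), "stage")
  prof4 <- prof2
  prof4$sample_id <- "other"
  expect_error(merge_amplicons(list(prof1, prof4)), "different samples")
})
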