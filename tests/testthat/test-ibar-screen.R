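make_lfc_table <- function(lfc_matrix, ref_norm = 500) {
  n <- nrow(lfc_matrix)
  data.frame(
    spacer_id = rep(sprintf("g%04d", seq_len(n)), each = ncol(lfc_matrix)),
    ibar = rep(sprintf("b%d", seq_len(ncol(lfc_matrix))), n),
    ref_norm = ref_norm,
    lfc = as.vector(t(lfc_matrix)),
    stringsAsFactors = FALSE
  )
}

test_that("count_guides assigns exact matches and tallies the rest", {
  lib <- make_synthetic_library(3, seed = 5)
  long <- do.call(rbind, lapply(c("ibar1", "ibar2", "ibar3"), function(cl) {
    data.frame(spacer = lib$spacer, ibar = lib[[cl]], id = lib$spacer_id)
  }))
  reads <- c(rep(paste0(long$spacer[1], long$ibar[1]), 100),
             paste0(strrep("N", 20), long$ibar[1]))  # one unassignable read
  ct <- count_guides(reads, lib, sample = "s1")
  expect_equal(sum(ct$s1), 100)
  expect_equal(ct$s1[ct$spacer_id == long$id[1] & ct$ibar == long$ibar[1]], 100)
  expect_equal(attr(ct, "n_unassigned"), 1L)
  # order invariance
  ct2 <- count_guides(rev(reads), lib, sample = "s1")
  expect_equal(ct[order(ct$spacer_id, ct$ibar), ],
               ct2[order(ct2$spacer_id, ct2$ibar), ], ignore_attr = TRUE)
  # round-trip through FASTQ
  fq <- tempfile(fileext = ".fq")
  write_fastq(reads, fq)
  ct3 <- count_guides(fq, lib, sample = "s1")
  expect_equal(ct3$s1, ct$s1)
})

test_that("median-of-ratios size factors behave and match a brute-force recomputation", {
  lib <- make_synthetic_library(200, seed = 21)
  sim <- simulate_screen(lib, screen_sim_config(seed = 22),
                         samples = "sorted_high")
  counts <- sim$counts
  # identical columns give unit factors; doubling a column doubles its factor
  same <- counts
  same$sorted_high <- same$reference
  nf <- normalize_counts(same)
  expect_equal(unname(nf$size_factors), c(1, 1))
  dbl <- counts
  dbl$sorted_high <- 2L * dbl$reference
  nf2 <- normalize_counts(dbl, pseudocount = 0)  # exact scale equivariance
  expect_equal(nf2$size_factors[["sorted_high"]] / nf2$size_factors[["reference"]],
               2, tolerance = 1e-12)
  # brute-force recomputation on the NB table
  nf3 <- normalize_counts(counts, pseudocount = 1)
  m <- as.matrix(counts[c("reference", "sorted_high")]) + 1
  geo <- apply(m, 1, function(r) prod(r)^(1 / length(r)))
  expect_equal(unname(nf3$size_factors),
               unname(apply(m / geo, 2, median)), tolerance = 1e-8)
  expect_equal(as.matrix(nf3$norm[c("reference", "sorted_high")]),
               sweep(as.matrix(counts[c("reference", "sorted_high")]), 2,
                     nf3$size_factors, "/"), ignore_attr = TRUE)
})

test_that("per-iBAR fold changes follow log2((t+pc)/(r+pc)) on normalized counts", {
  counts <- data.frame(
    spacer_id = c("g1", "g1", "g2", "g2"), ibar = c("b1", "b2", "b1", "b2"),
    reference = c(1L, 10L, 100L, 7L), treatment = c(3L, 10L, 100L, 7L),
    stringsAsFactors = FALSE
  )
  nf <- normalize_counts(counts)
  lfc <- per_ibar_lfc(nf, "treatment", "reference")
  sf <- nf$size_factors
  expected <- log2((counts$treatment / sf[["treatment"]] + 1) /
                   (counts$reference / sf[["reference"]] + 1))
  expect_equal(lfc$lfc, expected)
  # equal counts and equal size factors give exactly zero
  eq <- counts
  eq$treatment <- eq$reference
  lfc0 <- per_ibar_lfc(normalize_counts(eq), "treatment", "reference")
  expect_equal(lfc0$lfc, rep(0, 4))
  # t=3, r=1 at unit size factors: log2(4/2) = 1
  expect_equal(lfc$lfc[1], log2((3 / sf[["treatment"]] + 1) / (1 / sf[["reference"]] + 1)))
})

test_that("a null guide set yields near-zero scores and no hits", {
  set.seed(31)
  m <- matrix(rnorm(300 * 3, sd = 0.3), ncol = 3)
  m[1, ] <- 0  # the guide under scrutiny: all three iBARs exactly 0
  res <- score_sgrnas(make_lfc_table(m), direction = "up")
  g1 <- res[res$spacer_id == "g0001", ]
  expect_equal(g1$z_combined, 0)
  expect_equal(g1$p_raw, 0.5)
  expect_lt(abs(g1$screen_score), 0.35)
  expect_false(g1$is_hit)
})

test_that("concordant planted effects are recovered as hits", {
  set.seed(32)
  m <- matrix(rnorm(500 * 3, sd = 0.3), ncol = 3)
  hit_rows <- 1:10
  m[hit_rows, ] <- m[hit_rows, ] + 3 * 0.3 * 4  # strong concordant shift
  res <- score_sgrnas(make_lfc_table(m), direction = "up")
  expect_true(all(res$is_hit[hit_rows]))
  expect_true(all(abs(res$screen_score[hit_rows]) > 1))
})

test_that("sign-discordant iBAR triplets are penalized against concordant ones", {
  set.seed(33)
  n <- 1000
  noise <- matrix(rnorm(n * 3, sd = 0.25), ncol = 3)
  conc <- noise + 1.5                       # all three up, mean 1.5
  disc <- noise + matrix(c(5.5, -0.5, -0.5), n, 3, byrow = TRUE)  # same mean 1.5
  expect_equal(rowMeans(conc), rowMeans(disc), tolerance = 1e-12)
  res_c <- score_sgrnas(make_lfc_table(conc), direction = "up")
  res_d <- score_sgrnas(make_lfc_table(disc), direction = "up")
  expect_true(all(res_d$consistency_penalty > 1))
  expect_true(all(res_c$consistency_penalty == 1))
  # paired comparison, same guide order
  expect_true(all(abs(res_d$z_combined) < abs(res_c$z_combined)))
})

test_that("permuting iBAR labels within a guide leaves scores unchanged", {
  set.seed(34)
  m <- matrix(rnorm(100 * 3), ncol = 3)
  tab <- make_lfc_table(m)
  res1 <- score_sgrnas(tab, direction = "up")
  perm <- tab[order(tab$spacer_id, rev(seq_len(nrow(tab)))), ]
  res2 <- score_sgrnas(perm, direction = "up")
  expect_equal(res1$screen_score,
               res2$screen_score[match(res1$spacer_id, res2$spacer_id)])
})

test_that("guides with fewer than three iBARs are flagged but scored", {
  set.seed(35)
  tab <- make_lfc_table(matrix(rnorm(50 * 3, sd = 0.5), ncol = 3))
  tab <- tab[-2, ]  # drop one iBAR of g0001
  res <- score_sgrnas(tab, direction = "up")
  g1 <- res[res$spacer_id == "g0001", ]
  expect_equal(g1$n_ibars, 2L)
  expect_true(g1$few_ibars)
  expect_true(is.finite(g1$screen_score))
})

test_that("screen_score and call_hits implement the signed -log10 rule", {
  expect_equal(screen_score(0.1, "up"), 1)
  expect_equal(screen_score(0.01, "down"), -2)
  expect_equal(screen_score(1, "up"), 0)
  expect_true(is.finite(screen_score(0, "up")))  # clamped, not infinite
  res <- data.frame(screen_score = c(1, 1.0001, -2, -0.99))
  expect_equal(call_hits(res, 1)$is_hit, c(FALSE, TRUE, TRUE, FALSE))
})

test_that("monotonicity: scaling up a hit's sorted counts never lowers its score", {
  lib <- make_synthetic_library(300, n_controls = 50, seed = 41)
  sim <- simulate_screen(lib, screen_sim_config(seed = 42), samples = "sorted_high")
  counts <- sim$counts
  target <- "g00001"
  scores <- vapply(c(1, 2, 4, 8), function(f) {
    cc <- counts
    rows <- cc$spacer_id == target
    cc$sorted_high[rows] <- as.integer(round(cc$sorted_high[rows] * f))
    nf <- normalize_counts(cc)
    lfc <- per_ibar_lfc(nf, "sorted_high", "reference")
    res <- score_sgrnas(lfc, controls = lib$spacer_id[lib$is_control],
                        direction = "up")
    res$screen_score[res$spacer_id == target]
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("run_screen scores both gates and keeps library order stable", {
  lib <- make_synthetic_library(200, n_controls = 40, seed = 51)
  sim <- simulate_screen(lib, screen_sim_config(n_hits_up = 5, seed = 52))
  samples <- data.frame(sample = c("reference", "sorted_high", "sorted_low"),
                        role = c("reference", "sorted_high", "sorted_low"))
  res <- run_screen(sim$counts, samples,
                    controls = lib$spacer_id[lib$is_control])
  expect_setequal(unique(res$sorted_sample), c("sorted_high", "sorted_low"))
  expect_setequal(unique(res$direction), c("up", "down"))
  planted <- sim$truth$spacer_id[sim$truth$true_effect > 0]
  up <- res[res$sorted_sample == "sorted_high" & res$direction == "up", ]
  expect_true(all(planted %in% up$spacer_id[up$is_hit]))
})
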