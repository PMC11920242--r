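#' Validate an sgRNA-iBAR count table
#'
#' A count table has key columns `spacer_id` and `ibar`, then one
#' non-negative integer column per sample; every (spacer_id, ibar) pair is
#' unique.
#'
#' @param counts A data.frame.
#' @return The table, invisibly, or an error.
#' @export
validate_count_table <- function(counts) {
  stopifnot(is.data.frame(counts),
            all(c("spacer_id", "ibar") %in% names(counts)))
  samp <- count_sample_names(counts)
  if (length(samp) < 1L) stop("count table has no sample columns", call. = FALSE)
  vals <- as.matrix(counts[samp])
  if (any(is.na(vals)) || any(vals < 0)) {
    stop("counts must be non-negative and complete", call. = FALSE)
  }
  if (anyDuplicated(counts[c("spacer_id", "ibar")])) {
    stop("duplicate (spacer_id, ibar) rows", call. = FALSE)
  }
  invisible(counts)
}

count_sample_names <- function(counts) {
  setdiff(names(counts), c("spacer_id", "ibar"))
}

# Long (spacer_id, spacer, ibar) view of a barcoded guide table.
library_long <- function(library) {
  ibar_cols <- grep("^ibar[0-9]+$", names(library), value = TRUE)
  if (length(ibar_cols) == 0L) {
    stop("library has no ibar columns; run assign_ibars() first", call. = FALSE)
  }
  do.call(rbind, lapply(ibar_cols, function(cl) {
    data.frame(spacer_id = library$spacer_id, spacer = library$spacer,
               ibar = library[[cl]], stringsAsFactors = FALSE)
  }))
}

#' Count reads per (sgRNA, iBAR)
#'
#' Assigns reads to library members by exact match of the spacer and iBAR
#' substrings at fixed offsets within each read, the layout produced by
#' amplifying the sgRNA-coding cassette. Unmatched reads are tallied in the
#' `n_unassigned` attribute. The returned table is zero-filled over the
#' full library.
#'
#' @param reads FASTQ path, or a character vector of read sequences.
#' @param library Barcoded guide table (with `ibar1..ibarN` columns).
#' @param sample Name for the resulting count column.
#' @param spacer_start 1-based offset of the spacer within each read.
#' @param ibar_start 1-based offset of the iBAR; defaults to immediately
#'   after the spacer.
#' @param ibar_len iBAR length in nt.
#' @return A count table (see [validate_count_table()]) with attribute
#'   `n_unassigned`.
#' @export
count_guides <- function(reads, library, sample = "sample1",
                         spacer_start = 1L, ibar_start = NULL, ibar_len = 6L) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq(reads)$seq
  }
  lib <- library_long(library)
  plen <- nchar(lib$spacer[1])
  if (is.null(ibar_start)) ibar_start <- spacer_start + plen
  key <- paste0(substr(reads, spacer_start, spacer_start + plen - 1L),
                substr(reads, ibar_start, ibar_start + ibar_len - 1L))
  libkey <- paste0(lib$spacer, lib$ibar)
  idx <- match(key, libkey)
  tab <- tabulate(idx[!is.na(idx)], nbins = nrow(lib))
  out <- data.frame(spacer_id = lib$spacer_id, ibar = lib$ibar,
                    stringsAsFactors = FALSE)
  out[[sample]] <- tab
  out <- out[order(out$spacer_id, out$ibar), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unassigned") <- sum(is.na(idx))
  validate_count_table(out)
  out
}

#' Median-of-ratios count normalization
#'
#' Computes per-sample size factors as the median across rows of
#' `(count + pseudocount) / geometric mean across samples of
#' (count + pseudocount)`, then divides each sample by its factor. Rows
#' whose geometric mean is zero are excluded from the median (with a
#' positive pseudocount none are).
#'
#' @param counts A count table.
#' @param pseudocount Added to every count before forming ratios.
#' @return A list of class `normalized_counts`: `norm` (the table with
#'   sample columns replaced by normalized counts) and `size_factors`.
#' @export
normalize_counts <- function(counts, pseudocount = 1) {
  validate_count_table(counts)
  samp <- count_sample_names(counts)
  if (length(samp) < 2L) stop("need at least 2 samples", call. = FALSE)
  m <- as.matrix(counts[samp]) + pseudocount
  if (any(colSums(m - pseudocount) == 0)) {
    stop("sample with all-zero counts", call. = FALSE)
  }
  geo <- exp(rowMeans(log(m)))
  ok <- geo > 0
  sf <- apply(m[ok, , drop = FALSE] / geo[ok], 2, median)
  norm <- counts
  norm[samp] <- sweep(as.matrix(counts[samp]), 2, sf, "/")
  structure(list(norm = norm, size_factors = sf), class = "normalized_counts")
}

#' Per-iBAR log2 fold changes
#'
#' @param norm A `normalized_counts` object.
#' @param treatment,reference Sample column names.
#' @param pseudocount Added to normalized counts before the ratio.
#' @return A data.frame with `spacer_id`, `ibar`, `ref_norm` (normalized
#'   reference count, used downstream for abundance-dependent variance
#'   modelling) and `lfc`.
#' @export
per_ibar_lfc <- function(norm, treatment, reference, pseudocount = 1) {
  stopifnot(inherits(norm, "normalized_counts"))
  tab <- norm$norm
  stopifnot(all(c(treatment, reference) %in% names(tab)))
  data.frame(
    spacer_id = tab$spacer_id,
    ibar = tab$ibar,
    ref_norm = tab[[reference]],
    lfc = log2((tab[[treatment]] + pseudocount) / (tab[[reference]] + pseudocount)),
    stringsAsFactors = FALSE
  )
}

# Abundance-dependent null SD of per-iBAR lfcs, fitted on control guides
# (fallback: all guides). For NB counts the log-ratio variance is
# approximately a + b / mu (shot noise plus overdispersion), so a weighted
# regression of binned variances on reciprocal abundance gives a smooth,
# monotone trend; degenerate inputs fall back to a constant SD.
fit_sigma_trend <- function(ref_abund, lfc, n_bins = 10L) {
  const_fallback <- function() {
    s <- max(sd(lfc), 1e-3)
    function(x) rep(s, length(x))
  }
  mu <- pmax(ref_abund, 0.5)
  qs <- unique(quantile(mu, probs = seq(0, 1, length.out = n_bins + 1L)))
  if (length(qs) < 3L || length(lfc) < 30L) return(const_fallback())
  bin <- cut(mu, qs, include.lowest = TRUE)
  v <- tapply(lfc, bin, var)
  m <- tapply(mu, bin, median)
  w <- tapply(lfc, bin, length)
  keep <- !is.na(v) & v > 0
  if (sum(keep) < 3L) return(const_fallback())
  fit <- lm(v[keep] ~ I(1 / m[keep]), weights = w[keep])
  a <- coef(fit)[1]
  b <- coef(fit)[2]
  v_floor <- min(v[keep]) / 2
  if (!is.finite(a) || !is.finite(b) || b < 0) {
    # no abundance dependence resolvable: constant pooled variance
    a <- sum(v[keep] * w[keep]) / sum(w[keep])
    b <- 0
  }
  function(x) sqrt(pmax(a + b / pmax(x, 0.5), v_floor, 1e-6))
}

#' Score sgRNAs from per-iBAR fold changes
#'
#' Combines the significance and the inter-iBAR consistency of each
#' guide's fold changes into a one-sided P value for the tested direction:
#'
#' 1. a mean-variance trend `sigma(reference abundance)` is fitted on the
#'    per-iBAR fold changes of control guides (all guides if no or too few
#'    controls), binned by normalized reference abundance;
#' 2. each iBAR fold change is standardized, `z = lfc / sigma`;
#' 3. if the iBAR fold changes are not sign-concordant with the tested
#'    direction, the combined variance is inflated by
#'    `penalty = max(1, var(z))`, the between-iBAR variance relative to the
#'    unit variance expected of independent standardized replicates;
#' 4. the guide's combined statistic is `z_comb = sum(z) / sqrt(n * penalty)`
#'    (a consistency-penalized Stouffer combination over its `n` iBARs);
#' 5. one-sided normal P values for the tested direction are BH-adjusted
#'    across sgRNAs, and the signed screen score is
#'    `-log10(p_adj)` (negated for `direction = "down"`).
#'
#' @param lfcs Output of [per_ibar_lfc()].
#' @param controls Logical vector per row of `lfcs` (or character vector of
#'   control `spacer_id`s) marking control guides for the null model;
#'   `NULL` uses all guides.
#' @param direction `"up"` (enrichment) or `"down"` (depletion).
#' @param threshold Hit threshold on `|screen_score|` (strict).
#' @param n_bins Abundance bins for the variance trend.
#' @return A data.frame per sgRNA: `spacer_id`, `n_ibars`,
#'   `lfc_ibar1..3`, `mean_lfc`, `consistency_penalty`, `z_combined`,
#'   `p_raw`, `p_adj`, `direction`, `screen_score`, `is_hit`, plus a
#'   `few_ibars` flag for guides measured with fewer than three iBARs.
#' @export
score_sgrnas <- function(lfcs, controls = NULL, direction = c("up", "down"),
                         threshold = 1, n_bins = 10L) {
  direction <- match.arg(direction)
  stopifnot(all(c("spacer_id", "ibar", "ref_norm", "lfc") %in% names(lfcs)))
  if (is.null(controls)) {
    ctrl_mask <- rep(TRUE, nrow(lfcs))
  } else if (is.character(controls)) {
    ctrl_mask <- lfcs$spacer_id %in% controls
  } else {
    ctrl_mask <- as.logical(controls)
    stopifnot(length(ctrl_mask) == nrow(lfcs))
  }
  n_ctrl_guides <- length(unique(lfcs$spacer_id[ctrl_mask]))
  if (n_ctrl_guides < 20L) ctrl_mask <- rep(TRUE, nrow(lfcs))  # fallback null

  sigma_fun <- fit_sigma_trend(lfcs$ref_norm[ctrl_mask], lfcs$lfc[ctrl_mask],
                               n_bins = n_bins)
  z <- lfcs$lfc / sigma_fun(lfcs$ref_norm)

  # stable guide order: first appearance in the table
  ids <- unique(lfcs$spacer_id)
  grp <- split(seq_len(nrow(lfcs)), factor(lfcs$spacer_id, levels = ids))
  want_sign <- if (direction == "up") 1 else -1

  per_guide <- lapply(grp, function(ix) {
    lf <- lfcs$lfc[ix]
    zz <- z[ix]
    n <- length(ix)
    concordant <- all(sign(lf) * want_sign >= 0)
    penalty <- if (concordant || n < 2L) 1 else max(1, var(zz))
    z_comb <- sum(zz) / sqrt(n * penalty)
    c(n = n, mean_lfc = mean(lf), penalty = penalty, z_comb = z_comb,
      lfc1 = lf[1], lfc2 = if (n >= 2) lf[2] else NA_real_,
      lfc3 = if (n >= 3) lf[3] else NA_real_)
  })
  m <- do.call(rbind, per_guide)
  z_comb <- m[, "z_comb"]
  p_raw <- if (direction == "up") {
    pnorm(z_comb, lower.tail = FALSE)
  } else {
    pnorm(z_comb)
  }
  p_raw <- pmax(p_raw, .Machine$double.eps)
  p_adj <- p.adjust(p_raw, method = "BH")
  score <- screen_score(p_adj, direction)
  out <- data.frame(
    spacer_id = ids,
    n_ibars = as.integer(m[, "n"]),
    lfc_ibar1 = m[, "lfc1"], lfc_ibar2 = m[, "lfc2"], lfc_ibar3 = m[, "lfc3"],
    mean_lfc = m[, "mean_lfc"],
    consistency_penalty = m[, "penalty"],
    z_combined = z_comb,
    p_raw = p_raw,
    p_adj = p_adj,
    direction = direction,
    screen_score = score,
    few_ibars = as.integer(m[, "n"]) < 3L,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out$is_hit <- abs(out$screen_score) > threshold
  out
}

#' Signed screen score from adjusted P values
#'
#' The screen score is `-log10` of the BH-adjusted P value, negated for
#' depletion so that enriched and depleted guides sit on opposite sides of
#' zero. Zero P values are clamped to the smallest positive double.
#'
#' @param p_adj BH-adjusted P values in (0, 1].
#' @param direction `"up"` or `"down"`.
#' @return Signed numeric scores.
#' @export
screen_score <- function(p_adj, direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(all(p_adj >= 0 & p_adj <= 1))
  clamped <- pmax(p_adj, .Machine$double.xmin)
  s <- -log10(clamped)
  if (direction == "down") -s else s
}

#' Call hits from a screen result
#'
#' A guide is a hit when its absolute screen score strictly exceeds the
#' threshold (default 1, i.e. adjusted P below 0.1).
#'
#' @param results Output of [score_sgrnas()] (or any data.frame with a
#'   `screen_score` column).
#' @param threshold Strict threshold on `|screen_score|`.
#' @return `results` with `is_hit` recomputed.
#' @export
call_hits <- function(results, threshold = 1) {
  results$is_hit <- abs(results$screen_score) > threshold
  results
}

#' Run the full enrichment analysis on a count table
#'
#' Normalizes, computes per-iBAR fold changes of each sorted sample
#' against the reference, and scores both directions for each sorted
#' sample. Sense and antisense sub-libraries, when distinguishable in
#' `library`, should be analyzed separately and concatenated by the
#' caller; this helper treats the table it is given as one analysis unit.
#'
#' @param counts Count table.
#' @param samples Sample sheet data.frame (`sample`, `role`).
#' @param controls Character vector of control `spacer_id`s (or `NULL`).
#' @param directions Directions to score for each sorted sample.
#' @param threshold Hit threshold.
#' @return A data.frame of concatenated [score_sgrnas()] results with
#'   columns `sorted_sample` and `direction` identifying each analysis.
#' @export
run_screen <- function(counts, samples, controls = NULL,
                       directions = c("up", "down"), threshold = 1) {
  refs <- samples$sample[samples$role == "reference"]
  sorted <- samples$sample[samples$role != "reference"]
  if (length(refs) != 1L) stop("need exactly one reference sample", call. = FALSE)
  if (length(sorted) < 1L) stop("need at least one sorted sample", call. = FALSE)
  norm <- normalize_counts(counts)
  out <- list()
  for (smp in sorted) {
    lfcs <- per_ibar_lfc(norm, treatment = smp, reference = refs)
    for (dir in directions) {
      res <- score_sgrnas(lfcs, controls = controls, direction = dir,
                          threshold = threshold)
      res$sorted_sample <- smp
      out[[paste(smp, dir)]] <- res
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
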