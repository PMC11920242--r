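new_signature_model <- function(genes, weights, n_top, ranking = "stat") {
  stopifnot(length(genes) == length(weights), !anyDuplicated(genes))
  structure(
    list(genes = as.character(genes), weights = as.numeric(weights),
         n_top = as.integer(n_top), ranking = ranking),
    class = "signature_model"
  )
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("signature_model: %d genes (%d per direction), max|k| = %g\n",
              length(x$genes), x$n_top, max(abs(x$weights))))
  invisible(x)
}

#' Build a weighted mutation-expression signature from a DE table
#'
#' Selects the top `n_top` upregulated and top `n_top` downregulated genes
#' by Wald statistic and assigns each selected gene the normalized weight
#' `k_i = w_i / max|w|`, the maximum taken over the selected genes, so that
#' upregulated genes carry positive weights, downregulated genes negative
#' weights, and the strongest gene has `|k| = 1`. Ties are broken by gene
#' identifier.
#'
#' @param de Data.frame with columns `gene` and `stat` (Wald statistic);
#'   see [read_de_table()].
#' @param n_top Genes per direction.
#' @param ranking `"stat"` (default, consistent with Wald-statistic
#'   weights) or `"log2fc"` (requires a `log2fc` column).
#' @param max_signed Normalize by the signed maximum `max(w)` instead of
#'   `max|w|` (the literal reading of `k_i = w_i/max(w)`; weights can then
#'   exceed 1 in magnitude when depletion is stronger than enrichment).
#' @return A `signature_model`.
#' @export
build_signature <- function(de, n_top = 250L, ranking = c("stat", "log2fc"),
                            max_signed = FALSE) {
  ranking <- match.arg(ranking)
  stopifnot(all(c("gene", "stat") %in% names(de)))
  de <- de[is.finite(de$stat) & !is.na(de$gene), , drop = FALSE]
  de <- de[!duplicated(de$gene), , drop = FALSE]
  if (nrow(de) < 2L * n_top) {
    n_top <- nrow(de) %/% 2L
    warning(sprintf("fewer genes than requested; shrinking to %d per direction",
                    n_top), call. = FALSE)
  }
  key <- if (ranking == "stat") de$stat else de$log2fc
  up <- de[order(-key, de$gene)[seq_len(n_top)], , drop = FALSE]
  down <- de[order(key, de$gene)[seq_len(n_top)], , drop = FALSE]
  sel <- rbind(up, down)
  # a gene can top both directions only in degenerate all-tied tables
  sel <- sel[!duplicated(sel$gene), , drop = FALSE]
  denom <- if (max_signed) max(sel$stat) else max(abs(sel$stat))
  if (denom == 0) stop("all selected Wald statistics are zero", call. = FALSE)
  new_signature_model(sel$gene, sel$stat / denom, n_top = n_top,
                      ranking = ranking)
}

#' Score expression profiles against a signature
#'
#' The signature score of a sample is the weighted sum
#' `S = sum_i k_i * X_i` over the signature genes, with `X_i` the sample's
#' log2TPM expression. Genes absent from the profile contribute zero; the
#' number missing is reported, and a score based on fewer than half the
#' signature genes is flagged.
#'
#' @param model A `signature_model`.
#' @param profile Named numeric vector (one sample) or gene-by-sample
#'   numeric matrix of log2TPM values with gene names.
#' @return A data.frame per sample: `sample`, `score`, `n_missing`,
#'   `flagged`.
#' @export
score_profile <- function(model, profile) {
  stopifnot(inherits(model, "signature_model"))
  if (is.null(dim(profile))) {
    profile <- matrix(profile, ncol = 1,
                      dimnames = list(names(profile), "sample1"))
  }
  idx <- match(model$genes, rownames(profile))
  missing <- is.na(idx)
  x <- profile[idx[!missing], , drop = FALSE]
  scores <- as.numeric(t(x) %*% model$weights[!missing])
  n_missing <- sum(missing)
  data.frame(
    sample = colnames(profile),
    score = scores,
    n_missing = n_missing,
    flagged = n_missing > length(model$genes) / 2,
    stringsAsFactors = FALSE
  )
}

# Canonical immune-marker gene sets (human symbols as used in melanoma
# immunotherapy cohorts).
MARKER_GENE_SETS <- list(
  mhc1 = c("HLA-A", "HLA-B", "HLA-C", "B2M"),
  pdl1 = "CD274",
  ctl = c("CD8A", "CD8B", "GZMA", "GZMB", "PRF1")
)

#' Immune-marker composite scores
#'
#' Computes, per sample, the MHC-I score (mean log2TPM of HLA-A, HLA-B,
#' HLA-C and B2M), the PD-L1 score (log2TPM of CD274) and the cytotoxic T
#' lymphocyte score (mean log2TPM of CD8A, CD8B, GZMA, GZMB, PRF1).
#' Markers are averaged over the genes present; a marker whose entire gene
#' set is absent is `NA` and listed in the `missing_sets` attribute.
#'
#' @param profile Gene-by-sample log2TPM matrix (gene symbols as
#'   rownames; matching is case-insensitive to tolerate the GzmA/GZMA
#'   symbol dialects).
#' @return Data.frame per sample: `sample`, `mhc1`, `pdl1`, `ctl`.
#' @export
marker_scores <- function(profile) {
  if (is.null(dim(profile))) {
    profile <- matrix(profile, ncol = 1,
                      dimnames = list(names(profile), "sample1"))
  }
  rn <- toupper(rownames(profile))
  missing_sets <- character(0)
  one <- function(set) {
    idx <- match(toupper(set), rn)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) return(rep(NA_real_, ncol(profile)))
    colMeans(profile[idx, , drop = FALSE])
  }
  out <- data.frame(
    sample = colnames(profile),
    mhc1 = one(MARKER_GENE_SETS$mhc1),
    pdl1 = one(MARKER_GENE_SETS$pdl1),
    ctl = one(MARKER_GENE_SETS$ctl),
    stringsAsFactors = FALSE
  )
  for (nm in names(MARKER_GENE_SETS)) {
    if (all(is.na(out[[nm]]))) missing_sets <- c(missing_sets, nm)
  }
  attr(out, "missing_sets") <- missing_sets
  out
}

#' Correlate signature scores with markers and compare response groups
#'
#' Pearson correlation (with two-sided P) between per-sample signature
#' scores and a marker vector, and/or a two-tailed t test between
#' responders (PR/CR) and non-responders (PD/SD).
#'
#' @param scores Numeric signature scores per sample.
#' @param markers Optional numeric marker values, same order as `scores`.
#' @param response Optional character vector of RECIST-style response
#'   labels (`PD`, `SD`, `PR`, `CR`).
#' @return A list with elements `pearson` (`r`, `p`, `n`) and/or
#'   `response_test` (`t`, `p`, `mean_responder`, `mean_nonresponder`).
#' @export
correlate_and_compare <- function(scores, markers = NULL, response = NULL) {
  out <- list()
  if (!is.null(markers)) {
    ok <- is.finite(scores) & is.finite(markers)
    if (sum(ok) < 3L) stop("need >= 3 paired samples for correlation", call. = FALSE)
    if (sd(scores[ok]) == 0 || sd(markers[ok]) == 0) {
      out$pearson <- list(r = NA_real_, p = NA_real_, n = sum(ok),
                          flag = "zero variance")
    } else {
      ct <- cor.test(scores[ok], markers[ok], method = "pearson")
      out$pearson <- list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
    }
  }
  if (!is.null(response)) {
    stopifnot(length(response) == length(scores))
    resp <- scores[response %in% c("PR", "CR")]
    nonresp <- scores[response %in% c("PD", "SD")]
    if (length(resp) < 2L || length(nonresp) < 2L) {
      stop("need >= 2 samples per response group", call. = FALSE)
    }
    cg <- compare_groups(resp, nonresp)
    out$response_test <- list(t = cg$t, p = cg$p,
                              mean_responder = mean(resp),
                              mean_nonresponder = mean(nonresp))
  }
  out
}
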