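#' Generate a toy proteome of designable coding sequences
#'
#' Random CDS records (ATG start, no internal stop, TAA terminator) drawn
#' until each gene yields at least one missense-generating S/T/Y guide
#' under the given editor, so downstream demonstrations always have work
#' to do. Deterministic under a fixed seed.
#'
#' @param n_genes Number of genes.
#' @param cds_len_range Two-element range of CDS lengths (nt, multiples of
#'   3; the range is inclusive and lengths are rounded down to triplets).
#' @param editor Editor used for the designability check.
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling attempts per gene.
#' @return Named list of [transcript_model()] objects.
#' @export
make_toy_proteome <- function(n_genes, cds_len_range = c(300, 600),
                              editor = editor_spec(), seed = NULL,
                              max_tries = 200L) {
  stopifnot(all(cds_len_range >= 9))
  codons <- setdiff(names(Biostrings::GENETIC_CODE),
                    c("TAA", "TAG", "TGA"))
  with_seed(seed, {
    txs <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      gene <- sprintf("GENE%03d", g)
      tries <- 0L
      repeat {
        tries <- tries + 1L
        if (tries > max_tries) {
          stop("could not generate a designable CDS within retry budget",
               call. = FALSE)
        }
        len <- if (cds_len_range[1] == cds_len_range[2]) {
          cds_len_range[1]
        } else {
          sample(seq(cds_len_range[1], cds_len_range[2]), 1)
        }
        len <- (len %/% 3L) * 3L
        n_mid <- len %/% 3L - 2L
        cds <- paste0("ATG",
                      paste(sample(codons, n_mid, replace = TRUE), collapse = ""),
                      "TAA")
        tx <- transcript_model(gene, cds, protein_id = paste0(gene, "_P"))
        if (nrow(design_guides(tx, editor)) > 0L) {
          txs[[g]] <- tx
          break
        }
      }
    }
    names(txs) <- vapply(txs, `[[`, character(1), "gene_id")
    txs
  })
}

#' Configuration of a sorted-screen simulation
#'
#' Defaults mirror a two-round FACS enrichment screen collecting the
#' extreme 10% gates at about 500 reads of coverage per iBAR, with mild
#' negative-binomial overdispersion and lognormal library skew.
#'
#' @param n_hits_up,n_hits_down Number of guides planted with positive /
#'   negative selection effects.
#' @param effect Per-round log2 multiplier on a planted guide's
#'   gate-capture odds.
#' @param gate_fraction Sorted gate width as a fraction of cells.
#' @param rounds Sorting rounds.
#' @param depth Mean reads per iBAR per sample.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`).
#' @param lognormal_sigma SD (log scale) of per-iBAR reference abundances.
#' @param seed Integer seed.
#' @return A list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_hits_up = 0L, n_hits_down = 0L, effect = 2,
                              gate_fraction = 0.10, rounds = 2L, depth = 500,
                              nb_dispersion = 0.05, lognormal_sigma = 1.0,
                              seed = NULL) {
  stopifnot(gate_fraction > 0, gate_fraction < 1, depth > 0, rounds >= 1)
  structure(
    list(n_hits_up = n_hits_up, n_hits_down = n_hits_down, effect = effect,
         gate_fraction = gate_fraction, rounds = rounds, depth = depth,
         nb_dispersion = nb_dispersion, lognormal_sigma = lognormal_sigma,
         seed = seed),
    class = "screen_sim_config"
  )
}

#' Synthetic barcoded guide table
#'
#' Random distinct 20-nt spacers with iBARs and safe-harbor controls, for
#' screen-statistics simulations where sequence-level design is
#' irrelevant.
#'
#' @param n_guides Targeting guides.
#' @param n_controls Control guides.
#' @param n_ibars iBARs per guide.
#' @param seed Integer seed.
#' @return A barcoded guide table compatible with [simulate_screen()].
#' @export
make_synthetic_library <- function(n_guides, n_controls = 0L, n_ibars = 3L,
                                   seed = NULL) {
  with_seed(seed, {
    n <- n_guides + n_controls
    spacers <- character(0)
    while (length(spacers) < n) {
      need <- n - length(spacers)
      cand <- vapply(seq_len(need), function(i) {
        paste(sample(DNA_BASES, 20, replace = TRUE), collapse = "")
      }, character(1))
      spacers <- unique(c(spacers, cand))
    }
    lib <- data.frame(
      sublibrary = "sense",
      gene_id = c(sprintf("GENE%05d", seq_len(n_guides)),
                  rep("AAVS1", n_controls)),
      spacer_id = c(sprintf("g%05d", seq_len(n_guides)),
                    sprintf("AAVS1_ctrl%03d", seq_len(n_controls))),
      residue = NA_character_, residue_aa = NA_character_,
      residue_pos = NA_integer_,
      spacer = spacers, pam = "NGG", strand = "sense",
      on_target_change = NA_character_, bystanders = "", window_adenines = "",
      is_control = rep(c(FALSE, TRUE), c(n_guides, n_controls)),
      stringsAsFactors = FALSE
    )
    assign_ibars(lib, n_ibars = n_ibars, seed = sample.int(2^31 - 1, 1))
  })
}

# Gate-capture probability for a guide with per-round log2 odds effect e.
gate_capture_prob <- function(effect, gate_fraction, rounds) {
  odds0 <- gate_fraction / (1 - gate_fraction)
  odds <- odds0 * 2^(effect * rounds)
  odds / (1 + odds)
}

#' Simulate a FACS-sorted sgRNA-iBAR screen
#'
#' Reference abundances per (guide, iBAR) are lognormal. A guide with
#' selection effect `e` has its gate-capture odds multiplied by `2^e` per
#' sorting round, applied for `rounds` rounds; the expected abundance in a
#' sorted sample is proportional to reference abundance times capture
#' probability. Counts are drawn independently per iBAR from a negative
#' binomial at the configured depth. The high gate uses each guide's
#' effect as-is, the low gate its negation; controls and unselected guides
#' have effect zero.
#'
#' @param library Barcoded guide table ([make_synthetic_library()] or a
#'   designed library after [assign_ibars()]).
#' @param config A [screen_sim_config()]. `n_hits_up` / `n_hits_down`
#'   non-control guides are planted with effects `+effect` / `-effect`.
#' @param samples Which sorted samples to emit besides the reference.
#' @return A list: `counts` (count table with samples `reference` and the
#'   requested gates), `truth` (data.frame `spacer_id`, `true_effect`,
#'   `is_control`), `config`.
#' @export
simulate_screen <- function(library, config = screen_sim_config(),
                            samples = c("sorted_high", "sorted_low")) {
  stopifnot(nrow(library) > 0L)
  lib <- library_long(library)
  is_ctrl <- library$is_control[match(lib$spacer_id, library$spacer_id)]
  with_seed(config$seed, {
    guides <- unique(lib$spacer_id)
    guide_ctrl <- library$is_control[match(guides, library$spacer_id)]
    eligible <- guides[!guide_ctrl]
    n_plant <- config$n_hits_up + config$n_hits_down
    if (n_plant > length(eligible)) {
      stop("more planted hits than available non-control guides", call. = FALSE)
    }
    planted <- if (n_plant > 0) sample(eligible, n_plant) else character(0)
    effect <- setNames(rep(0, length(guides)), guides)
    if (config$n_hits_up > 0) {
      effect[planted[seq_len(config$n_hits_up)]] <- config$effect
    }
    if (config$n_hits_down > 0) {
      effect[planted[config$n_hits_up + seq_len(config$n_hits_down)]] <-
        -config$effect
    }
    e_row <- effect[lib$spacer_id]

    n <- nrow(lib)
    abund <- rlnorm(n, meanlog = 0, sdlog = config$lognormal_sigma)
    size <- 1 / config$nb_dispersion
    draw <- function(mean_abund) {
      mu <- config$depth * mean_abund / mean(mean_abund)
      rnbinom(n, size = size, mu = mu)
    }
    counts <- data.frame(spacer_id = lib$spacer_id, ibar = lib$ibar,
                         stringsAsFactors = FALSE)
    counts$reference <- draw(abund)
    if ("sorted_high" %in% samples) {
      p <- gate_capture_prob(e_row, config$gate_fraction, config$rounds)
      counts$sorted_high <- draw(abund * p)
    }
    if ("sorted_low" %in% samples) {
      p <- gate_capture_prob(-e_row, config$gate_fraction, config$rounds)
      counts$sorted_low <- draw(abund * p)
    }
    truth <- data.frame(spacer_id = guides, true_effect = unname(effect),
                        is_control = guide_ctrl, stringsAsFactors = FALSE)
    list(counts = counts, truth = truth, config = config)
  })
}

#' Simulate amplicon reads with planted editing outcomes
#'
#' Each read is assigned a target haplotype: first from the named
#' `haplotypes` fractions, the remainder wild type; wild-type reads then
#' receive independent per-position edits at the `edit_rates`
#' probabilities (A-to-G at reference adenines, C at reference thymines
#' for antisense-edited strands). Uniform sequencing errors are applied on
#' top. Reads are emitted either pre-merged (full amplicons) or as an
#' overlapping pair.
#'
#' @param spec An [amplicon_spec()].
#' @param edit_rates Numeric vector, one probability per target position
#'   (0 elsewhere), or `NULL`.
#' @param haplotypes Named numeric vector: full target haplotype sequences
#'   to fractions (must sum to at most 1), or `NULL`.
#' @param error_rate Per-base uniform sequencing error probability.
#' @param n_reads Number of reads (pairs).
#' @param seed Integer seed.
#' @param paired Emit an overlapping read pair instead of merged reads.
#' @param read_len Mate length when `paired`.
#' @return A list: `reads` (character vector of merged reads) or
#'   `r1`/`r2` plus `qual1`/`qual2` when paired, and `truth` (list with
#'   `haplotype_fractions` and `per_position_edit_rate`, the expected
#'   edited-base fraction per target position before sequencing error).
#' @export
simulate_amplicon_reads <- function(spec, edit_rates = NULL, haplotypes = NULL,
                                    error_rate = 0.001, n_reads = 10000L,
                                    seed = NULL, paired = FALSE,
                                    read_len = 150L) {
  ref_target <- target_reference(spec)
  tlen <- nchar(ref_target)
  ref_bases <- strsplit(ref_target, "")[[1]]
  if (!is.null(edit_rates)) {
    stopifnot(length(edit_rates) == tlen, all(edit_rates >= 0 & edit_rates <= 1))
    editable <- ref_bases %in% c("A", "T")
    if (any(edit_rates > 0 & !editable)) {
      stop("nonzero edit rate at a position that is neither A nor T", call. = FALSE)
    }
  }
  if (!is.null(haplotypes)) {
    stopifnot(!is.null(names(haplotypes)), all(nchar(names(haplotypes)) == tlen),
              all(haplotypes >= 0))
    if (sum(haplotypes) > 1 + 1e-12) {
      stop("haplotype fractions sum to more than 1", call. = FALSE)
    }
  }
  with_seed(seed, {
    hap_names <- names(haplotypes) %||% character(0)
    hap_frac <- unname(haplotypes) %||% numeric(0)
    probs <- c(hap_frac, 1 - sum(hap_frac))
    assign <- sample.int(length(probs), n_reads, replace = TRUE, prob = probs)
    targets <- c(hap_names, ref_target)[assign]
    wt <- assign == length(probs)
    if (!is.null(edit_rates) && any(edit_rates > 0) && any(wt)) {
      edited_to <- ifelse(ref_bases == "A", "G",
                          ifelse(ref_bases == "T", "C", ref_bases))
      wt_idx <- which(wt)
      for (pos in which(edit_rates > 0)) {
        hit <- wt_idx[runif(length(wt_idx)) < edit_rates[pos]]
        if (length(hit)) substr(targets[hit], pos, pos) <- edited_to[pos]
      }
    }
    full <- paste0(substr(spec$reference, 1L, spec$target_start),
                   targets,
                   substr(spec$reference, spec$target_end + 1L,
                          nchar(spec$reference)))
    full <- apply_sequencing_errors(full, error_rate)

    # expected per-position edited-base fraction before sequencing error
    exp_rate <- numeric(tlen)
    if (length(hap_frac)) {
      hm <- do.call(rbind, strsplit(hap_names, ""))
      for (pos in seq_len(tlen)) {
        exp_rate[pos] <- sum(hap_frac[hm[, pos] != ref_bases[pos]])
      }
    }
    if (!is.null(edit_rates)) {
      exp_rate <- exp_rate + (1 - sum(hap_frac)) * edit_rates
    }
    truth <- list(
      haplotype_fractions = c(setNames(hap_frac, hap_names),
                              WT = 1 - sum(hap_frac)),
      per_position_edit_rate = exp_rate
    )
    if (!paired) {
      return(list(reads = full, truth = truth))
    }
    L <- nchar(spec$reference)
    stopifnot(read_len <= L, 2L * read_len - L >= 1L)
    r1 <- substr(full, 1L, read_len)
    r2 <- revcomp(substring(full, L - read_len + 1L, L))
    list(r1 = r1, r2 = r2,
         qual1 = rep(strrep("I", read_len), n_reads),
         qual2 = rep(strrep("I", read_len), n_reads),
         truth = truth)
  })
}

# Uniform per-base errors: each base flips to one of the three other
# bases; vectorized over the (typically few) affected reads.
apply_sequencing_errors <- function(reads, error_rate) {
  if (error_rate <= 0) return(reads)
  L <- nchar(reads[1])
  n_err <- rbinom(length(reads), L, error_rate)
  for (i in which(n_err > 0L)) {
    pos <- sample.int(L, n_err[i])
    for (p in pos) {
      cur <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(DNA_BASES, cur), 1)
    }
  }
  reads
}

#' Simulate an expression cohort carrying a planted signature
#'
#' Signature-gene expression is `baseline + activation * k_i` plus
#' Gaussian noise; background genes are baseline plus noise. Immune-marker
#' genes can be co-activated (`marker_effect` per unit activation) to give
#' the marker correlation analyses a planted truth.
#'
#' @param model A `signature_model`.
#' @param n_samples Number of samples.
#' @param activation Per-sample activation scalars (recycled if length 1).
#' @param noise_sd Gaussian noise SD (log2TPM units).
#' @param n_background_genes Unrelated genes.
#' @param baseline Baseline log2TPM.
#' @param marker_effect Activation coefficient applied to the canonical
#'   immune-marker genes; 0 leaves them as background.
#' @param seed Integer seed.
#' @return A list: `profile` (gene-by-sample log2TPM matrix), `truth`
#'   (data.frame `sample`, `activation`).
#' @export
simulate_expression_cohort <- function(model, n_samples, activation = 0,
                                       noise_sd = 1, n_background_genes = 500L,
                                       baseline = 5, marker_effect = 0,
                                       seed = NULL) {
  stopifnot(inherits(model, "signature_model"))
  activation <- rep_len(activation, n_samples)
  with_seed(seed, {
    sig_genes <- model$genes
    bg_genes <- sprintf("BG%05d", seq_len(n_background_genes))
    marker_genes <- setdiff(toupper(unlist(MARKER_GENE_SETS)), toupper(sig_genes))
    genes <- c(sig_genes, bg_genes, marker_genes)
    n_genes <- length(genes)
    mean_mat <- matrix(baseline, nrow = n_genes, ncol = n_samples,
                       dimnames = list(genes, sprintf("S%03d", seq_len(n_samples))))
    mean_mat[seq_along(sig_genes), ] <- baseline +
      outer(model$weights, activation)
    if (marker_effect != 0 && length(marker_genes)) {
      mean_mat[marker_genes, ] <- baseline +
        matrix(rep(marker_effect * activation, each = length(marker_genes)),
               nrow = length(marker_genes))
    }
    profile <- mean_mat + matrix(rnorm(n_genes * n_samples, sd = noise_sd),
                                 nrow = n_genes)
    truth <- data.frame(sample = colnames(mean_mat), activation = activation,
                        stringsAsFactors = FALSE)
    list(profile = profile, truth = truth)
  })
}
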