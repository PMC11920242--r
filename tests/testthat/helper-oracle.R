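# Brute-force guide-design oracle, independent of design_guides():
# enumerate every 20-mer + NGG on both strands, then every non-empty subset
# of window adenine edits applied to the whole CDS, translate the full
# protein before and after, and keep (spacer, strand, residue) triples where
# an S/T/Y residue changes to a different non-stop amino acid.
oracle_design <- function(transcript, editor = editor_spec()) {
  full <- paste0(transcript$flank5, transcript$cds, transcript$flank3)
  cds_start <- nchar(transcript$flank5)
  cds_len <- nchar(transcript$cds)
  L <- nchar(full)
  plen <- editor$protospacer_len
  pam_len <- nchar(editor$pam)
  win <- seq.int(editor$window_start, editor$window_end)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(full)))

  translate_cds <- function(cds_chars) {
    n <- length(cds_chars) %/% 3L
    starts <- seq.int(1L, by = 3L, length.out = n)
    codons <- vapply(starts, function(s) {
      paste(cds_chars[s:(s + 2L)], collapse = "")
    }, character(1))
    unname(Biostrings::GENETIC_CODE[codons])
  }

  cds_chars <- strsplit(transcript$cds, "")[[1]]
  prot_ref <- translate_cds(cds_chars)

  pam_ok <- function(pam) grepl("^[ACGT]GG$", pam)  # NGG oracle
  hits <- list()
  for (strand in c("sense", "antisense")) {
    ss <- if (strand == "sense") full else rc
    if (nchar(ss) < plen + pam_len) next
    for (start1 in seq_len(nchar(ss) - plen - pam_len + 1L)) {
      spacer <- substr(ss, start1, start1 + plen - 1L)
      pam <- substr(ss, start1 + plen, start1 + plen + pam_len - 1L)
      if (!pam_ok(pam)) next
      win_abs0 <- (start1 - 1L) + win - 1L  # 0-based in ss
      bases <- substring(ss, win_abs0 + 1L, win_abs0 + 1L)
      ed <- win_abs0[bases == "A"]
      cod_pos <- if (strand == "sense") ed else (L - 1L) - ed
      cod_pos <- cod_pos[cod_pos >= cds_start & cod_pos < cds_start + cds_len]
      offs <- cod_pos - cds_start  # 0-based CDS offsets holding editable base
      if (length(offs) == 0L) next
      to <- if (strand == "sense") "G" else "C"
      for (k in seq_along(offs)) {
        for (subset in combn_list(offs, k)) {
          mut <- cds_chars
          mut[subset + 1L] <- to
          prot_alt <- translate_cds(mut)
          changed <- which(prot_ref != prot_alt)
          for (pp in changed) {
            if (prot_ref[pp] %in% c("S", "T", "Y") && prot_alt[pp] != "*") {
              hits[[length(hits) + 1L]] <- c(spacer, strand,
                                             paste0(prot_ref[pp], pp))
            }
          }
        }
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(spacer = character(), strand = character(),
                      residue = character(), stringsAsFactors = FALSE))
  }
  m <- unique(do.call(rbind, hits))
  out <- data.frame(spacer = m[, 1], strand = m[, 2], residue = m[, 3],
                    stringsAsFactors = FALSE)
  out[order(out$spacer, out$strand, out$residue), , drop = FALSE]
}

combn_list <- function(x, k) {
  if (length(x) == 1L) {
    if (k == 1L) list(x) else list()
  } else {
    utils::combn(x, k, simplify = FALSE)
  }
}

design_key <- function(tab) {
  if (nrow(tab) == 0L) return(character(0))
  sort(paste(tab$spacer, tab$strand, tab$residue, sep = "|"))
}

# Random CDS of n_codons with an ATG start and TAA stop; no internal stops.
random_cds <- function(n_codons) {
  codons <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  paste0("ATG",
         paste(sample(codons, n_codons - 2L, replace = TRUE), collapse = ""),
         "TAA")
}

random_flank <- function(n) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Rank-based AUROC of scores for separating positive from negative labels.
auroc <- function(scores, labels) {
  r <- rank(scores)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

replace_at <- function(x, pos, base) {
  substr(x, pos, pos) <- base
  x
}

# direct access to the haplotype labeller for degenerate inputs (indel,
# synonymous) that base_composition would refuse to profile alone
label_outcome_for_test <- function(spec, hap) {
  styscreen:::label_haplotype(hap, spec)
}
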