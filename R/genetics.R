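#' Translate a codon with the standard genetic code
#'
#' @param codon Character vector of 3-letter DNA codons.
#' @return One-letter amino-acid codes; `"*"` for stop codons.
#' @examples
#' translate_codon(c("ATG", "TAC", "TAA"))
#' @export
translate_codon <- function(codon) {
  stopifnot(all(nchar(codon) == 3L))
  unname(Biostrings::GENETIC_CODE[toupper(codon)])
}

#' Construct a transcript model
#'
#' A transcript model carries the coding sequence (coding strand, frame 0)
#' plus optional genomic flanks used for protospacer and PAM search beyond
#' the CDS bounds.
#'
#' @param gene_id,protein_id Identifiers.
#' @param cds Coding DNA sequence; length must be a multiple of 3.
#' @param flank5,flank3 Genomic context upstream/downstream of the CDS
#'   (coding-strand orientation); may be empty strings.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(gene_id, cds, protein_id = gene_id,
                             flank5 = "", flank3 = "") {
  cds <- toupper(cds)
  flank5 <- toupper(flank5)
  flank3 <- toupper(flank3)
  assert_dna(cds, "cds")
  if (nzchar(flank5)) assert_dna(flank5, "flank5")
  if (nzchar(flank3)) assert_dna(flank3, "flank3")
  if (nchar(cds) %% 3L != 0L) {
    stop("CDS length must be a multiple of 3", call. = FALSE)
  }
  structure(
    list(gene_id = gene_id, protein_id = protein_id, cds = cds,
         flank5 = flank5, flank3 = flank3),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (%s): %d nt CDS, flanks %d/%d nt\n",
              x$gene_id, x$protein_id, nchar(x$cds),
              nchar(x$flank5), nchar(x$flank3)))
  invisible(x)
}

#' Enumerate serine, threonine and tyrosine codons of a CDS
#'
#' @param transcript A [transcript_model()].
#' @return A data.frame with one row per S/T/Y codon: `protein_pos`
#'   (1-based), `aa`, `codon`, and `cds_offset` (0-based offset of the
#'   codon's first base within the CDS).
#' @examples
#' tx <- transcript_model("g", "AGTACTTAT")
#' enumerate_sty_residues(tx)
#' @export
enumerate_sty_residues <- function(transcript) {
  stopifnot(inherits(transcript, "transcript_model"))
  n_codon <- nchar(transcript$cds) %/% 3L
  if (n_codon == 0L) {
    return(data.frame(protein_pos = integer(), aa = character(),
                      codon = character(), cds_offset = integer(),
                      stringsAsFactors = FALSE))
  }
  starts <- seq.int(1L, by = 3L, length.out = n_codon)
  codons <- substring(transcript$cds, starts, starts + 2L)
  aa <- translate_codon(codons)
  keep <- aa %in% c("S", "T", "Y")
  data.frame(
    protein_pos = which(keep),
    aa = aa[keep],
    codon = codons[keep],
    cds_offset = starts[keep] - 1L,
    stringsAsFactors = FALSE
  )
}

#' Predict the consequence of adenine base edits within one codon
#'
#' Applies the ABE chemistry to a codon: A-to-G at the stated codon
#' positions for a sense-strand protospacer, or T-to-C (the coding-strand
#' view of an antisense A-to-G edit) for an antisense protospacer, then
#' translates the edited codon.
#'
#' @param codon 3-letter DNA codon (coding strand).
#' @param positions Integer subset of `c(1, 2, 3)`: codon positions edited.
#' @param strand `"sense"` or `"antisense"` (protospacer strand relative to
#'   the coding strand).
#' @return A list with `new_codon`, `new_aa`, and `category` in
#'   `"missense"`, `"synonymous"`, `"stop_gain"`, or `"other"`.
#' @examples
#' codon_edit_outcomes("TAC", 2, "sense")      # Tyr -> Cys
#' codon_edit_outcomes("TCT", 1, "antisense")  # Ser -> Pro
#' @export
codon_edit_outcomes <- function(codon, positions, strand = c("sense", "antisense")) {
  strand <- match.arg(strand)
  codon <- toupper(codon)
  stopifnot(nchar(codon) == 3L, length(positions) >= 1L,
            all(positions %in% 1:3))
  positions <- sort(unique(as.integer(positions)))
  from <- if (strand == "sense") "A" else "T"
  to <- if (strand == "sense") "G" else "C"
  bases <- strsplit(codon, "")[[1]]
  if (any(bases[positions] != from)) {
    stop(sprintf("edited codon position does not hold %s (%s strand)",
                 from, strand), call. = FALSE)
  }
  bases[positions] <- to
  new_codon <- paste(bases, collapse = "")
  old_aa <- translate_codon(codon)
  new_aa <- translate_codon(new_codon)
  category <- if (new_aa == old_aa) {
    "synonymous"
  } else if (new_aa == "*") {
    "stop_gain"
  } else if (old_aa == "*") {
    "other"
  } else {
    "missense"
  }
  list(new_codon = new_codon, new_aa = new_aa, category = category)
}
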