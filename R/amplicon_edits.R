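#' Amplicon specification for editing-outcome quantification
#'
#' Describes a ~200-bp amplicon around an sgRNA target site. The target
#' region is addressed 0-based half-open within the reference; the 10-bp
#' flanks used to locate it in reads are derived from the reference.
#'
#' @param reference Amplicon reference sequence (sequencing orientation).
#' @param target_start,target_end 0-based half-open target interval.
#' @param cds_strand `"+"` if the coding strand equals the reference
#'   orientation, `"-"` if it is the reverse complement.
#' @param frame_offset Codon phase of the first target base in coding
#'   orientation: 0, 1 or 2 bases of its codon precede the target.
#' @param residues Optional data.frame (`protein_pos`, `aa`,
#'   `codon_start`) anchoring protein numbering: `codon_start` is the
#'   0-based offset, in coding orientation, of the residue's codon start
#'   relative to the target start (negative if the codon begins upstream of
#'   the target).
#' @param flank_len Flank length used for read location (default 10 bp).
#' @return An object of class `amplicon_spec`.
#' @export
amplicon_spec <- function(reference, target_start, target_end,
                          cds_strand = c("+", "-"), frame_offset = 0L,
                          residues = NULL, flank_len = 10L) {
  cds_strand <- match.arg(cds_strand)
  reference <- toupper(reference)
  assert_dna(reference, "reference")
  L <- nchar(reference)
  stopifnot(target_start >= flank_len, target_end + flank_len <= L,
            target_start < target_end, frame_offset %in% 0:2)
  if (!is.null(residues)) {
    stopifnot(all(c("protein_pos", "aa", "codon_start") %in% names(residues)))
  }
  structure(
    list(
      reference = reference,
      target_start = as.integer(target_start),
      target_end = as.integer(target_end),
      flank5 = substr(reference, target_start - flank_len + 1L, target_start),
      flank3 = substr(reference, target_end + 1L, target_end + flank_len),
      cds_strand = cds_strand,
      frame_offset = as.integer(frame_offset),
      residues = residues,
      flank_len = as.integer(flank_len)
    ),
    class = "amplicon_spec"
  )
}

target_reference <- function(spec) {
  substr(spec$reference, spec$target_start + 1L, spec$target_end)
}

#' Read an amplicon specification from YAML or JSON
#'
#' Keys mirror the [amplicon_spec()] arguments; `residues` is a list of
#' mappings with `protein_pos`, `aa`, `codon_start`.
#'
#' @param path File path.
#' @return An `amplicon_spec`.
#' @export
read_amplicon_spec <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  res <- cfg$residues
  if (!is.null(res) && !is.data.frame(res)) {
    res <- do.call(rbind, lapply(res, as.data.frame))
  }
  amplicon_spec(cfg$reference, cfg$target_start, cfg$target_end,
                cds_strand = cfg$cds_strand %||% "+",
                frame_offset = cfg$frame_offset %||% 0L,
                residues = res,
                flank_len = cfg$flank_len %||% 10L)
}

# Hamming mismatches between two equal-length raw vectors.
raw_mismatches <- function(a, b) sum(a != b)

#' Merge overlapping read pairs
#'
#' A simple overlap merger: for each pair the reverse complement of read 2
#' is slid along read 1; the overlap with the most matching bases wins,
#' subject to a minimum length and a maximum mismatch fraction.
#' Disagreements within the overlap are resolved in favour of the
#' higher-quality base. Unmergeable pairs are dropped and tallied.
#'
#' @param r1,r2 FASTQ paths or lists as returned by [read_fastq()], mates
#'   in sync.
#' @param min_overlap Minimum acceptable overlap in nt.
#' @param max_mismatch_frac Maximum mismatch fraction within the overlap.
#' @return A list: `seq` (merged sequences), `n_dropped`.
#' @export
merge_pairs <- function(r1, r2, min_overlap = 20L, max_mismatch_frac = 0.1) {
  if (is.character(r1)) r1 <- read_fastq(r1)
  if (is.character(r2)) r2 <- read_fastq(r2)
  if (length(r1$seq) != length(r2$seq)) {
    stop("mate files differ in read count", call. = FALSE)
  }
  n <- length(r1$seq)
  rc2 <- revcomp(r2$seq)
  q2r <- vapply(strsplit(r2$qual, ""), function(q) {
    paste(rev(q), collapse = "")
  }, character(1))
  merged <- character(n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    s1 <- charToRaw(r1$seq[i]); s2 <- charToRaw(rc2[i])
    q1 <- charToRaw(r1$qual[i]); q2 <- charToRaw(q2r[i])
    l1 <- length(s1); l2 <- length(s2)
    if (min(l1, l2) < min_overlap) next
    best_o <- 0L; best_matches <- -1L
    for (o in seq.int(min(l1, l2), min_overlap, by = -1L)) {
      a <- s1[(l1 - o + 1L):l1]
      b <- s2[seq_len(o)]
      mm <- raw_mismatches(a, b)
      if (mm / o <= max_mismatch_frac) {
        matches <- o - mm
        if (matches > best_matches) {
          best_matches <- matches
          best_o <- o
        }
        if (mm == 0L) break  # cannot beat a perfect overlap of maximal length
      }
    }
    if (best_o < min_overlap) next
    o <- best_o
    ov1 <- (l1 - o + 1L):l1
    ov2 <- seq_len(o)
    cons <- s1[ov1]
    use2 <- s1[ov1] != s2[ov2] & q2[ov2] > q1[ov1]
    cons[use2] <- s2[ov2][use2]
    tail2 <- if (o < l2) s2[(o + 1L):l2] else raw(0)
    merged[i] <- rawToChar(c(s1[seq_len(l1 - o)], cons, tail2))
    keep[i] <- TRUE
  }
  list(seq = merged[keep], n_dropped = sum(!keep))
}

#' Extract the sgRNA-targeted region from reads by its flanks
#'
#' Locates the 10-bp flanking sequences of the target region in each read
#' (allowing `max_flank_mismatch` mismatches per flank) and returns the
#' enclosed subsequence. Reads with no or ambiguous placements yield `NA`.
#'
#' @param reads Character vector of (merged) read sequences.
#' @param spec An [amplicon_spec()].
#' @param max_flank_mismatch Mismatches tolerated per flank.
#' @param try_revcomp Also search the reverse complement of unlocated
#'   reads.
#' @return Character vector of extracted targets (`NA` where unlocated).
#' @export
locate_target <- function(reads, spec, max_flank_mismatch = 1L,
                          try_revcomp = FALSE) {
  locate_once <- function(rds) {
    set <- Biostrings::DNAStringSet(rds)
    m5 <- Biostrings::vmatchPattern(spec$flank5, set,
                                    max.mismatch = max_flank_mismatch)
    m3 <- Biostrings::vmatchPattern(spec$flank3, set,
                                    max.mismatch = max_flank_mismatch)
    out <- rep(NA_character_, length(rds))
    n5 <- S4Vectors::elementNROWS(m5)
    n3 <- S4Vectors::elementNROWS(m3)
    ok <- n5 == 1L & n3 == 1L
    if (any(ok)) {
      e5 <- unlist(IRanges::end(m5[ok]))
      s3 <- unlist(IRanges::start(m3[ok]))
      good <- s3 > e5
      idx <- which(ok)[good]
      out[idx] <- substr(rds[idx], e5[good] + 1L, s3[good] - 1L)
    }
    out
  }
  out <- locate_once(reads)
  if (try_revcomp && anyNA(out)) {
    miss <- is.na(out)
    out[miss] <- locate_once(revcomp(reads[miss]))
  }
  out
}

#' Per-position base composition and allele table of an amplicon
#'
#' Locates the target region in each read, tabulates the A/C/G/T fraction
#' at every target position over length-conserved reads, and builds an
#' allele (haplotype) table. Reads whose extracted target differs in
#' length from the reference target carry indels and are tallied
#' separately, excluded from positional composition.
#'
#' @param reads Character vector of merged reads (or already-extracted
#'   targets if `located = TRUE`).
#' @param spec An [amplicon_spec()].
#' @param max_flank_mismatch Passed to [locate_target()].
#' @param located Set `TRUE` when `reads` are already extracted targets.
#' @return An object of class `amplicon_profile`: `composition`
#'   (data.frame `position` 1-based in target, `ref`, `fA`, `fC`, `fG`,
#'   `fT`, `coverage`), `allele_table` (`haplotype`, `count`, `fraction`),
#'   `n_reads_used`, `n_indel`, `n_unlocated`.
#' @export
base_composition <- function(reads, spec, max_flank_mismatch = 1L,
                             located = FALSE) {
  targets <- if (located) reads else locate_target(reads, spec, max_flank_mismatch)
  n_unlocated <- sum(is.na(targets))
  targets <- targets[!is.na(targets)]
  ref <- target_reference(spec)
  tlen <- nchar(ref)
  is_len_ok <- nchar(targets) == tlen
  n_indel <- sum(!is_len_ok)
  used <- targets[is_len_ok]
  if (length(used) == 0L) {
    stop("no located, length-conserved reads to profile", call. = FALSE)
  }
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(used))
  bases <- DNA_BASES
  cnt <- matrix(0, nrow = 4, ncol = tlen, dimnames = list(bases, NULL))
  for (b in bases) if (b %in% rownames(cm)) cnt[b, ] <- cm[b, ]
  cov <- colSums(cnt)
  frac <- sweep(cnt, 2, pmax(cov, 1), "/")
  composition <- data.frame(
    position = seq_len(tlen),
    ref = strsplit(ref, "")[[1]],
    fA = frac["A", ], fC = frac["C", ], fG = frac["G", ], fT = frac["T", ],
    coverage = cov,
    stringsAsFactors = FALSE
  )
  tab <- sort(table(used), decreasing = TRUE)
  allele_table <- data.frame(
    haplotype = names(tab),
    count = as.integer(tab),
    fraction = as.numeric(tab) / length(used),
    stringsAsFactors = FALSE
  )
  structure(
    list(composition = composition, allele_table = allele_table,
         n_reads_used = length(used), n_indel = n_indel,
         n_unlocated = n_unlocated),
    class = "amplicon_profile"
  )
}

#' @export
print.amplicon_profile <- function(x, ...) {
  cat(sprintf("amplicon_profile: %d reads used, %d indel, %d unlocated; %d alleles\n",
              x$n_reads_used, x$n_indel, x$n_unlocated, nrow(x$allele_table)))
  invisible(x)
}

# Translate one target haplotype against the reference; returns the
# amino-acid outcome label.
label_haplotype <- function(hap, spec) {
  ref_target <- target_reference(spec)
  if (nchar(hap) != nchar(ref_target)) return("indel")
  if (hap == ref_target) return("WT")
  full_alt <- paste0(
    substr(spec$reference, 1L, spec$target_start),
    hap,
    substr(spec$reference, spec$target_end + 1L, nchar(spec$reference))
  )
  L <- nchar(spec$reference)
  if (spec$cds_strand == "+") {
    cref <- spec$reference; calt <- full_alt
    cs <- spec$target_start; ce <- spec$target_end
  } else {
    cref <- revcomp(spec$reference); calt <- revcomp(full_alt)
    cs <- L - spec$target_end; ce <- L - spec$target_start
  }
  first_codon <- cs - spec$frame_offset
  codon_starts <- seq.int(first_codon, ce - 1L, by = 3L)
  changes <- character(0)
  positions <- integer(0)
  for (c0 in codon_starts) {
    if (c0 < 0L || c0 + 3L > L) next
    rc <- substr(cref, c0 + 1L, c0 + 3L)
    ac <- substr(calt, c0 + 1L, c0 + 3L)
    if (rc == ac) next
    raa <- translate_codon(rc)
    aaa <- translate_codon(ac)
    if (raa == aaa) next
    ppos <- protein_pos_for(c0 - cs, spec)
    changes <- c(changes, sprintf("%s%s%s", raa,
                                  if (is.na(ppos)) "?" else ppos, aaa))
    positions <- c(positions, if (is.na(ppos)) .Machine$integer.max else ppos)
  }
  if (length(changes) == 0L) return("synonymous")
  paste(changes[order(positions)], collapse = "/")
}

# Protein position of the codon starting at `codon_start` (0-based, coding
# orientation, relative to target start), anchored on spec$residues.
protein_pos_for <- function(codon_start, spec) {
  res <- spec$residues
  if (is.null(res) || nrow(res) == 0L) {
    return((codon_start + spec$frame_offset) %/% 3L + 1L)
  }
  anchor <- res[1, ]
  anchor$protein_pos + (codon_start - anchor$codon_start) %/% 3L
}

#' Label alleles with their amino-acid outcomes
#'
#' Translates each observed haplotype in frame against the reference and
#' labels it `"WT"`, `"synonymous"`, `"indel"`, or a slash-separated list
#' of amino-acid changes sorted by protein position (e.g. `"Y98C"`,
#' `"L512P/S513P"`).
#'
#' @param profile An `amplicon_profile` from [base_composition()].
#' @param spec The matching [amplicon_spec()].
#' @return The profile with an `aa_outcome` column added to its
#'   `allele_table`.
#' @export
call_aa_outcomes <- function(profile, spec) {
  stopifnot(inherits(profile, "amplicon_profile"), inherits(spec, "amplicon_spec"))
  profile$allele_table$aa_outcome <- vapply(
    profile$allele_table$haplotype, label_haplotype, character(1), spec = spec,
    USE.NAMES = FALSE
  )
  profile
}

#' Per-position editing efficiency
#'
#' At reference-adenine positions the editing efficiency is the G
#' fraction; at reference-thymine positions (antisense editing viewed on
#' this strand) it is the C fraction; elsewhere `NA`.
#'
#' @param profile An `amplicon_profile`.
#' @return Numeric vector, one value per target position.
#' @export
editing_efficiency <- function(profile) {
  comp <- profile$composition
  ifelse(comp$ref == "A", comp$fG, ifelse(comp$ref == "T", comp$fC, NA_real_))
}

#' Write an amplicon profile to TSV files
#'
#' @param profile An `amplicon_profile` (ideally after
#'   [call_aa_outcomes()]).
#' @param prefix Output path prefix; writes `<prefix>.composition.tsv`,
#'   `<prefix>.alleles.tsv` and `<prefix>.summary.json`.
#' @export
write_amplicon_profile <- function(profile, prefix) {
  write.table(profile$composition, paste0(prefix, ".composition.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(profile$allele_table, paste0(prefix, ".alleles.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n_reads_used = profile$n_reads_used, n_indel = profile$n_indel,
         n_unlocated = profile$n_unlocated),
    paste0(prefix, ".summary.json"), auto_unbox = TRUE
  )
  invisible(prefix)
}

#' @rdname write_amplicon_profile
#' @param prefix_or_path Prefix used when writing.
#' @export
read_composition_tsv <- function(prefix_or_path) {
  path <- if (file.exists(prefix_or_path)) {
    prefix_or_path
  } else {
    paste0(prefix_or_path, ".composition.tsv")
  }
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(ref = "character"))
}
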