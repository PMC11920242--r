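#' Adenine base editor specification
#'
#' Describes the editor geometry used for guide design: protospacer length,
#' PAM, and the activity window within which A-to-G conversion is assumed
#' achievable. The default window, protospacer positions 4-8 counting from
#' the PAM-distal end, is the canonical ABEmax activity window; it is
#' configurable because editors differ.
#'
#' @param window_start,window_end 1-based protospacer positions bounding the
#'   editing window (inclusive).
#' @param protospacer_len Protospacer length in nt.
#' @param pam PAM as an IUPAC pattern, 5' to 3' immediately downstream of
#'   the protospacer.
#' @return An object of class `editor_spec`.
#' @export
editor_spec <- function(window_start = 4L, window_end = 8L,
                        protospacer_len = 20L, pam = "NGG") {
  window_start <- as.integer(window_start)
  window_end <- as.integer(window_end)
  protospacer_len <- as.integer(protospacer_len)
  if (!(1L <= window_start && window_start <= window_end &&
        window_end <= protospacer_len)) {
    stop("require 1 <= window_start <= window_end <= protospacer_len",
         call. = FALSE)
  }
  if (!nzchar(pam)) stop("PAM pattern must be non-empty", call. = FALSE)
  structure(
    list(window_start = window_start, window_end = window_end,
         protospacer_len = protospacer_len, pam = toupper(pam)),
    class = "editor_spec"
  )
}

#' Read an editor specification from a YAML or JSON file
#'
#' Recognised keys: `window_start`, `window_end`, `protospacer_len`, `pam`;
#' missing keys fall back to the [editor_spec()] defaults.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return An `editor_spec`.
#' @export
read_editor_spec <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  dflt <- editor_spec()
  editor_spec(
    window_start = cfg$window_start %||% dflt$window_start,
    window_end = cfg$window_end %||% dflt$window_end,
    protospacer_len = cfg$protospacer_len %||% dflt$protospacer_len,
    pam = cfg$pam %||% dflt$pam
  )
}

# IUPAC pattern -> regular expression character classes.
iupac_regex <- function(pattern) {
  map <- Biostrings::IUPAC_CODE_MAP
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- !(chars %in% names(map))
  if (any(bad)) stop("invalid IUPAC code in PAM pattern", call. = FALSE)
  paste0(vapply(chars, function(ch) {
    expand <- map[[ch]]
    if (nchar(expand) == 1L) expand else paste0("[", expand, "]")
  }, character(1)), collapse = "")
}

# One strand's worth of protospacer scanning. `seqchar` is the search
# sequence in protospacer orientation; returns 0-based protospacer start
# positions with a matching PAM.
scan_protospacers <- function(seqchar, editor) {
  L <- nchar(seqchar)
  plen <- editor$protospacer_len
  pam_len <- nchar(editor$pam)
  n <- L - plen - pam_len + 1L
  if (n < 1L) return(integer())
  starts <- seq_len(n)  # 1-based
  pams <- substring(seqchar, starts + plen, starts + plen + pam_len - 1L)
  hit <- grepl(paste0("^", iupac_regex(editor$pam), "$"), pams)
  starts[hit] - 1L
}

# Consequence of editing all window-editable bases of one codon, plus the
# per-subset outcomes needed to decide missense feasibility.
codon_window_outcomes <- function(codon, codon_positions, strand) {
  subsets <- if (length(codon_positions) == 1L) {
    list(codon_positions)
  } else {
    unlist(lapply(seq_along(codon_positions), function(k) {
      utils::combn(codon_positions, k, simplify = FALSE)
    }), recursive = FALSE)
  }
  out <- lapply(subsets, function(ps) codon_edit_outcomes(codon, ps, strand))
  all_idx <- length(subsets)  # combn emits the full set last
  list(all = out[[all_idx]], subsets = subsets, outcomes = out)
}

#' Design missense-generating sgRNAs for S/T/Y residues
#'
#' Scans both strands of `flank5 + cds + flank3` for protospacers with a
#' matching PAM, and emits one guide per (protospacer, strand, S/T/Y
#' residue) such that the residue's codon has at least one editable base in
#' the editing window and some combination of window edits converts it to a
#' different non-stop amino acid. Edits are A-to-G on the protospacer
#' strand, i.e. T-to-C on the coding strand for antisense guides.
#'
#' The `on_target_change` column records the outcome when all
#' window-editable bases of the residue's codon are edited (multi-adenine
#' windows routinely convert every adenine); if that joint outcome is not
#' itself missense the largest missense-yielding subset is reported
#' instead. `bystanders` records amino-acid changes at other codons
#' overlapping the window, again under the all-window-edits outcome.
#'
#' @param transcript A [transcript_model()].
#' @param editor An [editor_spec()].
#' @return A `data.frame` guide table with columns `sublibrary`, `gene_id`,
#'   `spacer_id`, `residue`, `residue_aa`, `residue_pos`, `spacer`, `pam`,
#'   `strand`, `on_target_change`, `bystanders` (slash-separated),
#'   `window_adenines` (comma-separated coding-strand CDS offsets, 0-based),
#'   `is_control`. Zero rows when the transcript offers no designable site.
#' @export
design_guides <- function(transcript, editor = editor_spec()) {
  stopifnot(inherits(transcript, "transcript_model"),
            inherits(editor, "editor_spec"))
  full <- paste0(transcript$flank5, transcript$cds, transcript$flank3)
  cds_start <- nchar(transcript$flank5)  # 0-based offset of CDS in `full`
  cds_len <- nchar(transcript$cds)
  L <- nchar(full)
  plen <- editor$protospacer_len
  win <- seq.int(editor$window_start, editor$window_end) - 1L  # 0-based in protospacer
  rc <- revcomp(full)

  rows <- list()
  for (strand in c("sense", "antisense")) {
    search_seq <- if (strand == "sense") full else rc
    base_needed <- "A"  # protospacer-strand adenines are the substrate
    for (p0 in scan_protospacers(search_seq, editor)) {
      spacer <- substr(search_seq, p0 + 1L, p0 + plen)
      pam <- substr(search_seq, p0 + plen + 1L, p0 + plen + nchar(editor$pam))
      win_abs <- p0 + win  # 0-based in search_seq
      bases <- substring(search_seq, win_abs + 1L, win_abs + 1L)
      edit_abs <- win_abs[bases == base_needed]
      # map to coding-strand coordinates within the CDS
      coding_pos <- if (strand == "sense") edit_abs else (L - 1L) - edit_abs
      in_cds <- coding_pos >= cds_start & coding_pos < cds_start + cds_len
      coding_pos <- coding_pos[in_cds]
      if (length(coding_pos) == 0L) next
      cds_off <- coding_pos - cds_start
      codon_idx <- cds_off %/% 3L            # 0-based codon index
      codon_pos <- cds_off %% 3L + 1L        # 1..3 within codon

      per_codon <- split(codon_pos, codon_idx)
      labels <- character()
      on_target <- NULL
      bystanders <- character()
      sty_rows <- list()
      for (ci_chr in names(per_codon)) {
        ci <- as.integer(ci_chr)
        codon <- substr(transcript$cds, ci * 3L + 1L, ci * 3L + 3L)
        aa <- translate_codon(codon)
        cw <- codon_window_outcomes(codon, per_codon[[ci_chr]], strand)
        all_out <- cw$all
        if (aa %in% c("S", "T", "Y")) {
          missense_idx <- which(vapply(cw$outcomes, function(o) {
            o$category == "missense"
          }, logical(1)))
          if (length(missense_idx) > 0L) {
            chosen <- if (all_out$category == "missense") {
              all_out
            } else {
              # largest missense subset (combn orders by size)
              cw$outcomes[[missense_idx[length(missense_idx)]]]
            }
            sty_rows[[length(sty_rows) + 1L]] <- list(
              protein_pos = ci + 1L, aa = aa,
              change = sprintf("%s%d%s", aa, ci + 1L, chosen$new_aa)
            )
          }
        }
        if (all_out$new_aa != aa) {
          labels <- c(labels, sprintf("%s%d%s", aa, ci + 1L, all_out$new_aa))
        }
      }
      if (length(sty_rows) == 0L) next
      win_adenines <- paste(sort(cds_off), collapse = ",")
      for (sr in sty_rows) {
        bys <- setdiff(labels, sr$change)
        rows[[length(rows) + 1L]] <- data.frame(
          sublibrary = strand,
          gene_id = transcript$gene_id,
          spacer_id = NA_character_,
          residue = sprintf("%s%d", sr$aa, sr$protein_pos),
          residue_aa = sr$aa,
          residue_pos = sr$protein_pos,
          spacer = spacer,
          pam = pam,
          strand = strand,
          on_target_change = sr$change,
          bystanders = paste(bys, collapse = "/"),
          window_adenines = win_adenines,
          is_control = FALSE,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(rows) == 0L) empty_library_table() else do.call(rbind, rows)
  out <- unique(out)
  if (nrow(out) > 0L) {
    out$spacer_id <- make.unique(
      paste(out$gene_id, out$residue, substr(out$strand, 1, 1), sep = "_"),
      sep = "."
    )
    rownames(out) <- NULL
  }
  out
}

empty_library_table <- function() {
  data.frame(
    sublibrary = character(), gene_id = character(), spacer_id = character(),
    residue = character(), residue_aa = character(), residue_pos = integer(),
    spacer = character(), pam = character(), strand = character(),
    on_target_change = character(), bystanders = character(),
    window_adenines = character(), is_control = logical(),
    stringsAsFactors = FALSE
  )
}

#' Design a library across a set of transcripts
#'
#' Convenience wrapper over [design_guides()] that concatenates per-gene
#' guide tables.
#'
#' @param transcripts List of [transcript_model()] objects.
#' @param editor An [editor_spec()].
#' @return A guide table (see [design_guides()]).
#' @export
design_library <- function(transcripts, editor = editor_spec()) {
  tabs <- lapply(transcripts, design_guides, editor = editor)
  out <- do.call(rbind, c(list(empty_library_table()), tabs))
  rownames(out) <- NULL
  out
}

# Barcode candidates of a given length with no homopolymer run >= 4.
has_long_homopolymer <- function(x, max_run = 3L) {
  grepl(sprintf("A{%d}|C{%d}|G{%d}|T{%d}",
                max_run + 1L, max_run + 1L, max_run + 1L, max_run + 1L), x)
}

#' Assign internal barcodes (iBARs) to each guide
#'
#' Each guide receives `n_ibars` distinct random barcodes drawn from the
#' set of DNA words of the given length with no homopolymer run of four or
#' more. Uniqueness is enforced within a guide, not globally: the iBARs act
#' as internal replicates of the same sgRNA, so collisions between guides
#' carry no information. Assignment is deterministic under a fixed seed.
#'
#' @param library A guide table from [design_guides()] / [add_controls()].
#' @param n_ibars Barcodes per guide.
#' @param length Barcode length in nt.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return The guide table with character columns `ibar1..ibarN` appended.
#' @export
assign_ibars <- function(library, n_ibars = 3L, length = 6L, seed = NULL) {
  stopifnot(is.data.frame(library), n_ibars >= 1L, length >= 1L)
  n_words <- 4^length
  if (n_words < n_ibars * 4) {  # crude capacity guard before filtering
    stop("barcode space too small for requested iBAR count", call. = FALSE)
  }
  with_seed(seed, {
    draw_one <- function() {
      bars <- character(0)
      tries <- 0L
      while (base::length(bars) < n_ibars) {
        tries <- tries + 1L
        if (tries > 1000L) stop("barcode space exhausted", call. = FALSE)
        cand <- paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
        if (!has_long_homopolymer(cand) && !(cand %in% bars)) {
          bars <- c(bars, cand)
        }
      }
      bars
    }
    mat <- t(vapply(seq_len(nrow(library)), function(i) draw_one(),
                    character(n_ibars)))
    if (nrow(library) == 0L) {
      mat <- matrix(character(), 0L, n_ibars)
    }
    colnames(mat) <- paste0("ibar", seq_len(n_ibars))
    cbind(library[setdiff(names(library), colnames(mat))],
          as.data.frame(mat, stringsAsFactors = FALSE))
  })
}

#' Add safe-harbor negative-control guides
#'
#' Appends control spacers (by default labelled AAVS1, the human
#' safe-harbor locus) to every sub-library present in the table, so that
#' sense and antisense sub-libraries share the same controls.
#'
#' @param library A guide table.
#' @param control_spacers Character vector of 20-nt control spacers.
#' @param label Gene label for the controls.
#' @return The guide table with control rows appended, flagged
#'   `is_control = TRUE`.
#' @export
add_controls <- function(library, control_spacers, label = "AAVS1") {
  stopifnot(is.data.frame(library))
  if (length(control_spacers) == 0L) return(library)
  control_spacers <- toupper(control_spacers)
  assert_dna(control_spacers, "control spacer")
  if (anyDuplicated(control_spacers)) {
    stop("duplicate control spacers", call. = FALSE)
  }
  if (any(control_spacers %in% library$spacer)) {
    stop("control spacer collides with a library spacer", call. = FALSE)
  }
  plen <- if (nrow(library) > 0L) unique(nchar(library$spacer)) else 20L
  if (any(nchar(control_spacers) != plen[1])) {
    stop(sprintf("control spacers must be %d nt", plen[1]), call. = FALSE)
  }
  sublibs <- unique(library$sublibrary)
  if (length(sublibs) == 0L) sublibs <- "controls"
  ctrl_one <- function(sublib) {
    n <- length(control_spacers)
    data.frame(
      sublibrary = sublib,
      gene_id = label,
      spacer_id = sprintf("%s_ctrl%02d", label, seq_len(n)),
      residue = NA_character_, residue_aa = NA_character_,
      residue_pos = NA_integer_,
      spacer = control_spacers, pam = NA_character_, strand = NA_character_,
      on_target_change = NA_character_, bystanders = "",
      window_adenines = "", is_control = TRUE,
      stringsAsFactors = FALSE
    )
  }
  ctrls <- do.call(rbind, lapply(sublibs, ctrl_one))
  extra <- setdiff(names(library), names(ctrls))
  for (cl in extra) ctrls[[cl]] <- NA_character_
  out <- rbind(library, ctrls[names(library)])
  rownames(out) <- NULL
  out
}
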