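#' Read coding sequences from FASTA
#'
#' Headers are parsed as `gene_id|protein_id`; a header without `|` uses
#' the whole name for both. Flanks default to empty.
#'
#' @param path FASTA file of CDS records.
#' @return A named list of [transcript_model()] objects.
#' @export
read_cds_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  parts <- strsplit(nm, "|", fixed = TRUE)
  txs <- lapply(seq_along(seqs), function(i) {
    gene <- parts[[i]][1]
    prot <- if (length(parts[[i]]) > 1L) parts[[i]][2] else gene
    transcript_model(gene, as.character(seqs[[i]]), protein_id = prot)
  })
  names(txs) <- vapply(txs, `[[`, character(1), "gene_id")
  txs
}

#' Write transcript models to FASTA
#'
#' @param transcripts List of [transcript_model()] objects.
#' @param path Output FASTA path.
#' @export
write_cds_fasta <- function(transcripts, path) {
  seqs <- Biostrings::DNAStringSet(vapply(transcripts, `[[`, character(1), "cds"))
  names(seqs) <- vapply(transcripts, function(tx) {
    paste(tx$gene_id, tx$protein_id, sep = "|")
  }, character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read and write guide library tables
#'
#' Plain TSV with one row per guide and `ibar1..ibarN` columns once
#' barcodes are assigned.
#'
#' @param library A guide table.
#' @param path File path.
#' @return `read_library_tsv` returns the guide table; `write_library_tsv`
#'   returns `path` invisibly.
#' @export
write_library_tsv <- function(library, path) {
  write.table(library, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' @rdname write_library_tsv
#' @export
read_library_tsv <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE, na.strings = "",
                    colClasses = "character")
  out$residue_pos <- as.integer(out$residue_pos)
  out$is_control <- as.logical(out$is_control)
  out$bystanders[is.na(out$bystanders)] <- ""
  out$window_adenines[is.na(out$window_adenines)] <- ""
  out
}

#' Read and write sgRNA-iBAR count tables
#'
#' Count tables are data.frames with key columns `spacer_id`, `ibar`
#' followed by one non-negative integer column per sample.
#'
#' @param counts A count table.
#' @param path File path.
#' @export
write_counts_tsv <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(spacer_id = "character", ibar = "character"))
  validate_count_table(out)
  out
}

#' Read a sample sheet
#'
#' Two-column TSV: `sample`, `role` with roles `reference`, `sorted_high`,
#' `sorted_low`.
#'
#' @param path File path.
#' @export
read_sample_sheet <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "role") %in% names(out)))
  bad <- !(out$role %in% c("reference", "sorted_high", "sorted_low"))
  if (any(bad)) {
    stop("unknown sample role: ", paste(unique(out$role[bad]), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Write sequences as FASTQ
#'
#' @param seqs Character vector of read sequences.
#' @param path Output path (`.gz` accepted).
#' @param ids Read names; defaults to `read1..readN`.
#' @param quals Phred+33 quality strings, recycled if length 1; default Q40.
#' @export
write_fastq <- function(seqs, path, ids = NULL, quals = NULL) {
  n <- length(seqs)
  if (is.null(ids)) ids <- sprintf("read%d", seq_len(n))
  if (is.null(quals)) {
    quals <- vapply(nchar(seqs), function(w) strrep("I", w), character(1))
  } else if (length(quals) == 1L && n > 1L) {
    quals <- rep(quals, n)
  }
  stopifnot(length(ids) == n, length(quals) == n,
            all(nchar(quals) == nchar(seqs)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con, sep = "\n")
  invisible(path)
}

#' Read a FASTQ file into sequences and qualities
#'
#' @param path FASTQ path (`.gz` accepted).
#' @return List with character vectors `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  sr <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  list(
    id = sub("\\s.*$", "", names(sr)),
    seq = unname(as.character(sr)),
    qual = unname(as.character(S4Vectors::mcols(sr)$qualities))
  )
}

#' Write and read a signature model as JSON
#'
#' @param model A `signature_model` from [build_signature()].
#' @param path File path.
#' @export
write_signature_json <- function(model, path) {
  jsonlite::write_json(
    list(genes = model$genes, weights = model$weights,
         n_top = model$n_top, ranking = model$ranking),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_signature_json
#' @export
read_signature_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_signature_model(x$genes, x$weights, n_top = x$n_top, ranking = x$ranking)
}

#' Read a differential-expression table
#'
#' Accepts the DESeq2 results dialect: columns `gene` (or rownames in the
#' first column), `log2FoldChange`/`log2FC`, `stat`/`wald_stat`, `pvalue`,
#' `padj`.
#'
#' @param path TSV path.
#' @return A data.frame with columns `gene`, `log2fc`, `stat`, `pvalue`,
#'   `padj`.
#' @export
read_de_table <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE)
  pick <- function(cands) {
    hit <- intersect(cands, names(raw))
    if (length(hit) == 0L) return(NULL)
    raw[[hit[1]]]
  }
  gene <- pick(c("gene", "gene_id", "symbol"))
  if (is.null(gene)) gene <- raw[[1]]
  out <- data.frame(
    gene = as.character(gene),
    log2fc = pick(c("log2FoldChange", "log2FC", "log2fc", "lfc")),
    stat = pick(c("stat", "wald_stat", "w")),
    pvalue = pick(c("pvalue", "p", "p_value")),
    padj = pick(c("padj", "p_adj", "fdr")),
    stringsAsFactors = FALSE
  )
  if (is.null(out$stat)) stop("DE table lacks a Wald-statistic column", call. = FALSE)
  out
}

#' Read an expression matrix (genes x samples, log2TPM)
#'
#' @param path TSV with gene identifiers in the first column.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- raw[[1]]
  m
}

#' @rdname read_expression_tsv
#' @param mat Numeric gene-by-sample matrix.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
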