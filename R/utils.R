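#' @keywords internal
"_PACKAGE"

#' @importFrom stats median pnorm p.adjust rnorm rnbinom rlnorm runif sd var
#'   approx cor.test t.test quantile setNames
#' @importFrom utils read.delim write.table head
NULL

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# DNA helpers on plain character vectors; Biostrings handles sets and files,
# these keep single-sequence hot paths allocation-light.
DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T}", what), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
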