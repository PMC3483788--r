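# Nucleotide alphabet utilities shared across modules.
#
# Internal convention: 3'UTR sequences are handled as DNA (U -> T on
# ingestion); seed-matching words are displayed as RNA to match the
# field's notation for miRNA sites.

RNA_LETTERS <- c("A", "C", "G", "U")
DNA_LETTERS <- c("A", "C", "G", "T")

#' Reverse complement of a nucleotide sequence
#'
#' @param seq A single character string over the stated alphabet.
#' @param alphabet `"RNA"` or `"DNA"`.
#' @return The reverse complement, in the same alphabet. Applying the
#'   function twice returns the input (involution).
#' @examples
#' reverse_complement("AAGGCAC", "RNA")  # "GUGCCUU"
#' @export
reverse_complement <- function(seq, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  if (nchar(seq) == 0L) return(seq)
  seq <- toupper(seq)
  letters_ok <- if (alphabet == "RNA") RNA_LETTERS else DNA_LETTERS
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% letters_ok)
  if (length(bad)) {
    stop(sprintf("invalid %s letter '%s' at position %d", alphabet,
                 chars[bad[1L]], bad[1L]), call. = FALSE)
  }
  comp <- if (alphabet == "RNA") chartr("ACGU", "UGCA", seq) else chartr("ACGT", "TGCA", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Convert between RNA and DNA representations
#'
#' Uppercases and swaps U/T. Vectorized.
#'
#' @param x Character vector of sequences.
#' @return Character vector in the requested alphabet.
#' @export
as_dna <- function(x) chartr("Uu", "Tt", toupper(x))

#' @rdname as_dna
#' @export
as_rna <- function(x) chartr("Tt", "Uu", toupper(x))

# Validate characters of a sequence vector; `extra` allows e.g. "N".
check_alphabet <- function(x, letters_ok, what = "sequence") {
  pat <- sprintf("[^%s]", paste(letters_ok, collapse = ""))
  hit <- regexpr(pat, x)
  bad <- which(hit > 0L)
  if (length(bad)) {
    i <- bad[1L]
    stop(sprintf("invalid letter '%s' at position %d of %s %s",
                 substr(x[i], hit[i], hit[i]), hit[i], what,
                 if (!is.null(names(x))) sQuote(names(x)[i]) else i),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Run code with a temporary RNG state; generators are pure in (config, seed).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
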