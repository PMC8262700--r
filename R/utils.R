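#' @import data.table
#' @importFrom stats prcomp cor hclust as.dendrogram order.dendrogram var sd
#' @importFrom stats t.test wilcox.test shapiro.test oneway.test kruskal.test
#' @importFrom stats p.adjust rnorm runif rbinom setNames aggregate
#' @importFrom utils head tail write.table read.table adist
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character vectors, `N` preserved.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Hamming distance between two equal-length strings; vectorised over bytes.
hamming <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra != rb)
}

## Positions (1-based) where two equal-length strings differ.
mismatch_positions <- function(a, b) {
  which(charToRaw(a) != charToRaw(b))
}

## gzip-compress a character payload, returning the raw vector.
gzip_bytes <- function(txt) {
  memCompress(charToRaw(txt), type = "gzip")
}

gunzip_text <- function(bytes) {
  rawToChar(memDecompress(bytes, type = "gzip"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic TSV writer used for every report table: fixed column order,
## no quoting, '.' decimal, LF line endings -- byte-identical across runs.
write_tsv_table <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.table(df, file = path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}
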