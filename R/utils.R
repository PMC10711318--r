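#' Reverse complement of nucleotide strings
#'
#' Vectorised reverse complement over character vectors. IUPAC ambiguity
#' codes are complemented too (e.g. `R` <-> `Y`); case is preserved.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of the same length.
#' @examples
#' revcomp(c("ATG", "TTT"))
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr(
    "ACGTUMRWSYKVHDBNacgtumrwsykvhdbn",
    "TGCAAKYWSRMBDHVNtgcaakywsrmbdhvn",
    x
  ))
}

# internal logger: messages go to stderr, data files never carry timestamps
pk_log <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message("[pankmer] ", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic TSV line writer (no quoting, "." never localised)
write_tsv_lines <- function(df, con) {
  if (nrow(df) == 0L) return(invisible(NULL))
  cols <- lapply(df, function(x) {
    if (is.numeric(x)) format(x, scientific = FALSE, trim = TRUE) else as.character(x)
  })
  writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(NULL)
}

# open a text connection, transparently gzipped when the path ends in .gz
open_out <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
}
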