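# FASTA and report I/O. Sequence files go through Biostrings; structured
# reports are JSON with a versioned schema.

REPORT_SCHEMA_VERSION <- "1.0"

#' Read / write FASTA
#'
#' Thin wrappers around Biostrings. FASTA has no topology field, so circular
#' topology is declared per record via function arguments or CLI flags, not
#' in the file.
#'
#' @param path File path.
#' @param sequences Named character vector of sequences.
#' @return `read_fasta()` returns a named character vector.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(set), names(set))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Export scan hits as TSV
#'
#' @param hits A data.frame from [scan_cores()].
#' @param path Output file.
#' @export
write_scan_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# JSON provenance record written by every CLI run
provenance_record <- function(subcommand, inputs, seed = NULL,
                              config = list()) {
  list(schema_version = REPORT_SCHEMA_VERSION,
       tool = "bridgerec",
       version = as.character(utils::packageVersion("bridgerec")),
       subcommand = subcommand,
       inputs = inputs,
       seed = seed,
       config = config)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

# GFF3-style feature lines marking junctions and heteroduplex positions on a
# product molecule
product_gff_lines <- function(m, seqid) {
  stopifnot(inherits(m, "ProductMolecule"))
  lines <- character(0)
  for (p in m$heteroduplex)
    lines <- c(lines, paste(seqid, "bridgerec", "heteroduplex", p, p, ".",
                            "+", ".", "Note=top/bottom from different parents",
                            sep = "\t"))
  lines
}
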