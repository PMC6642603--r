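#' Read and write FASTA
#'
#' Thin tibble adapters over Biostrings. Sequences are upper-cased on read
#' and restricted to the `A`/`C`/`G`/`T`/`N` alphabet.
#'
#' @param path Path to a FASTA file.
#' @return `read_fasta()`: a tibble with columns `id`, `seq`, `description`
#'   (text after the first whitespace in the header, `""` if none).
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' write_fasta(tibble::tibble(id = "x", seq = "ACGT", description = ""), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1L)
  if (length(first) && !startsWith(first, ">")) {
    stop("malformed FASTA header at line 1 (no '>'): ", first, call. = FALSE)
  }
  ss <- Biostrings::readBStringSet(path)
  if (!length(ss)) {
    return(tibble(id = character(), seq = character(),
                  description = character()))
  }
  hdr <- names(ss)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  seq <- unname(toupper(as.character(ss)))
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop("non-ACGTN characters in sequence(s): ",
         paste(utils::head(id[bad], 3), collapse = ", "), call. = FALSE)
  }
  if (any(id == "")) stop("empty FASTA record id", call. = FALSE)
  tibble(id = id, seq = seq, description = desc)
}

#' @rdname read_fasta
#' @param records Tibble with columns `id`, `seq` and optionally `description`.
#' @param wrap Line width for the sequence body.
#' @export
write_fasta <- function(records, path, wrap = 60L) {
  stopifnot(all(c("id", "seq") %in% names(records)), wrap >= 1)
  ss <- Biostrings::DNAStringSet(toupper(records$seq))
  desc <- if ("description" %in% names(records)) records$description else ""
  names(ss) <- ifelse(desc == "" | is.na(desc), records$id,
                      paste(records$id, desc))
  Biostrings::writeXStringSet(ss, filepath = path, width = as.integer(wrap))
  invisible(path)
}

#' Read and write FASTQ (phred+33)
#'
#' @param path Path to a FASTQ file.
#' @return `read_fastq()`: tibble with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  ln <- readLines(path)
  if (!length(ln)) return(tibble(id = character(), seq = character(),
                                 qual = character()))
  stopifnot(length(ln) %% 4 == 0)
  i <- seq(1, length(ln), by = 4)
  tibble(id = sub("^@", "", sub("\\s.*$", "", ln[i])),
         seq = toupper(ln[i + 1]), qual = ln[i + 3])
}

#' @rdname read_fastq
#' @param reads Tibble with columns `id`, `seq`, `qual`.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("qual" %in% names(reads)) reads$qual else
    strrep("I", nchar(reads$seq))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", qual), path)
  invisible(path)
}
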