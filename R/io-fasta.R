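#' Read protein sequences from FASTA
#'
#' Parses a FASTA file (or literal text) into a data frame of sequence
#' records. Sequences are uppercased and may contain the 20 standard amino
#' acids plus `X` (unknown) and `-` (gap). By default any other character is
#' a fatal error; with `lenient = TRUE` offending characters are masked to
#' `X` with a warning.
#'
#' @param path Path to a FASTA file. Ignored when `text` is given.
#' @param text Optional character scalar holding FASTA-formatted text.
#' @param lenient Mask out-of-alphabet characters to `X` instead of failing.
#' @return A data frame with columns `id`, `description`, `sequence`.
#' @examples
#' read_fasta(text = ">a description\nPLD\nLS\n")
#' @export
read_fasta <- function(path = NULL, text = NULL, lenient = FALSE) {
  if (!is.null(text)) {
    path <- tempfile(fileext = ".fa")
    on.exit(unlink(path), add = TRUE)
    writeLines(sub("\n$", "", text), path)
  }
  lines <- readLines(path, warn = FALSE)
  body <- lines[nzchar(trimws(lines))]
  if (length(body) == 0L) {
    return(data.frame(id = character(), description = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  if (!startsWith(body[[1L]], ">")) {
    stopf("FASTA format error: sequence data before any '>' header (line %d)",
          which(nzchar(trimws(lines)))[1L])
  }
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  id <- sub("\\s.*$", "", ids)
  desc <- ifelse(grepl("\\s", ids), sub("^\\S+\\s+", "", ids), "")
  seqs <- toupper(as.character(set))
  allowed <- c(AA1, "X", "-")
  bad <- !vapply(strsplit(seqs, ""), function(ch) all(ch %in% allowed),
                 logical(1))
  if (any(bad)) {
    if (!lenient) {
      stopf("FASTA alphabet error in record(s): %s",
            paste(id[bad], collapse = ", "))
    }
    warning("masking out-of-alphabet characters to 'X' in: ",
            paste(id[bad], collapse = ", "), call. = FALSE)
    seqs <- vapply(strsplit(seqs, ""), function(ch) {
      ch[!ch %in% allowed] <- "X"
      paste(ch, collapse = "")
    }, character(1))
  }
  if (any(!nzchar(id))) stopf("FASTA format error: empty record id")
  data.frame(id = id, description = desc, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' @param records Data frame with `id`, `sequence` and optionally
#'   `description` columns, as returned by [read_fasta()].
#' @param path Output file path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in%
                                          names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  hdr <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", hdr[[i]]), con)
    s <- records$sequence[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
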