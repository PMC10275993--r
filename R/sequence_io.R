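#' Read a protein FASTA file into a proteome table
#'
#' Parses a FASTA file into a data frame with one row per record.  The
#' accession is the first whitespace-delimited token of the header; UniProt
#' style `db|ACC|name` headers are reduced to the central accession.
#' Sequences are uppercased, whitespace is removed, and alignment gap
#' characters (`-`, `.`, `*`) are stripped, so the stored sequence is a plain
#' string over amino-acid one-letter codes.  Nonstandard letters (B, Z, X,
#' U, O) are retained; downstream modules each state their own handling.
#'
#' Accessions must be unique: a duplicate is a hard error, because
#' enrichment statistics depend on set cardinalities, and keep-first
#' behaviour would silently change counts.
#'
#' @param path path to a FASTA file.
#' @return data frame with character columns `accession` and `sequence`.
#' @seealso [write_fasta()], [read_localization_table()]
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|Q12345|NAME demo", "MKRP", "PR"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file does not exist: ", path)
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("no sequences in '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) {
    stop("no sequences in '", path, "'")
  }
  headers <- names(set)
  acc <- vapply(strsplit(headers, "[ \t\r]+"), function(x) {
    if (length(x) == 0L) "" else x[[1L]]
  }, character(1))
  # UniProt convention: db|ACC|entry_name -> ACC
  is_uniprot <- grepl("^[^|]*\\|[^|]+\\|", acc)
  acc[is_uniprot] <- vapply(strsplit(acc[is_uniprot], "|", fixed = TRUE),
                            `[`, character(1), 2L)
  empty <- !nzchar(acc)
  if (any(empty)) {
    i <- which(empty)[1L]
    stop("empty accession in FASTA header of entry ", i, " ('>",
         headers[i], "')")
  }
  dup <- unique(acc[duplicated(acc)])
  if (length(dup)) {
    stop("duplicate accession(s) in FASTA: ", paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub("[-.*[:space:]]", "", seqs)
  blank <- !nzchar(seqs)
  if (any(blank)) {
    stop("empty sequence for accession(s): ",
         paste(acc[blank], collapse = ", "))
  }
  data.frame(accession = acc, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write a proteome table to FASTA
#'
#' @param proteome data frame with columns `accession` and `sequence`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteome, path) {
  stopifnot(is.data.frame(proteome),
            all(c("accession", "sequence") %in% names(proteome)))
  set <- Biostrings::BStringSet(stats::setNames(proteome$sequence,
                                                proteome$accession))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a protein localization annotation table
#'
#' Reads a TSV with columns `accession` and `terms` (category terms joined
#' by `|`; an empty cell means "annotated, but with no category") and an
#' optional logical `has_data` column distinguishing "annotated with no
#' category of interest" from "no annotation available" (default `TRUE` for
#' every row present).  Terms are trimmed and lower-cased so matching
#' against category vocabularies is case-insensitive exact equality.
#' Accessions absent from the table are treated downstream as having no
#' localization data.
#'
#' @param path path to the TSV file.
#' @return data frame with columns `accession` (character), `terms`
#'   (list of character vectors), `has_data` (logical).
#' @seealso [localization_enrichment()]
#' @export
read_localization_table <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "")
  required <- c("accession", "terms")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("localization table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  has_data <- if ("has_data" %in% names(raw)) {
    # default for a present row is TRUE; only an explicit negative opts out
    !(toupper(trimws(raw$has_data)) %in% c("FALSE", "F", "0", "NO"))
  } else {
    rep(TRUE, nrow(raw))
  }
  terms <- split_terms(raw$terms)
  terms[!has_data] <- list(character(0))
  data.frame(accession = raw$accession, terms = I(terms),
             has_data = has_data, stringsAsFactors = FALSE)
}

# "A|B" -> c("a","b"); trims, lower-cases, drops empties
split_terms <- function(x) {
  lapply(strsplit(as.character(x), "|", fixed = TRUE), function(ts) {
    ts <- tolower(trimws(ts))
    ts[nzchar(ts)]
  })
}

#' Write a localization table produced by the simulator or parser
#'
#' Inverse of [read_localization_table()]: the `terms` list-column is joined
#' with `|`.
#'
#' @param loc data frame with columns `accession`, `terms` (list or
#'   character), `has_data`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_localization_table <- function(loc, path) {
  terms <- if (is.list(loc$terms)) {
    vapply(loc$terms, paste, character(1), collapse = "|")
  } else {
    as.character(loc$terms)
  }
  out <- data.frame(accession = loc$accession, terms = terms,
                    has_data = ifelse(loc$has_data, "TRUE", "FALSE"),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a result table as TSV
#'
#' Writes any result data frame as a UTF-8 TSV with a header row and `.` as
#' the decimal separator.  Numeric values whose magnitude is below `1e-4`
#' (and nonzero) are rendered in scientific notation, the convention used
#' for p-value columns; all numerics carry enough digits that a
#' write-then-read round trip reproduces them to at least 12 significant
#' digits.
#'
#' @param rows data frame sharing one column schema (may have zero rows).
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [read_table()]
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  out <- rows
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- format_numeric(out[[j]])
    } else if (is.list(out[[j]])) {
      out[[j]] <- vapply(out[[j]], paste, character(1), collapse = "|")
    }
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

format_numeric <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v != 0 && abs(v) < 1e-4) {
      format(v, digits = 13, scientific = TRUE)
    } else {
      format(v, digits = 15, scientific = FALSE)
    }
  }, character(1))
}

#' Read back a TSV result table
#'
#' @param path path to a TSV written by [write_table()].
#' @return data frame.
#' @export
read_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "")
}
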