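#' Read a lexicon from a text file
#'
#' Two dialects are supported.  `"tsv"` is the package's native format: one
#' entry per line, `orthography <TAB> space-separated phonemes <TAB> frequency`,
#' UTF-8, `#` comment lines and blank lines ignored.  `"trace"` reads the plain
#' word-list format used by public C-implementation distributions of the
#' classic 212-word interactive-activation lexicon: one word per line as a
#' string of single-character phoneme symbols, optionally followed by
#' whitespace and a frequency (default 1).
#'
#' Duplicate forms are merged by summing frequency; a malformed line or an
#' out-of-inventory phoneme raises an error naming the line or symbol.
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"trace"`.
#' @param inventory Optional [phoneme_inventory()]; inferred from the file if
#'   `NULL`.
#' @return A [lexicon()].
#' @export
read_lexicon <- function(path, dialect = c("tsv", "trace"), inventory = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no entries in ", path)
  if (dialect == "tsv") {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 3L)
    if (length(bad) > 0L) {
      stop("malformed lexicon line ", lineno[bad[1L]], " in ", path,
           " (expected 3 tab-separated fields)")
    }
    orth <- vapply(parts, `[`, character(1), 1L)
    form <- vapply(parts, `[`, character(1), 2L)
    freq <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 3L)))
    if (anyNA(freq)) {
      stop("malformed frequency on line ", lineno[which(is.na(freq))[1L]],
           " in ", path)
    }
  } else {
    parts <- strsplit(trimws(lines), "[[:space:]]+")
    word <- vapply(parts, `[`, character(1), 1L)
    freq <- vapply(parts, function(p) {
      if (length(p) >= 2L) suppressWarnings(as.numeric(p[2L])) else 1
    }, numeric(1))
    if (anyNA(freq)) {
      stop("malformed frequency on line ", lineno[which(is.na(freq))[1L]],
           " in ", path)
    }
    form <- vapply(strsplit(word, ""), paste, character(1), collapse = " ")
    orth <- word
  }
  if (any(freq < 0)) {
    stop("negative frequency on line ", lineno[which(freq < 0)[1L]], " in ", path)
  }
  lexicon(forms = form, frequencies = freq, orth = orth, inventory = inventory)
}

#' Write a lexicon to a text file
#'
#' @param lex A [lexicon()].
#' @param path Output path.
#' @param dialect See [read_lexicon()]; `"trace"` requires single-character
#'   phoneme symbols.
#' @return Invisibly, `path`.
#' @export
write_lexicon <- function(lex, path, dialect = c("tsv", "trace")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(lex, "lexicon"))
  e <- lex$entries
  if (dialect == "tsv") {
    lines <- paste(e$orth, e$form, format(e$frequency, trim = TRUE,
                                          scientific = FALSE), sep = "\t")
  } else {
    if (any(nchar(unclass(lex$inventory)) != 1L)) {
      stop("'trace' dialect requires single-character phoneme symbols")
    }
    lines <- paste(gsub(" ", "", e$form),
                   format(e$frequency, trim = TRUE, scientific = FALSE))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read item triples from a TSV file
#'
#' Format: `source_orth <TAB> source_phon <TAB> nonwordA_phon <TAB>
#' nonwordB_phon`, phonemes space-separated; `#` comments ignored.  The
#' deviation point is computed, never stored.
#'
#' @param path File path.
#' @return An [item_triples()] table.
#' @export
read_triples <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad) > 0L) {
    stop("malformed triples line ", lineno[bad[1L]], " in ", path,
         " (expected 4 tab-separated fields)")
  }
  item_triples(source = vapply(parts, `[`, character(1), 2L),
               nonword_a = vapply(parts, `[`, character(1), 3L),
               nonword_b = vapply(parts, `[`, character(1), 4L),
               source_orth = vapply(parts, `[`, character(1), 1L))
}

#' Write item triples to a TSV file
#'
#' @param triples An [item_triples()] table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_triples <- function(triples, path) {
  stopifnot(inherits(triples, "item_triples"))
  lines <- paste(triples$source_orth, triples$source, triples$nonword_a,
                 triples$nonword_b, sep = "\t")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
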