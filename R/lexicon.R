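#' Lexicons: phoneme-transcribed word forms with frequencies
#'
#' A `lexicon` is the object that "training" manipulates: a collection of
#' entries, each a phoneme sequence with a non-negative frequency (occurrences
#' per million or an arbitrary weight), over a fixed [phoneme_inventory()].
#' Two entries never share an identical phoneme sequence; duplicate forms are
#' merged by summing their frequencies, which preserves total cohort mass.
#'
#' @param forms Word forms: a character vector of space-separated phoneme
#'   strings (`"f O r m"`), or a list of phoneme character vectors.
#' @param frequencies Numeric vector of non-negative frequencies, recycled to
#'   the number of forms.
#' @param orth Optional orthographic labels (for display and file output only;
#'   identity of an entry is its phoneme sequence).
#' @param inventory A [phoneme_inventory()]; if `NULL`, inferred from the
#'   symbols occurring in `forms` (sorted).
#' @return An object of class `lexicon`: a list with elements `entries` (a
#'   `data.table` with columns `orth`, `form`, `frequency`, `len`) and
#'   `inventory`.
#' @examples
#' lex <- lexicon(c("f o r m j u l ^", "f o r b i d"), c(37, 12))
#' lex
#' @export
lexicon <- function(forms, frequencies = 1, orth = NULL, inventory = NULL) {
  if (is.list(forms)) forms <- vapply(forms, phon_join, character(1))
  forms <- as.character(forms)
  n <- length(forms)
  if (n == 0L) stop("a lexicon needs at least one entry")
  frequencies <- rep_len(as.numeric(frequencies), n)
  if (anyNA(frequencies) || any(frequencies < 0)) {
    stop("frequencies must be non-negative numbers")
  }
  phon <- lapply(forms, as_phonemes)
  if (any(lengths(phon) < 1L)) stop("every form must have at least one phoneme")
  forms <- vapply(phon, paste, character(1), collapse = " ")
  if (is.null(inventory)) {
    inventory <- phoneme_inventory(sort(unique(unlist(phon))))
  }
  for (p in phon) check_phonemes(p, inventory, what = "form")
  if (is.null(orth)) orth <- gsub(" ", "", forms) else orth <- as.character(orth)
  dt <- data.table::data.table(orth = orth, form = forms,
                               frequency = frequencies,
                               len = lengths(phon))
  # merge duplicate forms by frequency summation (first orth label kept)
  dt <- dt[, list(orth = orth[1L], frequency = sum(frequency), len = len[1L]),
           by = "form"]
  data.table::setcolorder(dt, c("orth", "form", "frequency", "len"))
  data.table::setorderv(dt, "form")
  if (sum(dt$frequency) <= 0) stop("total lexicon frequency must be > 0")
  structure(list(entries = dt[], inventory = inventory), class = "lexicon")
}

#' @exportS3Method base::print
print.lexicon <- function(x, ...) {
  cat("<lexicon> ", nrow(x$entries), " entries, ",
      length(x$inventory), "-phoneme inventory, total frequency ",
      format(sum(x$entries$frequency)), "\n", sep = "")
  print(utils::head(x$entries, 6L))
  if (nrow(x$entries) > 6L) cat("...\n")
  invisible(x)
}

#' @exportS3Method base::length
length.lexicon <- function(x) nrow(x$entries)

# list of phoneme vectors for all entries (computed on demand; cheap at the
# scales used here)
lexicon_phon <- function(lex) strsplit(lex$entries$form, " ", fixed = TRUE)

#' Deviation point of an item triple
#'
#' The deviation point (DP) is the position after which an item can be uniquely
#' identified: for a triple like *formula*/*formubo*/*formuty* it falls after
#' the shared *formu-*, i.e. `dp = 6` shared phonemes.  This function returns
#' the length of the longest common prefix of the three sequences; it is
#' symmetric in its arguments.
#'
#' @param source,novel,baseline Phoneme sequences (character vectors or
#'   space-separated strings).
#' @return Integer: the number of shared leading phonemes.
#' @examples
#' triple_deviation_point("f o r m j u l ^", "f o r m j u b o",
#'                        "f o r m j u t i")
#' @export
triple_deviation_point <- function(source, novel, baseline) {
  a <- as_phonemes(source); b <- as_phonemes(novel); c_ <- as_phonemes(baseline)
  if (length(a) == 0L || length(b) == 0L || length(c_) == 0L) {
    stop("all three sequences must be non-empty")
  }
  k <- min(length(a), length(b), length(c_))
  dp <- 0L
  while (dp < k && a[dp + 1L] == b[dp + 1L] && a[dp + 1L] == c_[dp + 1L]) {
    dp <- dp + 1L
  }
  if (dp == length(a) || dp == length(b) || dp == length(c_)) {
    stop("no divergence: the common prefix exhausts one of the sequences")
  }
  dp
}

#' Uniqueness point of a word in a lexicon
#'
#' The earliest position `n` such that the word's first `n` phonemes are a
#' prefix of no *other* lexicon entry.  Words embedded in (or identical to)
#' another entry have no uniqueness point and yield `NA`.
#'
#' @param word A phoneme sequence.
#' @param lex A [lexicon()].
#' @return Integer position, or `NA_integer_` if the full word is still
#'   compatible with another entry.
#' @export
uniqueness_point <- function(word, lex) {
  stopifnot(inherits(lex, "lexicon"))
  w <- check_phonemes(word, lex$inventory, "word")
  if (length(w) == 0L) stop("word must be non-empty")
  wstr <- paste(w, collapse = " ")
  others <- setdiff(lex$entries$form, wstr)
  # an entry is compatible with prefix w[1..n] iff the prefix is a prefix of it
  for (n in seq_along(w)) {
    pre <- paste(w[seq_len(n)], collapse = " ")
    compat <- others == pre | startsWith(others, paste0(pre, " "))
    if (!any(compat)) return(n)
    others <- others[compat]
  }
  NA_integer_
}

#' Item triples: source word, novel nonword, baseline nonword
#'
#' Builds and validates the stimulus structure of the novel-word-learning
#' design: each row holds an existing *source* word and two matched nonwords
#' that share its onset up to the deviation point (DP) and diverge, pairwise,
#' exactly at position `dp + 1`.  During "training" one of the two nonwords
#' (the *novel* item) is added to the lexicon at the source's frequency; the
#' other serves as the untrained *baseline*.
#'
#' @param source,nonword_a,nonword_b Character vectors of space-separated
#'   phoneme strings (or lists of phoneme vectors), one element per triple.
#' @param source_orth Optional orthographic labels for the source words.
#' @return A `data.table` of class `item_triples` with columns `triple_id`,
#'   `source_orth`, `source`, `nonword_a`, `nonword_b`, `dp`.  `dp` is always
#'   computed with [triple_deviation_point()], never supplied.
#' @export
item_triples <- function(source, nonword_a, nonword_b, source_orth = NULL) {
  norm <- function(x) {
    if (is.list(x)) vapply(x, phon_join, character(1)) else
      vapply(as.character(x), phon_join, character(1), USE.NAMES = FALSE)
  }
  source <- norm(source); nonword_a <- norm(nonword_a); nonword_b <- norm(nonword_b)
  n <- length(source)
  if (length(nonword_a) != n || length(nonword_b) != n) {
    stop("source, nonword_a and nonword_b must have equal length")
  }
  if (is.null(source_orth)) source_orth <- gsub(" ", "", source)
  dp <- integer(n)
  for (i in seq_len(n)) {
    dp[i] <- triple_deviation_point(source[i], nonword_a[i], nonword_b[i])
    a <- as_phonemes(source[i]); b <- as_phonemes(nonword_a[i])
    cc <- as_phonemes(nonword_b[i])
    if (min(length(a), length(b), length(cc)) < dp[i] + 1L) {
      stop("triple ", i, ": all sequences must extend past the deviation point")
    }
    at <- c(a[dp[i] + 1L], b[dp[i] + 1L], cc[dp[i] + 1L])
    if (anyDuplicated(at)) {
      stop("triple ", i, ": items must diverge pairwise at position dp+1")
    }
  }
  out <- data.table::data.table(triple_id = seq_len(n),
                                source_orth = as.character(source_orth),
                                source = source, nonword_a = nonword_a,
                                nonword_b = nonword_b, dp = dp)
  data.table::setattr(out, "class", c("item_triples", class(out)))
  out[]
}

#' Validate item triples against a pre-training lexicon
#'
#' Checks that every source word exists in `lex` and that neither nonword
#' does (nonwords must be absent from the pre-training lexicon).
#'
#' @param triples An [item_triples()] table.
#' @param lex The pre-training [lexicon()].
#' @return Invisibly `TRUE`; otherwise an error.
#' @export
validate_triples <- function(triples, lex) {
  stopifnot(inherits(triples, "item_triples"), inherits(lex, "lexicon"))
  forms <- lex$entries$form
  miss <- setdiff(triples$source, forms)
  if (length(miss) > 0L) {
    stop("source form(s) not in lexicon: ", paste(miss, collapse = "; "))
  }
  present <- intersect(c(triples$nonword_a, triples$nonword_b), forms)
  if (length(present) > 0L) {
    stop("nonword(s) already in lexicon: ", paste(present, collapse = "; "))
  }
  for (f in c(triples$source, triples$nonword_a, triples$nonword_b)) {
    check_phonemes(f, lex$inventory, "triple item")
  }
  invisible(TRUE)
}

#' Add trained novel words to a lexicon
#'
#' Word learning is modeled as lexicalization only: for each triple, the
#' assigned novel nonword is added to the lexicon with the same frequency as
#' its source word.  The input lexicon is not modified.
#'
#' @param lex The pre-training [lexicon()].
#' @param triples An [item_triples()] table.
#' @param assignment `"A"` or `"B"` (which nonword column is the novel item),
#'   either a single value or one per triple.
#' @return A new `lexicon` with one additional entry per triple.
#' @export
train_lexicon <- function(lex, triples, assignment = "A") {
  stopifnot(inherits(lex, "lexicon"), inherits(triples, "item_triples"))
  assignment <- rep_len(toupper(as.character(assignment)), nrow(triples))
  if (!all(assignment %in% c("A", "B"))) stop("assignment must be 'A' or 'B'")
  if (nrow(triples) == 0L) return(lex)
  novel <- ifelse(assignment == "A", triples$nonword_a, triples$nonword_b)
  idx <- match(triples$source, lex$entries$form)
  if (anyNA(idx)) {
    stop("source form(s) not in lexicon: ",
         paste(triples$source[is.na(idx)], collapse = "; "))
  }
  if (any(novel %in% lex$entries$form)) {
    stop("novel form(s) already in lexicon: ",
         paste(intersect(novel, lex$entries$form), collapse = "; "))
  }
  if (anyDuplicated(novel)) stop("duplicate novel forms across triples")
  lexicon(forms = c(lex$entries$form, novel),
          frequencies = c(lex$entries$frequency, lex$entries$frequency[idx]),
          orth = c(lex$entries$orth, gsub(" ", "", novel)),
          inventory = lex$inventory)
}
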