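# data.table is used via :: only; this flag keeps [.data.table semantics
.datatable.aware <- TRUE

#' Phoneme inventory
#'
#' An ordered set of phoneme labels.  Labels are opaque tokens (e.g. `"p"`,
#' `"a"`, `"^"`, or multi-character symbols); their order is fixed and defines
#' the indexing of every probability vector and activation matrix downstream.
#'
#' @param symbols Character vector of distinct, non-empty phoneme labels.
#' @return An object of class `phoneme_inventory` (a character vector).
#' @examples
#' inv <- phoneme_inventory(c("p", "a", "r", "t", "l", "i"))
#' length(inv)
#' @export
phoneme_inventory <- function(symbols) {
  symbols <- as.character(symbols)
  if (length(symbols) == 0L) stop("inventory must be non-empty")
  if (anyNA(symbols) || any(!nzchar(symbols))) {
    stop("inventory symbols must be non-empty strings")
  }
  if (anyDuplicated(symbols)) {
    stop("duplicate phoneme symbol: ",
         paste(unique(symbols[duplicated(symbols)]), collapse = ", "))
  }
  if (any(grepl("[[:space:]]", symbols))) {
    stop("phoneme symbols must not contain whitespace")
  }
  structure(symbols, class = "phoneme_inventory")
}

#' @exportS3Method base::print
print.phoneme_inventory <- function(x, ...) {
  cat("<phoneme_inventory> ", length(x), " symbols: ",
      paste(unclass(x), collapse = " "), "\n", sep = "")
  invisible(x)
}

# Normalize a phoneme sequence: accepts a character vector of phonemes or a
# single space-separated string ("f O r m").  Returns a character vector.
as_phonemes <- function(x) {
  if (length(x) == 1L && grepl(" ", x)) {
    x <- strsplit(x, " +")[[1]]
  }
  as.character(x)
}

phon_join <- function(x) paste(as_phonemes(x), collapse = " ")

check_phonemes <- function(x, inventory, what = "sequence") {
  x <- as_phonemes(x)
  bad <- setdiff(unique(x), unclass(inventory))
  if (length(bad) > 0L) {
    stop("unknown phoneme symbol in ", what, ": ", paste(bad, collapse = ", "))
  }
  x
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
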