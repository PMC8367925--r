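#' Cohort of a prefix
#'
#' The cohort is the set of lexical entries consistent with the input heard so
#' far: all entries whose form begins with `prefix` *and* continues beyond it.
#' Word-final entries (form identical to the prefix) are excluded — they have
#' no next phoneme to predict and no end-of-word symbol is modeled.
#'
#' @param lex A [lexicon()].
#' @param prefix Phoneme sequence (possibly empty: the whole lexicon).
#' @return A `data.table` subset of `lex$entries` (columns `orth`, `form`,
#'   `frequency`, `len`).
#' @examples
#' lex <- lexicon(c("f o r m j u l ^", "f o r b i d", "m u s r u m"))
#' cohort(lex, c("f", "o", "r"))
#' @export
cohort <- function(lex, prefix) {
  stopifnot(inherits(lex, "lexicon"))
  prefix <- if (length(prefix) == 0L || identical(prefix, "")) character(0)
            else check_phonemes(prefix, lex$inventory, "prefix")
  n <- length(prefix)
  e <- lex$entries
  if (n == 0L) return(e[e$len > 0L])
  pre <- paste(prefix, collapse = " ")
  # forms are space-separated, so a strict continuation starts with "pre "
  e[startsWith(e$form, paste0(pre, " "))]
}

#' Frequency-weighted next-phoneme prediction
#'
#' Computes the by-position, frequency-weighted probability of each phoneme
#' given the preceding input: for each inventory phoneme `p`,
#' `probs[p] = sum of frequencies of cohort entries whose next phoneme is p,
#' divided by the total cohort frequency`.  When the cohort is empty (typical
#' for nonword prefixes past the divergence point) the configured fallback is
#' used and flagged: `"uniform"` puts mass `1/|inventory|` on every phoneme;
#' `"zero"` returns an all-zero vector.
#'
#' @param lex A [lexicon()].
#' @param prefix Phoneme sequence heard so far (possibly empty).
#' @param freq_transform `"raw"` (default) or `"log1p"`: how entry frequencies
#'   enter the weighting.
#' @param fallback Empty-cohort policy, `"uniform"` or `"zero"`.
#' @return A list of class `phoneme_prediction`: `position` (the 1-based
#'   position being predicted), `probs` (named vector over the inventory),
#'   `cohort_mass` (summed raw frequency of the supporting cohort),
#'   `empty_cohort` (logical).
#' @export
predict_next <- function(lex, prefix,
                         freq_transform = c("raw", "log1p"),
                         fallback = c("uniform", "zero")) {
  freq_transform <- match.arg(freq_transform)
  fallback <- match.arg(fallback)
  prefix <- if (length(prefix) == 0L || identical(prefix, "")) character(0)
            else check_phonemes(prefix, lex$inventory, "prefix")
  inv <- unclass(lex$inventory)
  co <- cohort(lex, prefix)
  probs <- stats::setNames(numeric(length(inv)), inv)
  if (nrow(co) == 0L) {
    if (fallback == "uniform") probs[] <- 1 / length(inv)
    return(structure(list(position = length(prefix) + 1L, probs = probs,
                          cohort_mass = 0, empty_cohort = TRUE),
                     class = "phoneme_prediction"))
  }
  nxt <- vapply(strsplit(co$form, " ", fixed = TRUE), `[`, character(1),
                length(prefix) + 1L)
  w <- switch(freq_transform, raw = co$frequency, log1p = log1p(co$frequency))
  agg <- rowsum(w, nxt)
  probs[rownames(agg)] <- agg[, 1L] / sum(w)
  structure(list(position = length(prefix) + 1L, probs = probs,
                 cohort_mass = sum(co$frequency), empty_cohort = FALSE),
            class = "phoneme_prediction")
}

#' @exportS3Method base::print
print.phoneme_prediction <- function(x, ...) {
  cat("<phoneme_prediction> position ", x$position,
      if (x$empty_cohort) " (empty cohort)" else "",
      ", cohort mass ", format(x$cohort_mass), "\n", sep = "")
  top <- sort(x$probs[x$probs > 0], decreasing = TRUE)
  print(utils::head(top, 8L))
  invisible(x)
}

#' Summed-absolute prediction error
#'
#' The error signal is summed over all phonemes: with the presented phoneme
#' coded as a one-hot vector over the inventory, the error is
#' \eqn{\sum_p | probs_p - [p = observed] |}.  If the model assigns probability
#' 1.0 to one phoneme and a different phoneme arrives, the error is 2.0; if
#' the predicted phoneme arrives, 0.  For any normalized prediction this
#' equals `2 * (1 - probs[observed])`.
#'
#' @param pred A [predict_next()] result (or any numeric vector of
#'   probabilities named by phoneme).
#' @param observed The presented phoneme symbol.
#' @return A number in \[0, 2\].
#' @export
prediction_error <- function(pred, observed) {
  probs <- if (inherits(pred, "phoneme_prediction")) pred$probs else pred
  observed <- as.character(observed)
  if (!observed %in% names(probs)) {
    stop("observed phoneme '", observed, "' not in the inventory")
  }
  onehot <- as.numeric(names(probs) == observed)
  sum(abs(probs - onehot))
}

#' By-position prediction-error trajectory of an item
#'
#' Runs [predict_next()] at every position of `item` (position 1 uses the
#' empty prefix, i.e. the whole-lexicon first-phoneme distribution) and scores
#' the presented phoneme with [prediction_error()].
#'
#' @inheritParams predict_next
#' @param item Phoneme sequence to present.
#' @return A `data.frame` with one row per position: `position`, `observed`,
#'   `prob_observed`, `error`, `cohort_mass`, `empty_cohort`.  The
#'   `phoneme_prediction` objects are attached as attribute `"predictions"`.
#' @export
error_trajectory <- function(lex, item, freq_transform = c("raw", "log1p"),
                             fallback = c("uniform", "zero")) {
  freq_transform <- match.arg(freq_transform)
  fallback <- match.arg(fallback)
  item <- check_phonemes(item, lex$inventory, "item")
  if (length(item) == 0L) stop("item must be non-empty")
  preds <- vector("list", length(item))
  out <- data.frame(position = seq_along(item), observed = item,
                    prob_observed = NA_real_, error = NA_real_,
                    cohort_mass = NA_real_, empty_cohort = NA)
  for (i in seq_along(item)) {
    p <- predict_next(lex, item[seq_len(i - 1L)],
                      freq_transform = freq_transform, fallback = fallback)
    preds[[i]] <- p
    out$prob_observed[i] <- p$probs[[item[i]]]
    out$error[i] <- prediction_error(p, item[i])
    out$cohort_mass[i] <- p$cohort_mass
    out$empty_cohort[i] <- p$empty_cohort
  }
  attr(out, "predictions") <- preds
  out
}
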