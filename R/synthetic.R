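#' Specification for a synthetic lexicon
#'
#' Describes the statistical shape of a generated vocabulary: a fixed phoneme
#' inventory, variable word length, and a Zipfian rank-frequency profile
#' \eqn{f(r) \propto r^{-s}}.  Defaults emulate, at desk scale, the kind of
#' input the analysis assumes — a few hundred words over a 14-symbol
#' inventory (the size of the classic interactive-activation phoneme set),
#' word lengths 2-7 weighted toward the short words that dominate a natural
#' small vocabulary, and Zipf exponent 1.  Phoneme symbols themselves are
#' drawn with Zipf-skewed probabilities (`phoneme_zipf = 1`): natural phoneme
#' inventories are strongly non-uniform, and it is this skew that gives the
#' generated vocabulary the segmental overlap — shared onsets, embedded
#' matches at arbitrary alignments — on which cohort structure and lexical
#' neighborhood competition depend.  With uniform phonemes a 200-word
#' vocabulary is essentially neighborless and no model of lexical
#' competition has anything to compete over.
#'
#' @param n_words Number of distinct word forms (>= 1).
#' @param inventory_size Number of phoneme symbols (>= 3).  Symbols are
#'   `p01`, `p02`, ... unless `symbols` is given.
#' @param min_len,max_len Word length range (`min_len >= 2`).
#' @param length_probs Optional probability weights over `min_len:max_len`;
#'   the default (for the default 2-7 range) is
#'   `c(.08, .27, .27, .18, .12, .08)`, peaked at 3-4 phonemes with enough
#'   six-phoneme words to supply stimulus triples.
#' @param zipf_exponent Rank-frequency exponent `s >= 0`; 0 gives equal
#'   frequencies.
#' @param phoneme_zipf Zipf exponent of the per-symbol sampling
#'   probabilities (`0` = uniform symbols).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @param symbols Optional explicit inventory symbols.
#' @return A list of class `lexicon_spec`.
#' @export
lexicon_spec <- function(n_words = 200L, inventory_size = 14L,
                         min_len = 2L, max_len = 7L, length_probs = NULL,
                         zipf_exponent = 1, phoneme_zipf = 1,
                         seed = 1L, symbols = NULL) {
  stopifnot(n_words >= 1L, inventory_size >= 3L, min_len >= 2L,
            max_len >= min_len, zipf_exponent >= 0, phoneme_zipf >= 0)
  if (is.null(symbols)) {
    symbols <- sprintf("p%02d", seq_len(inventory_size))
  } else {
    stopifnot(length(symbols) == inventory_size)
  }
  lens <- seq.int(min_len, max_len)
  if (is.null(length_probs)) {
    length_probs <- if (min_len == 2L && max_len == 7L) {
      c(0.08, 0.27, 0.27, 0.18, 0.12, 0.08)
    } else {
      rep(1, length(lens))
    }
  }
  stopifnot(length(length_probs) == length(lens), all(length_probs >= 0))
  phoneme_probs <- seq_len(inventory_size)^(-phoneme_zipf)
  structure(list(n_words = as.integer(n_words),
                 inventory_size = as.integer(inventory_size),
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 length_probs = length_probs / sum(length_probs),
                 zipf_exponent = zipf_exponent, phoneme_zipf = phoneme_zipf,
                 phoneme_probs = phoneme_probs / sum(phoneme_probs),
                 seed = as.integer(seed),
                 symbols = as.character(symbols)),
            class = "lexicon_spec")
}

#' Generate a synthetic lexicon
#'
#' Draws `n_words` distinct forms with lengths from the spec's length
#' distribution and i.i.d. Zipf-skewed phonemes, then assigns Zipfian frequencies
#' `f(r) = 1000 * r^(-s)` to a random permutation of the forms (rank is
#' independent of form).  Deterministic given the spec (including its seed).
#'
#' @param spec A [lexicon_spec()].
#' @return A [lexicon()].
#' @export
generate_lexicon <- function(spec) {
  stopifnot(inherits(spec, "lexicon_spec"))
  lens <- seq.int(spec$min_len, spec$max_len)
  # feasibility: count of distinct forms available over the supported lengths
  capacity <- sum(as.numeric(spec$inventory_size)^lens[spec$length_probs > 0])
  if (capacity < spec$n_words) {
    stop("inventory/length budget cannot host ", spec$n_words, " distinct forms")
  }
  with_seed(spec$seed, {
    forms <- character(0)
    attempts <- 0L
    while (length(forms) < spec$n_words) {
      need <- spec$n_words - length(forms)
      ln <- sample(lens, size = 2L * need + 10L, replace = TRUE,
                   prob = spec$length_probs)
      new <- vapply(ln, function(k) {
        paste(sample(spec$symbols, k, replace = TRUE,
                     prob = spec$phoneme_probs), collapse = " ")
      }, character(1))
      forms <- unique(c(forms, new))
      attempts <- attempts + 1L
      if (attempts > 1000L) {
        stop("could not draw ", spec$n_words, " distinct forms after 1000 rounds")
      }
    }
    forms <- forms[seq_len(spec$n_words)]
    rank <- sample.int(spec$n_words)
    freq <- 1000 * rank^(-spec$zipf_exponent)
    lexicon(forms = forms, frequencies = freq,
            orth = sprintf("w%04d", seq_len(spec$n_words)),
            inventory = phoneme_inventory(spec$symbols))
  })
}

#' Specification for synthetic item triples
#'
#' Mirrors the stimulus design of the novel-word-learning experiments: source
#' words of a fixed length, with the deviation point 0-3 positions before
#' stimulus offset.  The default (`source_length = 6`,
#' `dp_offset_from_end = 2`, 15 triples) reproduces the design of six-phoneme
#' sources whose final two phonemes are replaced to form the two nonwords, so
#' `dp = 4`.
#'
#' @param n_triples Number of triples (>= 1).
#' @param source_length Length of source words to use.
#' @param dp_offset_from_end Integer in 1..3: how many positions before
#'   stimulus offset the deviation point falls, i.e.
#'   `dp = source_length - dp_offset_from_end`.  An offset of 0 would make
#'   the source a prefix of its nonwords (no within-item divergence), which
#'   the triple structure cannot represent with equal-length items.
#' @param seed Integer seed.
#' @param max_attempts Rejection-sampling cap per triple; infeasible specs
#'   error out rather than hang.
#' @return A list of class `triple_spec`.
#' @export
triple_spec <- function(n_triples = 15L, source_length = 6L,
                        dp_offset_from_end = 2L, seed = 1L,
                        max_attempts = 1000L) {
  stopifnot(n_triples >= 1L, source_length >= 2L,
            dp_offset_from_end >= 1L, dp_offset_from_end <= 3L,
            dp_offset_from_end < source_length)
  structure(list(n_triples = as.integer(n_triples),
                 source_length = as.integer(source_length),
                 dp_offset_from_end = as.integer(dp_offset_from_end),
                 seed = as.integer(seed),
                 max_attempts = as.integer(max_attempts)),
            class = "triple_spec")
}

#' Generate item triples from a lexicon
#'
#' Samples `n_triples` source words of the requested length whose prefixes up
#' to the deviation point are unique among the chosen sources, then builds the
#' two nonwords by replacing the final `source_length - dp` phonemes.  The
#' replacement phonemes at position `dp + 1` are drawn from the lexicon's
#' empirical segment distribution, excluding the source's phoneme at that
#' position and excluding each other, which guarantees three-way divergence
#' exactly at `dp + 1`; later positions are drawn from the same distribution.
#' Sampling replacements from the segment distribution (rather than
#' uniformly) keeps nonword continuations phonotactically comparable to word
#' continuations, as in stimuli built from an attested phone inventory.
#' Both nonwords are required to be absent from
#' the lexicon (and distinct from each other); construction is by rejection
#' sampling with a bounded number of attempts.
#'
#' @param lex A [lexicon()].
#' @param spec A [triple_spec()].
#' @return An [item_triples()] table, valid against `lex`.
#' @export
generate_triples <- function(lex, spec) {
  stopifnot(inherits(lex, "lexicon"), inherits(spec, "triple_spec"))
  dp <- spec$source_length - spec$dp_offset_from_end
  stopifnot(dp >= 1L)
  inv <- unclass(lex$inventory)
  if (length(inv) < 3L) stop("need at least 3 phonemes for three-way divergence")
  cand <- lex$entries$form[lex$entries$len == spec$source_length]
  if (length(cand) < spec$n_triples) {
    stop("lexicon has only ", length(cand), " words of length ",
         spec$source_length, "; need ", spec$n_triples)
  }
  # empirical segment (token) distribution of the lexicon
  seg <- table(factor(unlist(lexicon_phon(lex)), levels = inv))
  seg_prob <- as.numeric(seg) / sum(seg)
  with_seed(spec$seed, {
    # sources with pairwise-distinct pre-DP prefixes
    cand <- sample(cand)
    pref <- vapply(strsplit(cand, " ", fixed = TRUE),
                   function(p) paste(p[seq_len(dp)], collapse = " "),
                   character(1))
    sources <- cand[!duplicated(pref)]
    if (length(sources) < spec$n_triples) {
      stop("only ", length(sources), " sources with distinct pre-DP prefixes; ",
           "need ", spec$n_triples)
    }
    sources <- sources[seq_len(spec$n_triples)]
    forms <- lex$entries$form
    used <- character(0)
    nwa <- nwb <- character(spec$n_triples)
    for (i in seq_len(spec$n_triples)) {
      src <- as_phonemes(sources[i])
      ok <- FALSE
      for (att in seq_len(spec$max_attempts)) {
        ok_div <- inv != src[dp + 1L] & seg_prob > 0
        if (sum(ok_div) < 2L) ok_div <- inv != src[dp + 1L]
        div <- sample(inv[ok_div], 2L, prob = seg_prob[ok_div] + 1e-12)
        mk <- function(d) {
          tail_len <- spec$source_length - dp - 1L
          tl <- if (tail_len > 0L) {
            sample(inv, tail_len, replace = TRUE, prob = seg_prob + 1e-12)
          } else character(0)
          paste(c(src[seq_len(dp)], d, tl), collapse = " ")
        }
        a <- mk(div[1L]); b <- mk(div[2L])
        if (a != b && !(a %in% forms) && !(b %in% forms) &&
            !(a %in% used) && !(b %in% used)) {
          nwa[i] <- a; nwb[i] <- b; used <- c(used, a, b); ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("could not build nonwords for source '", sources[i], "' within ",
             spec$max_attempts, " attempts")
      }
    }
    tr <- item_triples(source = sources, nonword_a = nwa, nonword_b = nwb,
                       source_orth = lex$entries$orth[match(sources,
                                                            lex$entries$form)])
    validate_triples(tr, lex)
    tr
  })
}
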