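# Shared fixtures: a small hand-built lexicon in the style of the
# formula/formubo/formuty design, plus random-instance builders.

formula_lexicon <- function() {
  lexicon(forms = c("f o r m j u l ^",   # formula
                    "f o r b i d",       # forbid
                    "f o r s e p s",     # forceps
                    "m u s r u m",       # mushroom
                    "p a r t l i"),      # partly
          frequencies = c(37, 12, 3, 20, 8),
          orth = c("formula", "forbid", "forceps", "mushroom", "partly"),
          inventory = phoneme_inventory(c("f", "o", "r", "m", "j", "u", "l",
                                          "^", "b", "i", "d", "s", "e", "p",
                                          "a", "t", "k")))
}

formula_triples <- function() {
  item_triples(source = "f o r m j u l ^",
               nonword_a = "f o r m j u b o",
               nonword_b = "f o r m j u t i",
               source_orth = "formula")
}

# random lexicon built directly with base R (independent of generate_lexicon)
rand_lexicon <- function(n = 12, inv = c("a", "b", "c", "d"),
                         min_len = 1, max_len = 5) {
  forms <- unique(replicate(4 * n, paste(
    sample(inv, sample(min_len:max_len, 1), replace = TRUE), collapse = " ")))
  forms <- forms[seq_len(min(n, length(forms)))]
  lexicon(forms, frequencies = stats::runif(length(forms), 0.5, 50),
          inventory = phoneme_inventory(inv))
}

# small experiment world used by the experiment/CLI tests (kept far below the
# acceptance desk scale so the default suite stays fast)
small_world <- function(seed = 11, n_words = 80, n_triples = 4) {
  lex <- generate_lexicon(lexicon_spec(n_words = n_words, seed = seed))
  tri <- generate_triples(lex, triple_spec(n_triples = n_triples,
                                           seed = seed + 1L))
  list(lex = lex, triples = tri)
}

fast_params <- function(...) iam_params(n_cycles = 30L, ...)
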