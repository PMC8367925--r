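# Independent brute-force oracles.  These deliberately use naive loops and
# none of the package's vectorized/sparse machinery.

oracle_lcp3 <- function(a, b, c) {
  a <- strsplit(a, " ")[[1]]; b <- strsplit(b, " ")[[1]]; c <- strsplit(c, " ")[[1]]
  k <- 0L
  while (k < min(length(a), length(b), length(c)) &&
         a[k + 1L] == b[k + 1L] && a[k + 1L] == c[k + 1L]) k <- k + 1L
  k
}

oracle_cohort <- function(lex, prefix) {
  phon <- strsplit(lex$entries$form, " ", fixed = TRUE)
  keep <- logical(length(phon))
  for (i in seq_along(phon)) {
    w <- phon[[i]]
    keep[i] <- length(w) > length(prefix) &&
      (length(prefix) == 0 || all(w[seq_along(prefix)] == prefix))
  }
  lex$entries$form[keep]
}

oracle_predict <- function(lex, prefix) {
  inv <- unclass(lex$inventory)
  phon <- strsplit(lex$entries$form, " ", fixed = TRUE)
  probs <- stats::setNames(numeric(length(inv)), inv)
  tot <- 0
  for (i in seq_along(phon)) {
    w <- phon[[i]]
    if (length(w) > length(prefix) &&
        (length(prefix) == 0 || all(w[seq_along(prefix)] == prefix))) {
      nx <- w[length(prefix) + 1]
      probs[nx] <- probs[nx] + lex$entries$frequency[i]
      tot <- tot + lex$entries$frequency[i]
    }
  }
  if (tot == 0) NULL else probs / tot
}

oracle_uniqueness_point <- function(word, lex) {
  w <- strsplit(word, " ")[[1]]
  phon <- strsplit(setdiff(lex$entries$form, word), " ", fixed = TRUE)
  for (n in seq_along(w)) {
    is_prefix_of_other <- FALSE
    for (o in phon) {
      if (length(o) >= n && all(o[seq_len(n)] == w[seq_len(n)])) {
        is_prefix_of_other <- TRUE
        break
      }
    }
    if (!is_prefix_of_other) return(n)
  }
  NA_integer_
}

# naive dense re-implementation of one synchronous update, straight from the
# rules: positive senders only; word <- phoneme excitation via constituency;
# word-word inhibition graded by extent overlap in phoneme widths;
# phoneme <- drive + feedback - window inhibition
oracle_iam_step <- function(state, drive, net) {
  par <- net$params
  p <- state$p; w <- state$w
  pos_p <- pmax(p, 0); pos_w <- pmax(w, 0)
  Cd <- as.matrix(net$C)
  n_wu <- nrow(net$words)
  net_w <- numeric(n_wu)
  for (j in seq_len(n_wu)) {
    excit <- par$excite_phoneme_word * sum(Cd[j, ] * as.vector(pos_p))
    inh <- 0
    for (k in seq_len(n_wu)) {
      if (k == j) next
      ov <- min(net$ends[j], net$ends[k]) - max(net$starts[j], net$starts[k]) + 1L
      if (ov > 0) inh <- inh + pos_w[k] * ov / par$slices_per_phoneme
    }
    net_w[j] <- excit - par$inhibit_word_word * inh
  }
  fb <- par$feedback_word_phoneme * as.vector(t(Cd) %*% pos_w)
  net_p <- matrix(NA_real_, nrow(p), ncol(p))
  for (r in seq_len(nrow(p))) {
    for (t in seq_len(ncol(p))) {
      win <- max(1, t - par$input_spread):min(ncol(p), t + par$input_spread)
      inh <- sum(pos_p[, win]) - pos_p[r, t]
      net_p[r, t] <- par$excite_input_phoneme * drive[r, t] +
        fb[r + (t - 1) * nrow(p)] - par$inhibit_phoneme_phoneme * inh
    }
  }
  upd <- function(a, n, decay, rest) {
    da <- ifelse(n > 0, n * (par$act_max - a), n * (a - par$act_min)) -
      decay * (a - rest)
    pmin(pmax(a + da, par$act_min), par$act_max)
  }
  list(p = upd(p, net_p, par$decay_phoneme, par$rest_phoneme),
       w = upd(w, net_w, par$decay_word, par$rest_word))
}
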