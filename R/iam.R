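#' Parameters of the interactive-activation simulator
#'
#' Defaults follow the classic public parameter settings of the
#' interactive-activation (TRACE-family) tradition: feedforward
#' phoneme-to-word excitation 0.05, word-to-phoneme feedback 0.03, lateral
#' inhibition 0.04 (phoneme) / 0.03 (word), decay 0.03 / 0.05, resting levels
#' -0.1 / -0.01, activation range \[-0.3, 1\], six time slices per phoneme, a
#' triangular input ramp spreading over +/- 3 slices (coarticulatory overlap),
#' and 100 update cycles.  The feature layer is abstracted: bottom-up input
#' drives phoneme units directly through [encode_input()].
#'
#' @param excite_input_phoneme Input-to-phoneme excitation weight.
#' @param excite_phoneme_word Phoneme-to-word excitation weight.
#' @param feedback_word_phoneme Word-to-phoneme (lexical feedback) weight;
#'   set to 0 to ablate feedback.
#' @param inhibit_phoneme_phoneme,inhibit_word_word Lateral inhibition weights.
#' @param decay_phoneme,decay_word Decay rates in \[0, 1\].
#' @param rest_phoneme,rest_word Resting activations (`act_min < rest <= 0`).
#' @param act_min,act_max Activation bounds (`act_max = 1` by convention).
#' @param slices_per_phoneme Trace slices per input phoneme (>= 1).
#' @param input_spread Half-width, in slices, of the triangular input ramp
#'   and of the phoneme-level inhibition window.
#' @param n_cycles Number of synchronous update cycles.
#' @return A list of class `iam_params`.
#' @export
iam_params <- function(excite_input_phoneme = 0.1,
                       excite_phoneme_word = 0.05,
                       feedback_word_phoneme = 0.03,
                       inhibit_phoneme_phoneme = 0.04,
                       inhibit_word_word = 0.03,
                       decay_phoneme = 0.03, decay_word = 0.05,
                       rest_phoneme = -0.1, rest_word = -0.01,
                       act_min = -0.3, act_max = 1,
                       slices_per_phoneme = 6L, input_spread = 3L,
                       n_cycles = 100L) {
  p <- list(excite_input_phoneme = excite_input_phoneme,
            excite_phoneme_word = excite_phoneme_word,
            feedback_word_phoneme = feedback_word_phoneme,
            inhibit_phoneme_phoneme = inhibit_phoneme_phoneme,
            inhibit_word_word = inhibit_word_word,
            decay_phoneme = decay_phoneme, decay_word = decay_word,
            rest_phoneme = rest_phoneme, rest_word = rest_word,
            act_min = act_min, act_max = act_max,
            slices_per_phoneme = as.integer(slices_per_phoneme),
            input_spread = as.integer(input_spread),
            n_cycles = as.integer(n_cycles))
  stopifnot(p$excite_input_phoneme >= 0, p$excite_phoneme_word >= 0,
            p$feedback_word_phoneme >= 0, p$inhibit_phoneme_phoneme >= 0,
            p$inhibit_word_word >= 0,
            p$decay_phoneme >= 0, p$decay_phoneme <= 1,
            p$decay_word >= 0, p$decay_word <= 1,
            p$act_min < p$rest_phoneme, p$rest_phoneme <= 0,
            p$act_min < p$rest_word, p$rest_word <= 0, p$act_max > 0,
            p$slices_per_phoneme >= 1L, p$input_spread >= 0L, p$n_cycles >= 1L)
  structure(p, class = "iam_params")
}

#' Build a lexicon-parameterized interactive-activation network
#'
#' Allocates one phoneme unit per (phoneme symbol, time slice) and one word
#' unit per (lexical entry, alignment slice) for every alignment whose full
#' extent (`length * slices_per_phoneme` slices) fits in the slice range, and
#' records each word unit's constituent (phoneme, slice) positions: phoneme
#' `j` of a word aligned at slice `s` occupies the phoneme unit at slice
#' `s + (j - 1) * slices_per_phoneme`.  Off-canonical alignments are what let
#' spurious candidates (a word unit aligned mid-item) contribute to the
#' layer totals.
#'
#' @param lex A [lexicon()].
#' @param params An [iam_params()].
#' @param n_slices Number of time slices in the trace.
#' @return A list of class `iam_network` with the unit tables, the sparse
#'   word-to-phoneme constituency matrix, and precomputed inhibition indices.
#' @export
build_network <- function(lex, params, n_slices) {
  stopifnot(inherits(lex, "lexicon"), inherits(params, "iam_params"))
  n_slices <- as.integer(n_slices)
  if (n_slices < 1L) stop("n_slices must be >= 1")
  inv <- unclass(lex$inventory)
  n_phon <- length(inv)
  spp <- params$slices_per_phoneme
  phon <- lexicon_phon(lex)
  for (p in phon) check_phonemes(p, lex$inventory, "lexicon form")
  # word units: every (entry, start slice) whose extent fits
  lens <- lex$entries$len
  extents <- lens * spp
  wi <- rep.int(seq_along(phon), pmax(n_slices - extents + 1L, 0L))
  starts <- unlist(lapply(seq_along(phon), function(i) {
    k <- n_slices - extents[i] + 1L
    if (k >= 1L) seq_len(k) else integer(0)
  }))
  n_wu <- length(wi)
  if (n_wu == 0L) stop("no word fits in ", n_slices, " slices")
  ends <- starts + extents[wi] - 1L
  # constituency: word unit -> (phoneme row, slice) pairs
  ii <- rep.int(seq_len(n_wu), lens[wi])
  pos_in_word <- unlist(lapply(lens[wi], seq_len))
  sym <- unlist(phon[wi])
  rows <- match(sym, inv)
  slc <- starts[ii] + (pos_in_word - 1L) * spp
  C <- Matrix::sparseMatrix(i = ii, j = rows + (slc - 1L) * n_phon,
                            x = 1, dims = c(n_wu, n_phon * n_slices))
  # word-word inhibition is proportional to the slice overlap of the two
  # units' extents (the standard alignment-competition scheme); the per-slice
  # positive-activation coverage is accumulated with a difference array:
  # cov_delta maps unit activations to +a at start and -a past end
  cov_delta <- Matrix::sparseMatrix(
    i = c(starts, ends + 1L), j = rep.int(seq_len(n_wu), 2L),
    x = rep(c(1, -1), each = n_wu), dims = c(n_slices + 1L, n_wu))
  structure(list(inventory = lex$inventory, n_phon = n_phon,
                 n_slices = n_slices, params = params,
                 words = data.table::data.table(word_idx = wi, start = starts,
                                                end = ends, len = lens[wi],
                                                orth = lex$entries$orth[wi]),
                 C = C, n_const = lens[wi],
                 starts = starts, ends = ends, extent = extents[wi],
                 cov_delta = cov_delta),
            class = "iam_network")
}

#' @exportS3Method base::print
print.iam_network <- function(x, ...) {
  cat("<iam_network> ", x$n_phon, " phonemes x ", x$n_slices, " slices (",
      x$n_phon * x$n_slices, " phoneme units), ", nrow(x$words),
      " word units\n", sep = "")
  invisible(x)
}

#' Encode an item as a mock-speech input timecourse
#'
#' Phoneme `i` of the item drives the phoneme units of its symbol with a
#' triangular ramp peaking (value 1) at slice `(i - 1) * slices_per_phoneme +
#' 1` and falling linearly to 0 over `+/- input_spread` slices, emulating
#' sequential presentation with coarticulatory overlap.  Presentation is
#' gated in time: the input stream sits at slice `c` on cycle `c`, so the
#' unit at slice `t` is driven only while `|cycle - t| <= input_spread` —
#' a transient sweep, after which activation is carried by the network's own
#' dynamics (decay, feedback), not by the stimulus.
#'
#' @param item Phoneme sequence.
#' @param params An [iam_params()].
#' @param n_slices Number of time slices.
#' @param inventory A [phoneme_inventory()].
#' @return A list of class `input_timecourse` with the drive matrix `D`
#'   (`n_phon x n_slices`, values in \[0, 1\]).
#' @export
encode_input <- function(item, params, n_slices, inventory) {
  item <- check_phonemes(item, inventory, "item")
  if (length(item) == 0L) stop("item must be non-empty")
  inv <- unclass(inventory)
  spp <- params$slices_per_phoneme
  spread <- params$input_spread
  D <- matrix(0, nrow = length(inv), ncol = n_slices,
              dimnames = list(inv, NULL))
  for (i in seq_along(item)) {
    peak <- (i - 1L) * spp + 1L
    r <- match(item[i], inv)
    for (o in seq.int(-spread, spread)) {
      t <- peak + o
      if (t >= 1L && t <= n_slices) {
        D[r, t] <- D[r, t] + (1 - abs(o) / (spread + 1))
      }
    }
  }
  D <- pmin(D, 1)
  structure(list(D = D, item = item, n_slices = n_slices),
            class = "input_timecourse")
}

# sliding-window sum over slices: W[t] = sum_{|t'-t| <= win} x[t']
slice_window_sum <- function(x, win) {
  if (win == 0L) return(x)
  cs <- c(0, cumsum(x))
  n <- length(x)
  hi <- pmin(seq_len(n) + win, n)
  lo <- pmax(seq_len(n) - win, 1L)
  cs[hi + 1L] - cs[lo]
}

#' One synchronous interactive-activation update
#'
#' Standard interactive-activation dynamics.  Only positive activations
#' transmit.  Net input to a phoneme unit is bottom-up drive plus lexical
#' feedback from word units containing it, minus lateral inhibition from
#' other phoneme units within the spread window of its slice.  Net input to
#' a word unit is excitation from its constituent phoneme units minus lateral
#' inhibition from word units with overlapping extent, weighted by the amount
#' of overlap (in phoneme widths): alignment competition is graded, so a
#' candidate barely overlapping the current winner is only mildly suppressed.  For net input
#' `n > 0`, `da = n * (act_max - a) - decay * (a - rest)`; otherwise
#' `da = n * (a - act_min) - decay * (a - rest)`; activations are clamped to
#' `[act_min, act_max]`.  The update is synchronous across all units.
#'
#' @param state List with `p` (phoneme activation matrix), `w` (word unit
#'   activation vector) and `cycle`.
#' @param drive Bottom-up drive matrix for this cycle (`n_phon x n_slices`).
#' @param net An [build_network()] result.
#' @return The updated state; element `total_feedback` records the lexical
#'   feedback transmitted this cycle (`weight * sum over word-to-phoneme
#'   connections of the positive sender activation`).
#' @export
iam_step <- function(state, drive, net) {
  par <- net$params
  p <- state$p; w <- state$w
  pos_p <- pmax(p, 0); pos_w <- pmax(w, 0)
  # word layer net input
  excit_w <- par$excite_phoneme_word * as.numeric(net$C %*% as.vector(pos_p))
  # overlap-weighted competition: unit j receives sum over other units k of
  # pos_w[k] * overlap(j, k), overlap measured in phoneme widths
  # (slices / slices_per_phoneme); computed via per-slice coverage
  cov <- cumsum(as.numeric(net$cov_delta %*% pos_w))[seq_len(net$n_slices)]
  cov2 <- c(0, cumsum(cov))
  inh_w <- (cov2[net$ends + 1L] - cov2[net$starts] -
              pos_w * net$extent) / par$slices_per_phoneme
  net_w <- excit_w - par$inhibit_word_word * inh_w
  # phoneme layer net input
  fb <- par$feedback_word_phoneme *
    as.numeric(Matrix::crossprod(net$C, pos_w))
  Wsum <- slice_window_sum(colSums(pos_p), par$input_spread)
  inh_p <- rep(Wsum, each = net$n_phon) - pos_p
  net_p <- par$excite_input_phoneme * drive +
    matrix(fb, net$n_phon, net$n_slices) -
    par$inhibit_phoneme_phoneme * inh_p
  upd <- function(a, n, decay, rest) {
    da <- ifelse(n > 0, n * (par$act_max - a), n * (a - par$act_min)) -
      decay * (a - rest)
    pmin(pmax(a + da, par$act_min), par$act_max)
  }
  list(p = upd(p, net_p, par$decay_phoneme, par$rest_phoneme),
       w = upd(w, net_w, par$decay_word, par$rest_word),
       cycle = state$cycle + 1L,
       total_feedback = par$feedback_word_phoneme * sum(pos_w * net$n_const))
}

#' Cycle at which the post-DP input first arrives
#'
#' The divergent phoneme of a triple is at position `dp + 1`; its input ramp
#' peaks at slice `dp * slices_per_phoneme + 1` and, with the slice spread
#' and the temporal sweep window both extending `input_spread` wide, its
#' earliest drive arrives `2 * input_spread` cycles before the peak slice.
#' Cycles strictly before this onset constitute the pre-DP window, over which
#' the three items of a triple receive identical input.
#'
#' @param dp Deviation point (number of shared phonemes).
#' @param params An [iam_params()].
#' @return Integer cycle index.
#' @export
dp_onset_cycle <- function(dp, params) {
  pmax(dp * params$slices_per_phoneme + 1L - 2L * params$input_spread, 1L)
}

#' Run an instrumented simulation
#'
#' Initializes every unit at its layer resting level, encodes `item` with
#' [encode_input()], iterates [iam_step()] for `n_cycles`, and records per
#' cycle: all phoneme unit activations, all word unit activations, the total
#' lexical feedback flow, and the raw (negative-capable) activation totals of
#' each layer.  Fully deterministic.
#'
#' @param item Phoneme sequence to present.
#' @param lex A [lexicon()].
#' @param params An [iam_params()].
#' @param n_slices Trace length in slices; the default
#'   `(length(item) - 1) * spp + max_word_len * spp` leaves room for word
#'   units aligned at every position of the item, including candidates
#'   extending past item offset.
#' @param network Optionally a prebuilt [build_network()] (must match `lex`,
#'   `params`, `n_slices`); reuse across items saves setup time.
#' @param record_units Keep per-unit activation histories (needed by
#'   [phoneme_timecourse()] and the consistency checks).
#' @return A list of class `simulation_trace`: `totals` (a `data.frame` with
#'   columns `cycle`, `total_feedback`, `total_word_act`,
#'   `total_phoneme_act`), `phoneme_act` (`n_phon x n_slices x n_cycles`
#'   array), `word_act` (`n_word_units x n_cycles` matrix), plus the network
#'   and input used.
#' @export
run_iam <- function(item, lex, params = iam_params(), n_slices = NULL,
                    network = NULL, record_units = TRUE) {
  item <- check_phonemes(item, lex$inventory, "item")
  spp <- params$slices_per_phoneme
  if (is.null(n_slices)) {
    maxlen <- max(max(lex$entries$len), length(item))
    n_slices <- (length(item) - 1L) * spp + maxlen * spp
  }
  if (n_slices < length(item) * spp) {
    stop("n_slices must be at least item length x slices_per_phoneme")
  }
  net <- if (is.null(network)) build_network(lex, params, n_slices) else network
  stopifnot(inherits(net, "iam_network"), net$n_slices == n_slices)
  inp <- encode_input(item, params, n_slices, lex$inventory)
  n_phon <- net$n_phon
  n_wu <- nrow(net$words)
  state <- list(p = matrix(params$rest_phoneme, n_phon, n_slices,
                           dimnames = dimnames(inp$D)),
                w = rep(params$rest_word, n_wu), cycle = 0L)
  nc <- params$n_cycles
  totals <- data.frame(cycle = seq_len(nc), total_feedback = NA_real_,
                       total_word_act = NA_real_, total_phoneme_act = NA_real_)
  phoneme_act <- if (record_units) array(NA_real_, c(n_phon, n_slices, nc))
                 else NULL
  word_act <- if (record_units) matrix(NA_real_, n_wu, nc) else NULL
  slice_idx <- seq_len(n_slices)
  for (cyc in seq_len(nc)) {
    drive <- inp$D
    off <- abs(slice_idx - cyc) > params$input_spread
    if (any(off)) drive[, off] <- 0
    state <- iam_step(state, drive, net)
    totals$total_feedback[cyc] <- state$total_feedback
    totals$total_word_act[cyc] <- sum(state$w)
    totals$total_phoneme_act[cyc] <- sum(state$p)
    if (record_units) {
      phoneme_act[, , cyc] <- state$p
      word_act[, cyc] <- state$w
    }
  }
  structure(list(item = item, totals = totals, phoneme_act = phoneme_act,
                 word_act = word_act, network = net, input = inp,
                 params = params),
            class = "simulation_trace")
}

#' @exportS3Method base::print
print.simulation_trace <- function(x, ...) {
  cat("<simulation_trace> item [", paste(x$item, collapse = " "), "], ",
      nrow(x$totals), " cycles, ", nrow(x$network$words), " word units\n",
      sep = "")
  invisible(x)
}

#' Per-cycle activation of one phoneme unit of an item
#'
#' Reads the activation timecourse of the phoneme unit for `phoneme` at the
#' slice where the item's `position`-th phoneme peaks (the input-aligned
#' unit).  Any inventory phoneme may be read at that slice — e.g. the
#' replacement phonemes of a triple at the post-DP position.
#'
#' @param trace A [run_iam()] result (with `record_units = TRUE`).
#' @param phoneme Phoneme symbol to read.
#' @param position 1-based position within the presented item.
#' @return Numeric vector of length `n_cycles`.
#' @export
phoneme_timecourse <- function(trace, phoneme, position) {
  stopifnot(inherits(trace, "simulation_trace"))
  if (is.null(trace$phoneme_act)) stop("trace was run with record_units = FALSE")
  if (position < 1L || position > length(trace$item)) {
    stop("position ", position, " outside the presented item")
  }
  inv <- unclass(trace$network$inventory)
  r <- match(phoneme, inv)
  if (is.na(r)) stop("no unit for phoneme '", phoneme, "'")
  slice <- (position - 1L) * trace$params$slices_per_phoneme + 1L
  trace$phoneme_act[r, slice, ]
}
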