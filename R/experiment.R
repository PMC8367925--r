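#' Counterbalanced pre/post-training model runs, aligned at the deviation point
#'
#' Executes the full experimental design for one model: both counterbalance
#' assignments (A: nonword A is the trained novel item; B: nonword B is), each
#' in the pre-training phase (original lexicon) and the post-training phase
#' ([train_lexicon()] output), collecting the model's signals for every item
#' of every triple.  Results are aligned on the deviation point — by
#' DP-relative phoneme position for the prediction model (`rel <= 0` pre-DP,
#' `rel >= 1` post-DP), or by cycle relative to the onset of the divergent
#' phoneme's input for the interactive-activation model (`rel = cycle -
#' dp_onset_cycle + 1`) — and averaged over the two assignments.
#'
#' @param lex The pre-training [lexicon()].
#' @param triples An [item_triples()] table, valid against `lex`.
#' @param model `"prediction"` or `"iam"`.
#' @param params An [iam_params()] (IAM only).
#' @param freq_transform,fallback Passed to [error_trajectory()] (prediction
#'   model only).
#' @return A list of class `aligned_result`: `cells` (mean per signal x
#'   condition x phase x DP-relative position, with `n_items`), `per_item`
#'   (the underlying long table, one row per signal x triple x condition x
#'   phase x assignment x position), `model`, and `config` (echo of the
#'   settings used).
#' @export
run_counterbalanced <- function(lex, triples, model = c("prediction", "iam"),
                                params = iam_params(),
                                freq_transform = c("raw", "log1p"),
                                fallback = c("uniform", "zero")) {
  model <- match.arg(model)
  freq_transform <- match.arg(freq_transform)
  fallback <- match.arg(fallback)
  validate_triples(triples, lex)
  lexes <- list(pre = lex,
                post_A = train_lexicon(lex, triples, "A"),
                post_B = train_lexicon(lex, triples, "B"))
  rows <- list()
  # per-(lexicon, item) signal extraction, cached: pre-phase traces are shared
  # by both assignments, only the condition labels differ
  cache <- new.env(parent = emptyenv())
  item_signals <- function(lexkey, item, dp) {
    key <- paste(lexkey, item)
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- if (model == "prediction") {
      tr <- error_trajectory(lexes[[lexkey]], item,
                             freq_transform = freq_transform,
                             fallback = fallback)
      data.table::data.table(
        signal = rep(c("prediction_error", "prob_observed"),
                     each = nrow(tr)),
        rel = rep(tr$position - dp, 2L),
        value = c(tr$error, tr$prob_observed))
    } else {
      L <- lexes[[lexkey]]
      nlk <- paste0("net_", lexkey, "_", length(as_phonemes(item)))
      if (is.null(cache[[nlk]])) {
        spp <- params$slices_per_phoneme
        n_it <- length(as_phonemes(item))
        n_slices <- (n_it - 1L) * spp + max(max(L$entries$len), n_it) * spp
        cache[[nlk]] <- build_network(L, params, n_slices)
      }
      net <- cache[[nlk]]
      tr <- run_iam(item, L, params, n_slices = net$n_slices,
                    network = net, record_units = FALSE)
      onset <- dp_onset_cycle(dp, params)
      data.table::data.table(
        signal = rep(c("total_feedback", "total_word_act",
                       "total_phoneme_act"), each = nrow(tr$totals)),
        rel = rep(tr$totals$cycle - onset + 1L, 3L),
        value = c(tr$totals$total_feedback, tr$totals$total_word_act,
                  tr$totals$total_phoneme_act))
    }
    cache[[key]] <- val
    val
  }
  for (assignment in c("A", "B")) {
    items_by_cond <- list(
      source = triples$source,
      novel = if (assignment == "A") triples$nonword_a else triples$nonword_b,
      baseline = if (assignment == "A") triples$nonword_b else triples$nonword_a)
    for (phase in c("pre", "post")) {
      lexkey <- if (phase == "pre") "pre" else paste0("post_", assignment)
      for (cond in names(items_by_cond)) {
        for (i in seq_len(nrow(triples))) {
          sig <- item_signals(lexkey, items_by_cond[[cond]][i], triples$dp[i])
          rows[[length(rows) + 1L]] <- data.table::data.table(
            signal = sig$signal, triple_id = triples$triple_id[i],
            item = items_by_cond[[cond]][i], condition = cond, phase = phase,
            assignment = assignment, rel = sig$rel, value = sig$value)
        }
      }
    }
  }
  per_item <- data.table::rbindlist(rows)
  cells <- per_item[, list(mean = mean(value), n_items = .N),
                    by = c("signal", "condition", "phase", "rel")]
  data.table::setorderv(cells, c("signal", "condition", "phase", "rel"))
  structure(list(cells = cells[], per_item = per_item[], model = model,
                 config = list(model = model,
                               freq_transform = freq_transform,
                               fallback = fallback,
                               params = if (model == "iam") unclass(params),
                               n_triples = nrow(triples))),
            class = "aligned_result")
}

#' @exportS3Method base::print
print.aligned_result <- function(x, ...) {
  cat("<aligned_result> model '", x$model, "', signals: ",
      paste(unique(x$cells$signal), collapse = ", "), ", ",
      x$config$n_triples, " triples\n", sep = "")
  invisible(x)
}

rel_diff <- function(a, b) {
  d <- max(abs(a), abs(b))
  if (d == 0) 0 else abs(a - b) / d
}

default_windows <- function(res) {
  if (res$model == "prediction") {
    list(post = c(1, 2), pre = c(-Inf, 0))
  } else {
    list(post = c(1, Inf), pre = c(-Inf, 0))
  }
}

finding3_direction <- function(signal) {
  switch(signal,
         prediction_error = "decrease", total_word_act = "decrease",
         total_feedback = "increase", prob_observed = "increase",
         total_phoneme_act = "equal",
         stop("no default training direction for signal '", signal, "'"))
}

#' Score the three empirical findings on an aligned result
#'
#' The three findings that operationalize "signal reduction for expected
#' input" in the novel-word-learning design, evaluated on one signal:
#'
#' 1. *Pre-training*: on the post-DP window, the source word carries less
#'    signal than the novel item and than the baseline nonword, and the two
#'    (both unknown to the lexicon) are approximately equal.
#' 2. *Post-training*: source and trained novel item both carry less signal
#'    than the baseline nonword, and are approximately equal to each other.
#' 3. *Pre-DP training effect*: the pre-DP aggregate (all conditions pooled;
#'    their inputs are identical before the DP) moves between phases in the
#'    direction characteristic of the signal — prediction error and total
#'    word-layer activation decrease after training, total lexical feedback
#'    increases (lexical competition from the added word), and total
#'    phoneme-layer activation is unchanged within tolerance.
#'
#' @param res An [run_counterbalanced()] result.
#' @param signal Which signal to score (default: the model's headline signal).
#' @param post_dp_window,pre_dp_window Length-2 `c(lo, hi)` ranges of
#'   DP-relative positions (prediction model) or cycles (IAM); defaults are
#'   positions 1..2 / cycles from DP-input onset onward, and everything
#'   at or before the DP.
#' @param tol Relative tolerance for the "approximately equal" comparisons
#'   (default 0.10: the design argues patterns, not point equality).
#' @param direction Direction for finding 3: `"decrease"`, `"increase"`,
#'   `"equal"`, or `"auto"` (per-signal default).
#' @return A list of class `findings_report`: logical `finding1`, `finding2`,
#'   `finding3`, the compared cell means, and a metadata echo.
#' @export
check_findings <- function(res, signal = NULL, post_dp_window = NULL,
                           pre_dp_window = NULL, tol = 0.10,
                           direction = "auto") {
  stopifnot(inherits(res, "aligned_result"))
  if (is.null(signal)) {
    signal <- if (res$model == "prediction") "prediction_error"
              else "total_feedback"
  }
  w <- default_windows(res)
  if (is.null(post_dp_window)) post_dp_window <- w$post
  if (is.null(pre_dp_window)) pre_dp_window <- w$pre
  if (identical(direction, "auto")) direction <- finding3_direction(signal)
  keep_rows <- which(res$per_item[["signal"]] == signal)
  pi <- res$per_item[keep_rows]
  if (nrow(pi) == 0L) stop("signal '", signal, "' not present in the result")
  post <- pi[pi$rel >= post_dp_window[1] & pi$rel <= post_dp_window[2]]
  m <- post[, list(mean = mean(value)), by = c("condition", "phase")]
  need <- expand.grid(condition = c("source", "novel", "baseline"),
                      phase = c("pre", "post"), stringsAsFactors = FALSE)
  if (nrow(merge(m, need)) < 6L) {
    stop("missing condition x phase cells on the post-DP window")
  }
  g <- function(cond, ph) m$mean[m$condition == cond & m$phase == ph]
  finding1 <- g("source", "pre") < g("novel", "pre") &&
    g("source", "pre") < g("baseline", "pre") &&
    rel_diff(g("novel", "pre"), g("baseline", "pre")) <= tol
  finding2 <- g("source", "post") < g("baseline", "post") &&
    g("novel", "post") < g("baseline", "post") &&
    rel_diff(g("source", "post"), g("novel", "post")) <= tol
  predp <- pi[pi$rel >= pre_dp_window[1] & pi$rel <= pre_dp_window[2]]
  pre_mean <- mean(predp$value[predp$phase == "pre"])
  post_mean <- mean(predp$value[predp$phase == "post"])
  finding3 <- switch(direction,
                     decrease = post_mean < pre_mean,
                     increase = post_mean > pre_mean,
                     equal = rel_diff(post_mean, pre_mean) <= tol,
                     stop("unknown direction '", direction, "'"))
  structure(list(signal = signal, finding1 = finding1, finding2 = finding2,
                 finding3 = finding3,
                 post_dp_means = stats::setNames(
                   lapply(seq_len(nrow(m)), function(i) m$mean[i]),
                   paste(m$condition, m$phase, sep = ".")),
                 pre_dp_phase_means = list(pre = pre_mean, post = post_mean),
                 metadata = list(model = res$model, tol = tol,
                                 direction = direction,
                                 post_dp_window = post_dp_window,
                                 pre_dp_window = pre_dp_window,
                                 config = res$config)),
            class = "findings_report")
}

#' @exportS3Method base::print
print.findings_report <- function(x, ...) {
  cat("<findings_report> signal '", x$signal, "'\n", sep = "")
  cat(sprintf("  finding1 (pre:  source < novel ~ baseline, post-DP): %s\n",
              x$finding1))
  cat(sprintf("  finding2 (post: source ~ novel < baseline, post-DP): %s\n",
              x$finding2))
  cat(sprintf("  finding3 (pre-DP %s after training): %s  [pre %.4g, post %.4g]\n",
              x$metadata$direction, x$finding3,
              x$pre_dp_phase_means$pre, x$pre_dp_phase_means$post))
  invisible(x)
}

#' Anticipatory phoneme activation around the deviation point
#'
#' The lexical-feedback signature of predictive processing: while the input is
#' still in the shared pre-DP region, the word layer feeds activation down to
#' the phonemes it expects next.  For each triple the source item is
#' presented and the activations of the three candidate phonemes at position
#' `dp + 1` (the source's own continuation and the two replacement phonemes)
#' are read over the `window` cycles immediately before the divergent input's
#' onset; inputs are identical across the three items in this window.
#'
#' @param lex The pre-training [lexicon()].
#' @param triples An [item_triples()] table.
#' @param params An [iam_params()].
#' @param window Number of pre-onset cycles to average (default 10).
#' @return A list of class `anticipation_report`: `anticipation_pre` (pre-
#'   training, the lexically supported phoneme out-activates both replacement
#'   phonemes), `training_boost` (the trained replacement's pre-DP activation
#'   rises from pre- to post-training, averaged over counterbalance), and the
#'   underlying means.
#' @export
anticipation_check <- function(lex, triples, params = iam_params(),
                               window = 10L) {
  validate_triples(triples, lex)
  lexes <- list(pre = lex,
                post_A = train_lexicon(lex, triples, "A"),
                post_B = train_lexicon(lex, triples, "B"))
  nets <- new.env(parent = emptyenv())
  get_tc <- function(lexkey, item, dp, phonemes) {
    L <- lexes[[lexkey]]
    it <- as_phonemes(item)
    spp <- params$slices_per_phoneme
    n_slices <- (length(it) - 1L) * spp + max(max(L$entries$len),
                                              length(it)) * spp
    nk <- paste0(lexkey, "_", n_slices)
    if (is.null(nets[[nk]])) nets[[nk]] <- build_network(L, params, n_slices)
    tr <- run_iam(it, L, params, n_slices = n_slices, network = nets[[nk]])
    onset <- dp_onset_cycle(dp, params)
    cycles <- seq.int(max(onset - window, 1L), onset - 1L)
    vapply(phonemes, function(ph) {
      mean(phoneme_timecourse(tr, ph, dp + 1L)[cycles])
    }, numeric(1))
  }
  n <- nrow(triples)
  src <- rep(NA_real_, n); repA <- rep(NA_real_, n); repB <- rep(NA_real_, n)
  postA_trained <- rep(NA_real_, n); postB_trained <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    dp <- triples$dp[i]
    phs <- c(as_phonemes(triples$source[i])[dp + 1L],
             as_phonemes(triples$nonword_a[i])[dp + 1L],
             as_phonemes(triples$nonword_b[i])[dp + 1L])
    pre <- get_tc("pre", triples$source[i], dp, phs)
    src[i] <- pre[1L]; repA[i] <- pre[2L]; repB[i] <- pre[3L]
    postA_trained[i] <- get_tc("post_A", triples$source[i], dp, phs[2L])
    postB_trained[i] <- get_tc("post_B", triples$source[i], dp, phs[3L])
  }
  means <- list(source_pre = mean(src), replacement_a_pre = mean(repA),
                replacement_b_pre = mean(repB),
                trained_pre = mean(c(repA, repB)),
                trained_post = mean(c(postA_trained, postB_trained)))
  structure(list(
    anticipation_pre = means$source_pre > means$replacement_a_pre &&
      means$source_pre > means$replacement_b_pre,
    training_boost = means$trained_post > means$trained_pre,
    means = means,
    metadata = list(window = window, params = unclass(params))),
    class = "anticipation_report")
}

#' @exportS3Method base::print
print.anticipation_report <- function(x, ...) {
  cat("<anticipation_report>\n")
  cat(sprintf("  pre-training anticipation (source phoneme > replacements): %s\n",
              x$anticipation_pre))
  cat(sprintf("  training boost (trained replacement rises pre-DP): %s\n",
              x$training_boost))
  cat(sprintf("  means: source %.4f, repl A %.4f, repl B %.4f, trained pre %.4f -> post %.4f\n",
              x$means$source_pre, x$means$replacement_a_pre,
              x$means$replacement_b_pre, x$means$trained_pre,
              x$means$trained_post))
  invisible(x)
}

#' Export an experiment report
#'
#' Writes the DP-aligned cell means as a tidy CSV (one row per signal x
#' condition x phase x DP-relative position), a machine-readable findings
#' summary as JSON, and optionally DP-aligned line plots (dashed marker
#' between relative positions 0 and 1) as a PDF.  The CSV and JSON outputs
#' are byte-deterministic for a fixed input.
#'
#' @param results A single [run_counterbalanced()] result or a list of them.
#' @param findings A [check_findings()] report or a list of them (optional).
#' @param dir Output directory (created if needed).
#' @param plots Whether to draw the PDF figures.
#' @return Invisibly, the paths written.
#' @export
export_report <- function(results, findings = NULL, dir, plots = TRUE) {
  if (inherits(results, "aligned_result")) results <- list(results)
  if (inherits(findings, "findings_report")) findings <- list(findings)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cells <- data.table::rbindlist(lapply(results, function(r) {
    cbind(data.table::data.table(model = r$model), r$cells)
  }))
  data.table::setorderv(cells, c("model", "signal", "condition", "phase", "rel"))
  paths <- file.path(dir, "cells.csv")
  data.table::fwrite(cells, paths[1L])
  if (!is.null(findings)) {
    fj <- lapply(findings, function(f) {
      list(signal = f$signal, finding1 = f$finding1, finding2 = f$finding2,
           finding3 = f$finding3, post_dp_means = f$post_dp_means,
           pre_dp_phase_means = f$pre_dp_phase_means, metadata = f$metadata)
    })
    names(fj) <- vapply(findings, function(f)
      paste(f$metadata$model, f$signal, sep = "."), character(1))
    fp <- file.path(dir, "findings.json")
    jsonlite::write_json(fj, fp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    paths <- c(paths, fp)
  }
  if (plots) {
    pp <- file.path(dir, "aligned_signals.pdf")
    grDevices::pdf(pp, width = 8, height = 4.5)
    on.exit(grDevices::dev.off(), add = TRUE)
    cols <- c(source = "#1b9e77", novel = "#d95f02", baseline = "#7570b3")
    for (sg in unique(cells$signal)) {
      d <- cells[cells$signal == sg]
      graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
      for (ph in c("pre", "post")) {
        dd <- d[d$phase == ph]
        graphics::plot(NA, xlim = range(dd$rel), ylim = range(dd$mean),
                       xlab = "position relative to deviation point",
                       ylab = sg, main = paste0(ph, "-training"))
        graphics::abline(v = 0.5, lty = 2, col = "red")
        for (cond in names(cols)) {
          dc <- dd[dd$condition == cond]
          graphics::lines(dc$rel, dc$mean, col = cols[[cond]], lwd = 2)
        }
        graphics::legend("topleft", legend = names(cols), col = cols,
                         lwd = 2, bty = "n", cex = 0.8)
      }
    }
    paths <- c(paths, pp)
  }
  invisible(paths)
}
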