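#' Filtered rank of a true answer among scored candidates
#'
#' Implements the filtered evaluation protocol: every other answer known
#' to be true for the same query (train/valid/other test answers,
#' excluding the truth being ranked) is removed from the candidate list,
#' then the rank is `1 + #{candidates scoring strictly above the truth} +
#' #{ties}/2` (mean rank over ties). A truth missing from `scores`
#' receives the minimum score, with a message.
#'
#' @param scores named numeric vector: candidate id -> score
#' @param truth the true answer's entity id
#' @param other_known_truths ids of other known answers to filter out
#'   (must not contain `truth`)
#' @return list with `rank` (numeric, >= 1), `truth`, `filtered` = TRUE
#' @export
kg_filtered_rank <- function(scores, truth, other_known_truths = character()) {
  if (truth %in% other_known_truths) {
    stop("truth must not appear among other_known_truths")
  }
  if (!truth %in% names(scores)) {
    message("truth ", truth, " unscored; assigning the minimum score")
    scores[truth] <- if (length(scores)) min(scores) else 0
  }
  scores <- scores[!(names(scores) %in% other_known_truths)]
  st <- scores[[truth]]
  others <- scores[names(scores) != truth]
  rank <- 1 + sum(others > st) + sum(others == st) / 2
  list(rank = rank, truth = truth, filtered = TRUE)
}

#' Summarize filtered ranks into MRR, Hits@k and confidence intervals
#'
#' MRR is the mean reciprocal rank; Hits@k the fraction of ranks <= k.
#' Because repurposing test sets are small, interval estimates accompany
#' the points: exact Clopper-Pearson binomial intervals for the Hits
#' proportions (Wilson available), and a seeded bootstrap percentile
#' interval for MRR.
#'
#' @param ranks numeric vector of (filtered) ranks
#' @param ks Hits@k cutoffs
#' @param ci_level confidence level (default 0.90)
#' @param ci_method `"clopper-pearson"` or `"wilson"` for the Hits
#'   intervals
#' @param bootstrap number of bootstrap resamples for the MRR interval
#' @param seed bootstrap seed
#' @return object of class `kg_eval`: list with `mrr`, `hits` (named
#'   vector), `n`, `ci` (named list of `c(lower, upper)`), `level`
#' @export
kg_eval_summary <- function(ranks, ks = c(1, 3, 10), ci_level = 0.90,
                            ci_method = c("clopper-pearson", "wilson"),
                            bootstrap = 10000L, seed = 1L) {
  ci_method <- match.arg(ci_method)
  if (length(ranks) == 0L) stop("no rank records to summarize")
  stopifnot(all(ranks >= 1))
  n <- length(ranks)
  mrr <- mean(1 / ranks)
  hits <- vapply(ks, function(k) mean(ranks <= k), 0)
  names(hits) <- paste0("hits_at_", ks)
  ci <- lapply(ks, function(k) {
    binom_ci(sum(ranks <= k), n, ci_level, ci_method)
  })
  names(ci) <- names(hits)
  ci$mrr <- with_seed(seed, {
    bs <- vapply(seq_len(bootstrap), function(i) {
      mean(1 / ranks[sample.int(n, n, replace = TRUE)])
    }, 0)
    unname(stats::quantile(bs, c((1 - ci_level) / 2, (1 + ci_level) / 2)))
  })
  structure(list(mrr = mrr, hits = hits, n = n, ci = ci, level = ci_level,
                 method = ci_method),
            class = "kg_eval")
}

#' Exact binomial proportion confidence interval
#'
#' Clopper-Pearson bounds via beta quantiles: lower =
#' qbeta(alpha/2; x, n-x+1) (0 when x = 0), upper =
#' qbeta(1-alpha/2; x+1, n-x) (1 when x = n). The Wilson score interval
#' is available as an alternative.
#'
#' @param x number of successes
#' @param n number of trials
#' @param level confidence level
#' @param method `"clopper-pearson"` or `"wilson"`
#' @return numeric `c(lower, upper)`
#' @export
binom_ci <- function(x, n, level = 0.90,
                     method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  stopifnot(n >= 1, x >= 0, x <= n)
  alpha <- 1 - level
  if (method == "clopper-pearson") {
    lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
    upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    p <- x / n
    den <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / den
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    lower <- max(0, centre - half)
    upper <- min(1, centre + half)
  }
  c(lower = lower, upper = upper)
}

#' @export
print.kg_eval <- function(x, ...) {
  cat(sprintf("Filtered-rank evaluation on %d queries (%.0f%% CIs, %s)\n",
              x$n, 100 * x$level, x$method))
  cat(sprintf("  MRR     %.4f  [%.4f, %.4f]\n", x$mrr,
              x$ci$mrr[1], x$ci$mrr[2]))
  for (nm in names(x$hits)) {
    cat(sprintf("  %-7s %.4f  [%.4f, %.4f]\n",
                sub("hits_at_", "Hits@", nm), x$hits[[nm]],
                x$ci[[nm]][1], x$ci[[nm]][2]))
  }
  invisible(x)
}

#' Evaluate a scoring function over held-out target triples
#'
#' Runs the filtered-rank protocol in the tail-prediction direction
#' (compound to disease): for each test triple, candidates are scored by
#' `score_fn`, every other known answer for the same compound is filtered
#' out, and the truth's rank is recorded.
#'
#' @param test data.frame of test triples (`head`, `tail`)
#' @param score_fn function(head) returning a named score vector over
#'   candidates
#' @param known data.frame of all known target triples (train + valid +
#'   test) used for filtering
#' @param ... passed to [kg_eval_summary()]
#' @return list with `records` (data.frame compound/truth/rank/
#'   reciprocal_rank) and `summary` (a `kg_eval`)
#' @export
kg_evaluate <- function(test, score_fn, known, ...) {
  stopifnot(nrow(test) > 0L)
  recs <- lapply(seq_len(nrow(test)), function(i) {
    h <- test$head[i]; tr <- test$tail[i]
    others <- setdiff(known$tail[known$head == h], tr)
    fr <- kg_filtered_rank(score_fn(h), tr, others)
    data.frame(compound = h, truth = tr, rank = fr$rank,
               reciprocal_rank = 1 / fr$rank, stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, recs)
  list(records = records, summary = kg_eval_summary(records$rank, ...))
}

#' Write per-query ranks as TSV and the metric summary as JSON
#' @param eval result of [kg_evaluate()]
#' @param ranks_path TSV path (`compound	truth	rank	reciprocal_rank`)
#' @param summary_path JSON path
#' @return invisibly, the two paths
#' @export
kg_eval_write <- function(eval, ranks_path, summary_path) {
  utils::write.table(eval$records, ranks_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  s <- eval$summary
  jsonlite::write_json(
    list(n = s$n, mrr = s$mrr, hits = as.list(s$hits),
         ci = lapply(s$ci, function(v) list(lower = v[[1]], upper = v[[2]])),
         level = s$level, method = s$method),
    summary_path, auto_unbox = TRUE, digits = NA)
  invisible(c(ranks_path, summary_path))
}
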