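# Statistical layer: comparative-Ct qPCR analysis plus the tests applied to
# counts, measurements and ranks, with explicit-family Holm correction.
# Standard tests delegate to their canonical R implementations (t.test,
# wilcox.test, glm.nb, p.adjust); this layer fixes the conventions — paired
# batches, exactness switching, NB likelihood-ratio testing — and returns a
# uniform result object.

#' Uniform test result
#'
#' @param method method name.
#' @param statistic test statistic.
#' @param df degrees of freedom (`NA` for exact tests).
#' @param p_raw raw p value.
#' @param exact logical: exact-distribution p.
#' @param family_id optional Holm-family label.
#' @param note optional diagnostic note (e.g. degenerate data flags).
#' @return An object of class `test_result`.
#' @export
test_result <- function(method, statistic, df = NA_real_, p_raw, exact = FALSE,
                        family_id = NA_character_, note = NULL) {
  if (is.finite(p_raw) && (p_raw < 0 || p_raw > 1)) stopf("p must be in [0, 1]")
  structure(list(method = method, statistic = statistic, df = df,
                 p_raw = p_raw, p_adjusted = NA_real_, exact = exact,
                 family_id = family_id, note = note),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g%s%s\n", x$method, x$statistic,
              if (is.finite(x$df)) sprintf(", df = %.3g", x$df) else "",
              x$p_raw,
              if (is.finite(x$p_adjusted)) sprintf(" (adj. %.4g)", x$p_adjusted) else "",
              if (!is.null(x$note)) paste0(" [", x$note, "]") else ""))
  invisible(x)
}

#' Long-format Ct table
#'
#' @param rows data.frame with columns `gene`, `sample_id`, `condition`
#'   (`"virgin"`/`"mated"`), `batch_id`, `ct` (cycles, `> 0`). Technical
#'   replicates are additional rows for the same (sample, gene).
#' @param housekeeping_gene reference gene name (default `"rp49"`).
#' @return An object of class `ct_table`.
#' @export
ct_table <- function(rows, housekeeping_gene = "rp49") {
  rows <- as.data.frame(rows)
  need <- c("gene", "sample_id", "condition", "batch_id", "ct")
  if (!all(need %in% names(rows)))
    stopf("ct table needs columns: %s", paste(need, collapse = ", "))
  if (any(rows$ct <= 0)) stopf("Ct values must be > 0")
  if (!all(rows$condition %in% c("virgin", "mated")))
    stopf("condition must be 'virgin' or 'mated'")
  structure(rows, housekeeping_gene = housekeeping_gene,
            class = c("ct_table", "data.frame"))
}

#' Comparative-Ct (delta-delta-Ct) analysis
#'
#' Technical replicate Cts are averaged per (sample, gene) first; per sample
#' `dCt = Ct_gene - Ct_housekeeping`; per batch
#' `ddCt = dCt_mated - dCt_virgin` (condition means within the batch) and
#' `fold = 2^(-ddCt)`. Relative expression is thus invariant to any
#' per-sample additive Ct shift applied to all genes.
#'
#' @param table a [ct_table].
#' @param gene target gene name.
#' @return A list of class `ct_analysis`: `gene`, `delta_ct` (per-sample
#'   dCt table), `per_batch` (batch, ddCt, fold), `mean_fold`.
#' @export
comparative_ct <- function(table, gene) {
  hk <- attr(table, "housekeeping_gene") %||% "rp49"
  d <- as.data.frame(table)
  if (!gene %in% d$gene) stopf("gene '%s' absent from the Ct table", gene)
  # mean over technical replicates
  agg <- stats::aggregate(ct ~ gene + sample_id + condition + batch_id,
                          data = d, FUN = mean)
  samples <- unique(agg[, c("sample_id", "condition", "batch_id")])
  dct <- vapply(seq_len(nrow(samples)), function(i) {
    sid <- samples$sample_id[i]
    g <- agg$ct[agg$sample_id == sid & agg$gene == gene]
    h <- agg$ct[agg$sample_id == sid & agg$gene == hk]
    if (!length(h)) stopf("housekeeping gene '%s' missing for sample '%s'", hk, sid)
    if (!length(g)) stopf("gene '%s' missing for sample '%s'", gene, sid)
    mean(g) - mean(h)
  }, 0)
  delta_ct <- cbind(samples, delta_ct = dct)
  per_batch <- do.call(rbind, lapply(split(delta_ct, delta_ct$batch_id), function(b) {
    if (!all(c("virgin", "mated") %in% b$condition))
      stopf("batch '%s' lacks one condition; paired analysis needs both", b$batch_id[1])
    ddct <- mean(b$delta_ct[b$condition == "mated"]) -
            mean(b$delta_ct[b$condition == "virgin"])
    data.frame(batch_id = b$batch_id[1], ddct = ddct, fold = 2^(-ddct))
  }))
  rownames(per_batch) <- NULL
  structure(list(gene = gene, housekeeping_gene = hk, delta_ct = delta_ct,
                 per_batch = per_batch, mean_fold = mean(per_batch$fold)),
            class = "ct_analysis")
}

#' @export
print.ct_analysis <- function(x, ...) {
  cat(sprintf("Comparative Ct: %s (vs %s), %d batch(es)\n", x$gene,
              x$housekeeping_gene, nrow(x$per_batch)))
  print(x$per_batch)
  cat(sprintf("mean fold change: %.4g\n", x$mean_fold))
  invisible(x)
}

#' Paired t test on within-batch differences
#'
#' Used on housekeeping-subtracted Cts of experimentally matched virgin and
#' mated samples: one-tailed when a prior reporter experiment fixes the
#' expected direction, two-tailed otherwise.
#'
#' @param x numeric vector: paired differences, or the first members of the
#'   pairs when `y` is given.
#' @param y optional second members; differences are `x - y`.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (direction of the mean difference).
#' @return A [test_result]. Zero-variance differences give an `NA` p with a
#'   `"zero-variance differences"` note.
#' @export
paired_t <- function(x, y = NULL, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) x else x - y
  if (length(d) < 2L) stopf("need >= 2 paired differences")
  if (sd(d) == 0)
    return(test_result("paired t", statistic = NA_real_, df = length(d) - 1,
                       p_raw = NA_real_, note = "zero-variance differences"))
  ht <- t.test(d, alternative = alternative)
  test_result("paired t", unname(ht$statistic), unname(ht$parameter), ht$p.value)
}

#' Welch two-sample t test
#'
#' Student's t with Welch's correction for unequal variances
#' (Welch-Satterthwaite degrees of freedom), two-tailed.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @return A [test_result]. Two zero-variance samples give a degenerate flag.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stopf("each sample needs n >= 2")
  if (sd(x) == 0 && sd(y) == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(test_result("Welch t", statistic = if (eq) 0 else Inf, df = NA_real_,
                       p_raw = if (eq) 1 else 0, note = "zero variance in both samples"))
  }
  ht <- t.test(x, y, var.equal = FALSE)
  test_result("Welch t", unname(ht$statistic), unname(ht$parameter), ht$p.value)
}

#' Mann-Whitney-Wilcoxon rank-sum test
#'
#' U is the number of (x, y) pairs with x exceeding y (ties counting 1/2).
#' The p value is exact by enumeration of the U null distribution when the
#' combined sample size is at most `exact_threshold` and there are no ties;
#' otherwise the normal approximation with mid-rank tie correction and
#' continuity correction is used.
#'
#' @param x,y numeric samples (e.g. blind intensity ranks), non-empty.
#' @param exact_threshold combined-n cutoff for the exact path (default 12).
#' @return A [test_result] with `statistic = U`.
#' @export
mann_whitney <- function(x, y, exact_threshold = 12L) {
  if (!length(x) || !length(y)) stopf("both groups must be non-empty")
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y)) <= exact_threshold && !ties
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  test_result("Mann-Whitney U", unname(ht$statistic), NA_real_, ht$p.value,
              exact = exact, note = if (ties) "ties: mid-ranks, corrected variance")
}

#' Holm step-down multiple-testing adjustment
#'
#' Adjusts a declared family of p values by the Bonferroni-Holm step-down
#' procedure (sort ascending, multiply the i-th by m - i + 1, enforce
#' monotonicity, cap at 1). Families are always declared explicitly by the
#' caller — membership is never guessed.
#'
#' @param p numeric p values in `[0, 1]`, or a list of [test_result]s.
#' @param family_id optional family label attached to the results.
#' @return Adjusted p values in the input order (or the test results with
#'   `p_adjusted` filled in).
#' @export
holm_adjust <- function(p, family_id = NA_character_) {
  if (is.list(p) && all(vapply(p, inherits, TRUE, "test_result"))) {
    adj <- p.adjust(vapply(p, function(t) t$p_raw, 0), method = "holm")
    return(mapply(function(t, a) { t$p_adjusted <- a; t$family_id <- family_id; t },
                  p, adj, SIMPLIFY = FALSE))
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p values must be in [0, 1]")
  p.adjust(p, method = "holm")
}

#' Count data for group tests
#'
#' @param rows data.frame with columns `unit_id`, `group`, `count`
#'   (non-negative integers), >= 2 groups.
#' @return An object of class `count_data`.
#' @export
count_data <- function(rows) {
  rows <- as.data.frame(rows)
  need <- c("unit_id", "group", "count")
  if (!all(need %in% names(rows)))
    stopf("count data needs columns: %s", paste(need, collapse = ", "))
  if (any(rows$count < 0) || any(rows$count != round(rows$count)))
    stopf("counts must be non-negative integers")
  structure(rows, class = c("count_data", "data.frame"))
}

#' Negative-binomial GLM with likelihood-ratio test
#'
#' Mitosis (pH3) counts are over-dispersed, so groups are compared by a
#' negative-binomial regression with log link (variance mu + mu^2/theta,
#' theta estimated by maximum likelihood) and a likelihood-ratio test of the
#' group term against the intercept-only model, with chi-square reference on
#' `groups - 1` degrees of freedom.
#'
#' @param data a [count_data] (or data.frame with `group` and `count`).
#' @return A [test_result]; convergence problems are reported in `note`.
#' @export
nb_glm_lrt <- function(data) {
  d <- as.data.frame(data)
  d$group <- factor(d$group)
  if (nlevels(d$group) < 2L) stopf("need >= 2 groups")
  if (any(table(d$group) < 2L)) stopf("each group needs >= 2 units")
  if (all(d$count == 0)) stopf("all counts are zero; the NB model is degenerate")
  notes <- character(0)
  # Per-model log-likelihood maximised over theta. glm.nb provides the ML
  # fit when its theta iteration converges; if it diverges the profile is
  # maximised directly over log(theta), and the Poisson boundary (theta ->
  # infinity) always provides a floor so that the supremum is never
  # under-estimated for one model but not the other.
  loglik_nb <- function(fml) {
    l_po <- as.numeric(logLik(stats::glm(fml, family = stats::poisson(), data = d)))
    l_nb <- tryCatch(
      as.numeric(logLik(withCallingHandlers(
        MASS::glm.nb(fml, data = d, control = stats::glm.control(maxit = 100)),
        warning = function(w) {
          notes <<- c(notes, conditionMessage(w)); invokeRestart("muffleWarning")
        }))),
      error = function(e) {
        notes <<- c(notes, "theta ML diverged; profile/Poisson supremum used")
        tryCatch(
          stats::optimize(function(lt) as.numeric(logLik(suppressWarnings(
            stats::glm(fml, family = MASS::negative.binomial(exp(lt)), data = d)))),
            c(-3, 12), maximum = TRUE)$objective,
          error = function(e2) -Inf)
      })
    max(l_po, l_nb)
  }
  stat <- 2 * (loglik_nb(count ~ group) - loglik_nb(count ~ 1))
  df <- nlevels(d$group) - 1L
  test_result("negative-binomial LRT", max(0, stat), df,
              pchisq(max(0, stat), df, lower.tail = FALSE),
              note = if (length(notes)) paste(unique(notes), collapse = "; "))
}

#' Egg-hatching fractions with group comparison
#'
#' Per-vial hatched fraction (`hatched / laid`), excluding zero-laid vials
#' with a warning, plus pairwise Welch comparisons between groups (Holm
#' adjusted when more than one comparison results).
#'
#' @param eggs_laid,eggs_hatched per-vial counts, `hatched <= laid`.
#' @param group per-vial group labels (optional; single group if missing).
#' @return A list with `fractions` (per-vial table), `group_means`, and
#'   `comparisons` (list of [test_result], possibly empty).
#' @export
hatch_fraction <- function(eggs_laid, eggs_hatched, group = NULL) {
  if (length(eggs_laid) != length(eggs_hatched)) stopf("laid/hatched lengths differ")
  if (any(eggs_hatched > eggs_laid)) stopf("hatched count exceeds laid count")
  if (any(eggs_laid < 0 | eggs_hatched < 0)) stopf("counts must be >= 0")
  group <- if (is.null(group)) rep("all", length(eggs_laid)) else as.character(group)
  keep <- eggs_laid > 0
  if (!all(keep)) warnf("excluding %d vial(s) with zero eggs laid", sum(!keep))
  d <- data.frame(group = group[keep], laid = eggs_laid[keep],
                  hatched = eggs_hatched[keep],
                  fraction = eggs_hatched[keep] / eggs_laid[keep])
  gm <- stats::aggregate(fraction ~ group, data = d, FUN = mean)
  cmp <- list()
  gs <- unique(d$group)
  if (length(gs) >= 2L) {
    pairs <- utils::combn(gs, 2L, simplify = FALSE)
    cmp <- lapply(pairs, function(pr) {
      t <- welch_t(d$fraction[d$group == pr[1]], d$fraction[d$group == pr[2]])
      t$note <- paste(pr, collapse = " vs "); t
    })
    if (length(cmp) > 1L) cmp <- holm_adjust(cmp, family_id = "hatch_fraction")
  }
  list(fractions = d, group_means = gm, comparisons = cmp)
}
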