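# Behavior matrix: scans x individuals, integer behavior code or NA when
# absent. The workhorse layout behind synchrony, dyad and kappa computations.
behavior_matrix <- function(x) {
  s <- x$scans[!is.na(x$scans$behavior), ]
  key <- paste(s$session_id, s$scan_index, sep = "\r")
  ids <- sort(unique(x$individuals$id))
  ukey <- unique(key)
  B <- matrix(NA_integer_, nrow = length(ukey), ncol = length(ids),
              dimnames = list(ukey, ids))
  B[cbind(match(key, ukey), match(s$animal_id, ids))] <- as.integer(s$behavior)
  B
}

#' Group synchrony degree of one scan
#'
#' The percentage of animals present that perform the single most common
#' behavior: `100 * max_b count(b) / group size`.
#'
#' @param scan data.frame of one scan's rows.
#' @return Percentage in (0, 100\].
#' @export
group_synchrony_degree <- function(scan) {
  if (nrow(scan) == 0L) stop("empty scan")
  beh <- scan$behavior[!is.na(scan$behavior)]
  if (length(beh) == 0L) stop("scan has no recorded behaviors")
  100 * max(table(beh)) / nrow(scan)
}

#' Group synchrony summary over all scans
#'
#' Per-scan synchrony degrees with their mean, SD and range, plus the
#' proportion of scans at or above each threshold. Threshold proportions are
#' cumulative: the proportion at the 70% threshold includes the scans at or
#' above 90% and at 100%.
#'
#' @param x a [herd_data] object.
#' @param thresholds percentages; default `c(70, 90, 100)`.
#' @return list: `degrees` (per-scan, named by scan key), `mean`, `sd`,
#'   `min`, `max`, `threshold_props` (named numeric, proportion of scans with
#'   degree >= threshold).
#' @export
group_synchrony_summary <- function(x, thresholds = c(70, 90, 100)) {
  s <- x$scans
  key <- paste(s$session_id, s$scan_index, sep = "\r")
  deg <- vapply(split(s, key), group_synchrony_degree, 0.0)
  props <- vapply(thresholds, function(th) mean(deg >= th), 0.0)
  list(degrees = deg, mean = mean(deg), sd = stats::sd(deg),
       min = min(deg), max = max(deg),
       threshold_props = stats::setNames(props, paste0(">=", thresholds)))
}

#' Fleiss' kappa from a subject-by-category count table
#'
#' Multi-rater chance-corrected agreement: with `m` raters per subject and
#' counts `n_ij` of raters assigning subject `i` to category `j`,
#' `P_i = (sum_j n_ij^2 - m) / (m (m - 1))`, the mean observed agreement is
#' `Pbar = mean(P_i)`, chance agreement `Pe = sum_j p_j^2` over the pooled
#' category shares `p_j`, and `K = (Pbar - Pe) / (1 - Pe)`.
#'
#' @param counts integer matrix, subjects in rows, categories in columns;
#'   every row must sum to the same rater count `m >= 2`.
#' @return list of class `herd_kappa`: `K`, `P_bar`, `Pe_bar`, `n_subjects`,
#'   `n_raters`, `n_categories`.
#' @export
fleiss_kappa_counts <- function(counts) {
  counts <- as.matrix(counts)
  m <- unique(rowSums(counts))
  if (length(m) != 1L) stop("all subjects must have the same number of raters")
  if (m < 2L) stop("need at least 2 raters")
  if (nrow(counts) < 2L)
    stop("need at least 2 subjects, got ", nrow(counts))
  P_i <- (rowSums(counts^2) - m) / (m * (m - 1))
  p_j <- colSums(counts) / sum(counts)
  P_bar <- mean(P_i)
  Pe <- sum(p_j^2)
  if (1 - Pe < .Machine$double.eps^0.5)
    stop("chance agreement is 1 (every assignment in one category); ",
         "kappa is undefined")
  structure(list(K = (P_bar - Pe) / (1 - Pe), P_bar = P_bar, Pe_bar = Pe,
                 n_subjects = nrow(counts), n_raters = as.integer(m),
                 n_categories = ncol(counts)),
            class = "herd_kappa")
}

#' @export
print.herd_kappa <- function(x, ...) {
  cat(sprintf("Fleiss kappa: K = %.3f (%d subjects, %d raters, %d categories; Pbar = %.3f, Pe = %.3f)\n",
              x$K, x$n_subjects, x$n_raters, x$n_categories, x$P_bar, x$Pe_bar))
  invisible(x)
}

#' Fleiss' kappa on complete scans
#'
#' Group membership fluctuates between scans, so the full kappa is not
#' computable; instead agreement is evaluated on the subset of scans where
#' every roster individual is present (subjects = complete scans, raters =
#' animals, categories = the four behaviors).
#'
#' @param x a [herd_data] object.
#' @param require_all keep only scans where every roster individual is
#'   present (default `TRUE`; there is deliberately no padding mode for
#'   incomplete scans).
#' @return A `herd_kappa` object (see [fleiss_kappa_counts()]).
#' @export
fleiss_kappa <- function(x, require_all = TRUE) {
  B <- behavior_matrix(x)
  if (require_all) B <- B[rowSums(!is.na(B)) == ncol(B), , drop = FALSE]
  if (nrow(B) < 2L)
    stop("need at least 2 complete scans for kappa, got ", nrow(B))
  counts <- t(apply(B, 1, function(r) tabulate(r, nbins = 4L)))
  colnames(counts) <- behavior_levels()
  fleiss_kappa_counts(counts)
}

#' Per-individual behavior profiles
#'
#' Each individual's proportion of observed scans spent in each behavior, in
#' the canonical order lying, standing, walking, foraging. These are the
#' `P_A` vectors entering the expected-synchrony independence null, computed
#' from all scans where the individual is present.
#'
#' @param x a [herd_data] object.
#' @return Numeric matrix, individuals in rows (ids as rownames), the four
#'   behaviors in columns; rows sum to 1.
#' @export
behavior_profiles <- function(x) {
  b <- behavior_budget(x)
  m <- as.matrix(b[, behavior_levels()])
  rownames(m) <- b$id
  m
}

#' Expected dyadic synchrony under independence
#'
#' The probability that two animals match by chance if each behaves
#' according to its own activity budget, independently of the other:
#' `sum_x P_A(x) * P_B(x)` over the four behavior categories.
#'
#' @param p_a,p_b numeric behavior-proportion vectors of equal length,
#'   each summing to 1.
#' @return Expected matching proportion in \[0, 1\].
#' @export
expected_synchrony <- function(p_a, p_b) {
  stopifnot(length(p_a) == length(p_b), all(p_a >= 0), all(p_b >= 0))
  stopifnot(abs(sum(p_a) - 1) < 1e-8, abs(sum(p_b) - 1) < 1e-8)
  sum(p_a * p_b)
}

#' Observed synchrony of one dyad
#'
#' The proportion of scans in which both animals were present and performed
#' the same behavior, over their co-presence scans.
#'
#' @param x a [herd_data] object.
#' @param pair character vector of two distinct ids.
#' @return list: `observed`, `n_co_present`.
#' @export
dyadic_observed_synchrony <- function(x, pair) {
  stopifnot(length(pair) == 2L, pair[1] != pair[2])
  B <- behavior_matrix(x)
  if (!all(pair %in% colnames(B))) stop("pair ids not observed in dataset")
  a <- B[, pair[1]]; b <- B[, pair[2]]
  co <- !is.na(a) & !is.na(b)
  if (!any(co)) stop("pair never co-present; observed synchrony undefined")
  list(observed = mean(a[co] == b[co]), n_co_present = sum(co))
}

#' Dyad table of observed and expected synchrony
#'
#' All unordered pairs of observed individuals, with co-presence counts,
#' observed synchrony, and the independence-null expectation from the
#' all-scan behavior profiles. Pairs never co-present are dropped with a
#' message.
#'
#' @param x a [herd_data] object.
#' @return data.frame: `id_a`, `id_b` (id_a < id_b), `n_co_present`,
#'   `observed`, `expected`.
#' @export
dyad_synchrony_table <- function(x) {
  B <- behavior_matrix(x)
  prof <- behavior_profiles(x)
  ids <- intersect(colnames(B), rownames(prof))
  cmb <- utils::combn(sort(ids), 2)
  res <- vector("list", ncol(cmb))
  dropped <- 0L
  for (k in seq_len(ncol(cmb))) {
    a <- B[, cmb[1, k]]; b <- B[, cmb[2, k]]
    co <- !is.na(a) & !is.na(b)
    if (!any(co)) { dropped <- dropped + 1L; next }
    res[[k]] <- data.frame(
      id_a = cmb[1, k], id_b = cmb[2, k], n_co_present = sum(co),
      observed = mean(a[co] == b[co]),
      expected = expected_synchrony(prof[cmb[1, k], ], prof[cmb[2, k], ]),
      stringsAsFactors = FALSE)
  }
  if (dropped) message(dropped, " dyad(s) never co-present; excluded")
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Paired t-test of observed versus expected dyadic synchrony
#'
#' Classical paired-samples t-test on (observed - expected) across dyads;
#' two-sided. Degrees of freedom are `n_dyads - 1`.
#'
#' @param dyads data.frame with columns `observed` and `expected`, as
#'   returned by [dyad_synchrony_table()].
#' @return list: `t`, `df`, `p`, `mean_observed`, `mean_expected`,
#'   `mean_difference`.
#' @export
observed_vs_expected_test <- function(dyads) {
  stopifnot(nrow(dyads) >= 2L)
  d <- dyads$observed - dyads$expected
  if (stats::sd(d) == 0)
    stop("zero variance of observed - expected differences; t undefined")
  tt <- stats::t.test(dyads$observed, dyads$expected, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_observed = mean(dyads$observed),
       mean_expected = mean(dyads$expected), mean_difference = mean(d))
}
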