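#' Fraction of animals foraging in one scan
#'
#' @param scan data.frame of one scan's rows (as stored in
#'   `herd_data$scans`).
#' @return Fraction in \[0, 1\]: animals foraging / animals present.
#' @export
scan_foraging_fraction <- function(scan) {
  if (nrow(scan) == 0L) stop("empty scan")
  sum(scan$behavior == "foraging", na.rm = TRUE) / nrow(scan)
}

#' Per-scan foraging fractions
#'
#' @param x a [herd_data] object.
#' @return data.frame: `session_id`, `scan_index`, `n_present`, `n_foraging`,
#'   `fraction`.
#' @export
foraging_fractions <- function(x) {
  s <- x$scans
  key <- paste(s$session_id, s$scan_index, sep = "\r")
  np <- tapply(s$animal_id, key, length)
  nf <- tapply(s$behavior == "foraging", key, function(z) sum(z, na.rm = TRUE))
  parts <- strsplit(names(np), "\r", fixed = TRUE)
  out <- data.frame(
    session_id = vapply(parts, `[`, "", 1L),
    scan_index = as.integer(vapply(parts, `[`, "", 2L)),
    n_present = as.integer(np),
    n_foraging = as.integer(nf),
    stringsAsFactors = FALSE
  )
  out$fraction <- out$n_foraging / out$n_present
  out <- out[order(out$session_id, out$scan_index), ]
  rownames(out) <- NULL
  out
}

#' Foraging-activity threshold filter, scan level
#'
#' Retains scans in which strictly less than `threshold` of the animals
#' present were foraging; scans foraging at or above the threshold are
#' excluded. The default 0.80 builds the low-foraging subset used to check
#' that synchrony results are not driven by mass grazing bouts.
#'
#' @param x a [herd_data] object.
#' @param threshold exclusive upper bound on the foraging fraction, in
#'   (0, 1\].
#' @return list: `data` (filtered [herd_data]), `n_retained`, `n_excluded`,
#'   `excluded` (data.frame of excluded scan keys with fractions).
#' @export
filter_scans <- function(x, threshold = 0.80) {
  stopifnot(threshold > 0, threshold <= 1)
  ff <- foraging_fractions(x)
  keep <- ff$fraction < threshold
  keepkey <- paste(ff$session_id, ff$scan_index, sep = "\r")[keep]
  rowkey <- paste(x$scans$session_id, x$scans$scan_index, sep = "\r")
  out <- x
  out$scans <- x$scans[rowkey %in% keepkey, , drop = FALSE]
  list(data = out, n_retained = sum(keep), n_excluded = sum(!keep),
       excluded = ff[!keep, , drop = FALSE])
}

#' Foraging-activity threshold filter, session level
#'
#' A session is retained only when all of its scans fall strictly below the
#' threshold; a single high-foraging scan removes the whole session. Used for
#' the session-level nearest-neighbour synchrony model, whose unit of
#' analysis is the session.
#'
#' @inheritParams filter_scans
#' @return list: `data` (filtered [herd_data]), `n_retained_sessions`,
#'   `n_excluded_sessions`, `retained_sessions` (character vector).
#' @export
filter_sessions <- function(x, threshold = 0.80) {
  stopifnot(threshold > 0, threshold <= 1)
  ff <- foraging_fractions(x)
  ok <- tapply(ff$fraction < threshold, ff$session_id, all)
  keep <- names(ok)[ok]
  out <- x
  out$scans <- x$scans[x$scans$session_id %in% keep, , drop = FALSE]
  list(data = out, n_retained_sessions = length(keep),
       n_excluded_sessions = sum(!ok), retained_sessions = keep)
}

#' Advisory diagnostics for choosing a foraging threshold
#'
#' Returns the moments of the per-scan foraging fractions and the
#' `mean + k * sd` offset, together with histogram bin counts, mirroring the
#' combination of a histogram inspection and a moment rule used to pick the
#' 80% cut-off. Purely advisory: no threshold is applied.
#'
#' @param x a [herd_data] object with at least two scans.
#' @param k multiplier on the standard deviation (default 0.5, i.e. half an
#'   SD above the mean; `k = 1` gives the full-SD reading).
#' @param breaks passed to [graphics::hist()] semantics via [base::cut()];
#'   default 10 equal bins on \[0, 1\].
#' @return list: `mean`, `sd`, `offset` (= mean + k*sd), `k`, `histogram`
#'   (named bin counts).
#' @export
suggest_threshold <- function(x, k = 0.5, breaks = 10) {
  f <- foraging_fractions(x)$fraction
  if (length(f) < 2L) stop("need at least two scans")
  h <- table(cut(f, breaks = seq(0, 1, length.out = breaks + 1),
                 include.lowest = TRUE))
  m <- mean(f); s <- stats::sd(f)
  list(mean = m, sd = s, offset = m + k * s, k = k,
       histogram = stats::setNames(as.integer(h), names(h)))
}
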