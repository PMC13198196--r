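#' Draw the random-conspecific control for one scan
#'
#' The control animal is sampled uniformly from the animals present in the
#' scan, excluding the focal and its three recorded nearest neighbours. The
#' draw uses the current RNG state; seed at the table level (see
#' [session_neighbor_synchrony()]) for reproducibility.
#'
#' @param scan data.frame of one scan's rows.
#' @return An id, or `NA_character_` (with a warning) when no animal is
#'   eligible.
#' @export
select_random_conspecific <- function(scan) {
  focal <- scan$focal_id[1]
  nn_ids <- scan$animal_id[!is.na(scan$nn_rank)]
  eligible <- setdiff(scan$animal_id, c(focal, nn_ids))
  if (length(eligible) == 0L) {
    warning("no eligible animal for random conspecific in scan (",
            scan$session_id[1], ", ", scan$scan_index[1], ")")
    return(NA_character_)
  }
  eligible[sample.int(length(eligible), 1L)]
}

#' Session-level synchrony with neighbours and the random conspecific
#'
#' For every session and every neighbour type (NN1, NN2, NN3, random
#' conspecific), the proportion of that session's scans in which the animal
#' of that type performed the same behavior as the focal. Neighbour
#' identities may change between scans; the type, not the identity, is the
#' unit. A scan is valid for a type only when an animal of that type exists
#' in it.
#'
#' @param x a [herd_data] object.
#' @param seed optional integer seed for the random-conspecific draws.
#' @return data.frame: `session_id`, `focal_id`, `hour`, `type` (factor with
#'   reference level `random_conspecific`), `n_valid`, `n_sync`, `prop`.
#'   Session-type combinations with zero valid scans are omitted.
#' @export
session_neighbor_synchrony <- function(x, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- x$scans
  key <- paste(s$session_id, s$scan_index, sep = "\r")
  out <- list()
  for (scan in split(s, key)) {
    focal <- scan$focal_id[1]
    fb <- scan$behavior[scan$animal_id == focal]
    if (length(fb) != 1L || is.na(fb)) next
    ids <- c(NN1 = scan$animal_id[match(1L, scan$nn_rank)],
             NN2 = scan$animal_id[match(2L, scan$nn_rank)],
             NN3 = scan$animal_id[match(3L, scan$nn_rank)],
             random_conspecific = suppressWarnings(select_random_conspecific(scan)))
    for (ty in names(ids)) {
      if (is.na(ids[[ty]])) next
      tb <- scan$behavior[scan$animal_id == ids[[ty]]]
      if (length(tb) != 1L || is.na(tb)) next
      out[[length(out) + 1L]] <- data.frame(
        session_id = scan$session_id[1], focal_id = focal,
        hour = scan$hour[1], type = ty, sync = as.integer(tb == fb),
        stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, out)
  agg <- stats::aggregate(sync ~ session_id + focal_id + type, data = long,
                          FUN = function(z) c(n = length(z), s = sum(z)))
  hours <- stats::aggregate(hour ~ session_id, data = long, FUN = function(h) h[1])
  res <- data.frame(
    session_id = agg$session_id, focal_id = agg$focal_id,
    hour = hours$hour[match(agg$session_id, hours$session_id)],
    type = factor(agg$type, levels = c("random_conspecific", "NN1", "NN2", "NN3")),
    n_valid = as.integer(agg$sync[, "n"]), n_sync = as.integer(agg$sync[, "s"]),
    stringsAsFactors = FALSE)
  res$prop <- res$n_sync / res$n_valid
  res <- res[order(res$session_id, res$type), ]
  rownames(res) <- NULL
  res
}

#' Scan-level focal/NN1 synchrony table
#'
#' One record per scan pairing the focal animal with its first nearest
#' neighbour: whether the two were synchronized, the dyad's sex combination,
#' binary affiliation, absolute dominance-rank difference, the neighbour's
#' distance category and the hour of observation. This is the input to the
#' scan-level binomial GLMM.
#'
#' @param x a [herd_data] object.
#' @param affiliation symmetric binary matrix over ids
#'   (see [build_affiliation()]).
#' @param ranks named integer vector of ordinal dominance ranks
#'   (1 = most dominant).
#' @return data.frame: `session_id`, `scan_index`, `focal_id`, `nn1_id`,
#'   `synchronized` (0/1), `sex_combo` (`same`/`different`), `affiliation`
#'   (0/1), `rank_diff`, `distance`, `hour`. Scans without an NN1 or with an
#'   unrecorded behavior are skipped; the count is in attribute `n_skipped`.
#' @export
nn_scan_table <- function(x, affiliation, ranks) {
  s <- x$scans
  key <- paste(s$session_id, s$scan_index, sep = "\r")
  sex <- stats::setNames(x$individuals$sex, x$individuals$id)
  out <- list(); skipped <- 0L
  for (scan in split(s, key)) {
    focal <- scan$focal_id[1]
    i <- match(1L, scan$nn_rank)
    fb <- scan$behavior[scan$animal_id == focal]
    if (is.na(i) || length(fb) != 1L || is.na(fb) || is.na(scan$behavior[i])) {
      skipped <- skipped + 1L; next
    }
    nn1 <- scan$animal_id[i]
    out[[length(out) + 1L]] <- data.frame(
      session_id = scan$session_id[1], scan_index = scan$scan_index[1],
      focal_id = focal, nn1_id = nn1,
      synchronized = as.integer(scan$behavior[i] == fb),
      sex_combo = ifelse(sex[[focal]] == sex[[nn1]], "same", "different"),
      affiliation = affiliation[focal, nn1],
      rank_diff = abs(ranks[[focal]] - ranks[[nn1]]),
      distance = as.character(scan$distance_to_focal[i]),
      hour = scan$hour[1], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_skipped") <- skipped
  res
}

#' Dyadic proximity likelihood
#'
#' For each unordered pair, the number of scans in which the non-focal
#' member was recorded within three body lengths of the focal member
#' (the within-1-BL category nests inside within-3-BL), divided by the
#' number of scans in which both were present and one of them was the
#' focal. Pairs with a zero denominator are omitted.
#'
#' @param x a [herd_data] object.
#' @return data.frame: `id_a`, `id_b` (id_a < id_b), `n_focal_scans`,
#'   `n_close`, `proximity`.
#' @export
proximity_likelihood_table <- function(x) {
  s <- x$scans
  num <- list(); den <- list()
  foc <- s[s$animal_id != s$focal_id, ]
  pair_a <- pmin(foc$focal_id, foc$animal_id)
  pair_b <- pmax(foc$focal_id, foc$animal_id)
  key <- paste(pair_a, pair_b, sep = "\r")
  close <- foc$distance_to_focal %in% c("within_1BL", "within_3BL")
  n_den <- tapply(rep(1L, nrow(foc)), key, sum)
  n_num <- tapply(close, key, sum)
  parts <- strsplit(names(n_den), "\r", fixed = TRUE)
  out <- data.frame(
    id_a = vapply(parts, `[`, "", 1L), id_b = vapply(parts, `[`, "", 2L),
    n_focal_scans = as.integer(n_den), n_close = as.integer(n_num),
    stringsAsFactors = FALSE)
  out$proximity <- out$n_close / out$n_focal_scans
  out <- out[order(out$id_a, out$id_b), ]
  rownames(out) <- NULL
  out
}

#' Proximity likelihood for a single pair
#'
#' @inheritParams dyadic_observed_synchrony
#' @return Proportion in \[0, 1\].
#' @seealso [proximity_likelihood_table()]
#' @export
dyadic_proximity_likelihood <- function(x, pair) {
  stopifnot(length(pair) == 2L, pair[1] != pair[2])
  tab <- proximity_likelihood_table(x)
  row <- tab[tab$id_a == min(pair) & tab$id_b == max(pair), ]
  if (nrow(row) == 0L)
    stop("pair never co-present with one member as focal; undefined")
  row$proximity
}
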