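#' Read social-interaction events from CSV
#'
#' @param path CSV with header and columns `timestamp`, `actor`, `recipient`,
#'   `kind` (`allogrooming` or `displacement`; for displacements the actor is
#'   the winner and the recipient the loser).
#' @return data.frame with those columns, kinds validated.
#' @export
read_interactions <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "actor", "recipient", "kind")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("interaction file missing columns: ",
                         paste(miss, collapse = ", "))
  raw$kind <- tolower(trimws(raw$kind))
  bad <- which(!raw$kind %in% c("allogrooming", "displacement"))
  if (length(bad)) stop("unknown interaction kind at rows ",
                        paste(utils::head(bad, 5), collapse = ", "))
  if (any(raw$actor == raw$recipient))
    stop("self-directed interaction (actor == recipient) at rows ",
         paste(utils::head(which(raw$actor == raw$recipient), 5), collapse = ", "))
  raw
}

#' Binary affiliation matrix from allogrooming events
#'
#' Affiliation is a binary, direction-free dyadic measure: 1 when the pair
#' has exchanged allogrooming at least once (in either direction), else 0.
#'
#' @param records interaction data.frame (see [read_interactions()]); only
#'   rows with `kind == "allogrooming"` are used.
#' @param roster character vector of ids.
#' @return Symmetric 0/1 matrix with zero diagonal, ids as dimnames.
#' @export
build_affiliation <- function(records, roster) {
  g <- records[records$kind == "allogrooming", , drop = FALSE]
  unknown <- setdiff(unique(c(g$actor, g$recipient)), roster)
  if (length(unknown)) stop("interaction ids absent from roster: ",
                            paste(unknown, collapse = ", "))
  A <- matrix(0L, length(roster), length(roster), dimnames = list(roster, roster))
  if (nrow(g)) {
    A[cbind(g$actor, g$recipient)] <- 1L
    A <- pmax(A, t(A))
  }
  diag(A) <- 0L
  A
}

#' Winner-loser count matrix from displacement events
#'
#' @inheritParams build_affiliation
#' @return Integer matrix `W` with `W[i, j]` = number of times `i` displaced
#'   `j`; zero diagonal.
#' @export
build_winner_loser <- function(records, roster) {
  d <- records[records$kind == "displacement", , drop = FALSE]
  unknown <- setdiff(unique(c(d$actor, d$recipient)), roster)
  if (length(unknown)) stop("interaction ids absent from roster: ",
                            paste(unknown, collapse = ", "))
  W <- matrix(0L, length(roster), length(roster), dimnames = list(roster, roster))
  if (nrow(d)) {
    tab <- table(factor(d$actor, roster), factor(d$recipient, roster))
    W <- W + unclass(tab)
  }
  diag(W) <- 0L
  storage.mode(W) <- "integer"
  W
}

# One sequential Elo pass over a winner/loser event sequence.
# `winner`/`loser` are integer indices into the roster for speed.
elo_sequence_idx <- function(winner, loser, n, k_factor, init) {
  r <- rep(init, n)
  for (e in seq_along(winner)) {
    w <- winner[e]; l <- loser[e]
    delta <- k_factor * (1 - 1 / (1 + 10^((r[l] - r[w]) / 400)))
    r[w] <- r[w] + delta
    r[l] <- r[l] - delta
  }
  r
}

elo_sequence <- function(winner, loser, roster, k_factor, init) {
  stats::setNames(elo_sequence_idx(match(winner, roster), match(loser, roster),
                                   length(roster), k_factor, init), roster)
}

#' Randomized Elo dominance scores and ordinal ranks
#'
#' Sequential Elo ratings depend on interaction order; scan-era dominance
#' data has no meaningful order, so the method shuffles the event sequence
#' uniformly `n_rand` times, runs the sequential updates each time
#' (expected win probability `1 / (1 + 10^((R_loser - R_winner)/400))`,
#' winner gains and loser loses `K * (1 - E_w)`), and averages the final
#' scores. Ordinal ranks 1..N are assigned by descending mean score
#' (1 = most dominant); ties are broken lexicographically by id and flagged.
#'
#' @param interactions either an interaction data.frame (rows with
#'   `kind == "displacement"` are used; actor = winner) or a winner-loser
#'   count matrix from [build_winner_loser()].
#' @param roster character vector of ids; individuals without interactions
#'   keep the initial score.
#' @param n_rand number of order randomizations (default 10000).
#' @param k_factor Elo K (default 200).
#' @param init initial score (default 1000).
#' @param seed optional integer seed.
#' @return list of class `herd_dominance`: `scores` (data.frame `id`,
#'   `score`, `rank`), `n_randomizations`, `k_factor`, `initial_score`,
#'   `tied` (ids involved in mean-score ties).
#' @export
randomized_elo <- function(interactions, roster, n_rand = 10000,
                           k_factor = 200, init = 1000, seed = NULL) {
  if (n_rand < 1) stop("n_rand must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.matrix(interactions)) {
    W <- interactions
    idx <- which(W > 0, arr.ind = TRUE)
    winner <- rep(rownames(W)[idx[, 1]], W[idx])
    loser <- rep(colnames(W)[idx[, 2]], W[idx])
  } else {
    d <- interactions[interactions$kind == "displacement", , drop = FALSE]
    winner <- d$actor; loser <- d$recipient
  }
  if (length(winner) == 0L) stop("no displacement interactions supplied")
  unknown <- setdiff(unique(c(winner, loser)), roster)
  if (length(unknown)) stop("interaction ids absent from roster: ",
                            paste(unknown, collapse = ", "))
  wi <- match(winner, roster); li <- match(loser, roster)
  acc <- numeric(length(roster))
  n_ev <- length(winner)
  for (b in seq_len(n_rand)) {
    perm <- sample.int(n_ev)
    acc <- acc + elo_sequence_idx(wi[perm], li[perm], length(roster),
                                  k_factor, init)
  }
  mean_score <- stats::setNames(acc / n_rand, roster)
  ord <- order(-mean_score, roster)
  rank <- integer(length(roster)); rank[ord] <- seq_along(roster)
  tied <- roster[mean_score %in% mean_score[duplicated(mean_score)]]
  structure(list(
    scores = data.frame(id = roster, score = unname(mean_score),
                        rank = rank, stringsAsFactors = FALSE),
    n_randomizations = n_rand, k_factor = k_factor, initial_score = init,
    tied = tied), class = "herd_dominance")
}

#' @export
print.herd_dominance <- function(x, ...) {
  cat("<herd_dominance> randomized Elo, ", x$n_randomizations,
      " randomizations (K = ", x$k_factor, ", init = ", x$initial_score, ")\n",
      sep = "")
  print(x$scores[order(x$scores$rank), ], row.names = FALSE)
  if (length(x$tied)) cat("ties on mean score:", paste(x$tied, collapse = ", "), "\n")
  invisible(x)
}

#' Ordinal ranks as a named vector
#'
#' @param dom a `herd_dominance` object.
#' @return Named integer vector of ranks, 1 = most dominant.
#' @export
dominance_ranks <- function(dom) {
  stats::setNames(dom$scores$rank, dom$scores$id)
}

#' Dyadic covariates: sex combination, affiliation, rank difference
#'
#' @param individuals roster data.frame (`id`, `sex`).
#' @param ranks named integer vector of ordinal ranks.
#' @param affiliation symmetric binary matrix over ids.
#' @return data.frame, one row per unordered pair (`id_a < id_b`):
#'   `sex_combo` (`same`/`different`), `affiliation` (0/1),
#'   `rank_diff` (absolute ordinal difference).
#' @export
dyad_covariates <- function(individuals, ranks, affiliation) {
  ids <- sort(individuals$id)
  sex <- stats::setNames(individuals$sex, individuals$id)
  cmb <- utils::combn(ids, 2)
  data.frame(
    id_a = cmb[1, ], id_b = cmb[2, ],
    sex_combo = ifelse(sex[cmb[1, ]] == sex[cmb[2, ]], "same", "different"),
    affiliation = affiliation[cbind(cmb[1, ], cmb[2, ])],
    rank_diff = abs(ranks[cmb[1, ]] - ranks[cmb[2, ]]),
    stringsAsFactors = FALSE, row.names = NULL)
}
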