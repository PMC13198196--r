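# Shared generators and oracles used by the model unit tests and the
# acceptance calibrations. These generate each model's own input table
# directly (reduced size) so the 500-replicate calibrations stay cheap.

# independent pairwise-agreement brute force for Fleiss kappa
brute_fleiss <- function(counts) {
  m <- sum(counts[1, ])
  P_i <- apply(counts, 1, function(r) {
    sum(vapply(r, function(k) choose(k, 2), 0.0)) / choose(m, 2)
  })
  p_j <- colSums(counts) / sum(counts)
  (mean(P_i) - sum(p_j^2)) / (1 - sum(p_j^2))
}

# activity-budget table at the study's n = 17 with a configurable rank effect
gen_budget <- function(n = 17, beta_rank = 0, seed = 1) {
  set.seed(seed)
  n_f <- round(n * 13 / 17)   # keep the study's sex ratio
  rank <- sample.int(n)
  mu <- stats::plogis(stats::qlogis(0.62) + beta_rank * (rank - mean(rank)))
  phi <- 60
  y <- stats::rbeta(n, mu * phi, (1 - mu) * phi)
  list(budget = data.frame(id = sprintf("C%02d", 1:n),
                           sex = c(rep("female", n_f), rep("male", n - n_f)),
                           n_obs = 400, lying = (1 - y) / 3,
                           standing = (1 - y) / 3, walking = (1 - y) / 3,
                           foraging = y, stringsAsFactors = FALSE),
       ranks = stats::setNames(rank, sprintf("C%02d", 1:n)))
}

# dyad table with crossed member effects and a configurable rank_diff slope
gen_dyads <- function(n_animals = 10, effect_rank = 0, seed = 1) {
  set.seed(seed)
  ids <- sprintf("C%02d", 1:n_animals)
  sex <- sample(rep(c("female", "male"), length.out = n_animals))
  u <- stats::setNames(stats::rnorm(n_animals, 0, 0.02), ids)
  cmb <- utils::combn(ids, 2)
  rank <- stats::setNames(sample.int(n_animals), ids)
  rd <- abs(rank[cmb[1, ]] - rank[cmb[2, ]])
  data.frame(id_a = cmb[1, ], id_b = cmb[2, ],
             sex_combo = ifelse(sex[match(cmb[1, ], ids)] ==
                                  sex[match(cmb[2, ], ids)], "same", "different"),
             affiliation = stats::rbinom(ncol(cmb), 1, 0.3),
             rank_diff = as.numeric(rd),
             observed = 0.6 + u[cmb[1, ]] + u[cmb[2, ]] +
               effect_rank * rd + stats::rnorm(ncol(cmb), 0, 0.05),
             stringsAsFactors = FALSE, row.names = NULL)
}

# session x neighbour-type table with no type effect (null for model ii)
gen_neighbor_null <- function(n_sessions = 40, seed = 1) {
  set.seed(seed)
  ids <- sprintf("C%02d", 1:17)
  u <- stats::setNames(stats::rnorm(17, 0, 0.3), ids)
  hrs <- 9:17
  v <- stats::setNames(stats::rnorm(9, 0, 0.2), hrs)
  focal <- sample(ids, n_sessions, replace = TRUE)
  hour <- sample(hrs, n_sessions, replace = TRUE)
  tab <- expand.grid(session = seq_len(n_sessions),
                     type = c("random_conspecific", "NN1", "NN2", "NN3"),
                     stringsAsFactors = FALSE)
  p <- stats::plogis(stats::qlogis(0.65) + u[focal[tab$session]] +
                       v[as.character(hour[tab$session])])
  data.frame(session_id = sprintf("S%03d", tab$session),
             focal_id = focal[tab$session], hour = hour[tab$session],
             type = factor(tab$type,
                           c("random_conspecific", "NN1", "NN2", "NN3")),
             n_valid = 4L, n_sync = stats::rbinom(nrow(tab), 4, p),
             stringsAsFactors = FALSE)
}

# scan-level NN1 table with no fixed effects (null for model iii-scan)
gen_nn_scan_null <- function(n_scans = 160, seed = 1) {
  set.seed(seed)
  ids <- sprintf("C%02d", 1:12)
  sex <- stats::setNames(rep(c("female", "male"), c(9, 3)), ids)
  rank <- stats::setNames(sample.int(12), ids)
  u <- stats::setNames(stats::rnorm(12, 0, 0.4), ids)
  focal <- sample(ids, n_scans, replace = TRUE)
  nn1 <- vapply(focal, function(f) sample(setdiff(ids, f), 1), "")
  p <- stats::plogis(0.5 + u[focal] + u[nn1])
  data.frame(session_id = sprintf("S%03d", seq_len(n_scans)), scan_index = 1L,
             focal_id = focal, nn1_id = nn1,
             synchronized = stats::rbinom(n_scans, 1, p),
             sex_combo = ifelse(sex[focal] == sex[nn1], "same", "different"),
             affiliation = stats::rbinom(n_scans, 1, 0.3),
             rank_diff = abs(rank[focal] - rank[nn1]),
             distance = sample(distance_levels(), n_scans, replace = TRUE),
             hour = sample(9:17, n_scans, replace = TRUE),
             stringsAsFactors = FALSE, row.names = NULL)
}
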