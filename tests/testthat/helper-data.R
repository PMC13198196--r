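# Hand-built five-animal dataset used across the unit tests.
#
# Roster: A, B, C female; D, E male. Two sessions of four scans; focal A in
# S1 (hour 9), focal B in S2 (hour 10). Every animal present in every scan,
# NN ranks and distances assigned by hand.
tiny_scan <- function(session, idx, date, hour, focal, ids, beh, dist, nn) {
  data.frame(session_id = session, scan_index = idx, date = as.Date(date),
             hour = hour, focal_id = focal, animal_id = ids, behavior = beh,
             distance_to_focal = dist, nn_rank = nn, stringsAsFactors = FALSE)
}

tiny_data <- function() {
  ids <- c("A", "B", "C", "D", "E")
  roster <- data.frame(id = ids, sex = c("female", "female", "female",
                                         "male", "male"),
                       stringsAsFactors = FALSE)
  d1 <- "2023-03-13"; d2 <- "2023-03-14"
  F <- "foraging"; L <- "lying"; S <- "standing"; W <- "walking"
  n3 <- c(NA, 1L, 2L, 3L, NA)
  dst <- c(NA, "within_1BL", "within_3BL", "within_3BL", "over_3BL")
  scans <- rbind(
    tiny_scan("S1", 1, d1, 9, "A", ids, c(F, F, F, F, F), dst, n3),
    tiny_scan("S1", 2, d1, 9, "A", ids, c(F, F, F, L, L), dst, n3),
    tiny_scan("S1", 3, d1, 9, "A", ids, c(L, L, S, L, L), dst, n3),
    tiny_scan("S1", 4, d1, 9, "A", ids, c(W, S, S, W, F), dst, n3),
    tiny_scan("S2", 1, d2, 10, "B", ids[c(2, 1, 3, 4, 5)],
              c(F, F, F, F, W), dst, n3),
    tiny_scan("S2", 2, d2, 10, "B", ids[c(2, 1, 3, 4, 5)],
              c(S, S, S, S, S), dst, n3),
    tiny_scan("S2", 3, d2, 10, "B", ids[c(2, 1, 3, 4, 5)],
              c(F, F, L, F, F), dst, n3),
    tiny_scan("S2", 4, d2, 10, "B", ids[c(2, 1, 3, 4, 5)],
              c(L, F, L, W, S), dst, n3))
  herd_data(roster, scans)
}

# CSV round-trip fixture on disk
tiny_csv <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "scans.csv")
  write_scans(tiny_data(), path)
  path
}

tiny_interactions <- function() {
  data.frame(
    timestamp = "2022-10-01 12:00",
    actor = c("A", "B", "A", "A", "B", "D"),
    recipient = c("B", "A", "C", "B", "C", "E"),
    kind = c("allogrooming", "allogrooming", "allogrooming",
             "displacement", "displacement", "displacement"),
    stringsAsFactors = FALSE)
}

small_config <- function(seed = 1, n_sessions = 30, ...) {
  sim_config(seed = seed, n_sessions = n_sessions, ...)
}
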