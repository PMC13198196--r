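test_that("CSV round-trip preserves every record and value", {
  x <- tiny_data()
  path <- tiny_csv()
  y <- read_scans(path)
  expect_equal(nrow(y$scans), nrow(x$scans))  # 2 sessions x 4 scans x 5 animals
  expect_equal(nrow(y$scans), 40L)
  for (col in c("session_id", "scan_index", "focal_id", "animal_id"))
    expect_equal(y$scans[[col]], x$scans[[col]])
  expect_equal(as.character(y$scans$behavior), as.character(x$scans$behavior))
  expect_equal(y$scans$nn_rank, x$scans$nn_rank)
  expect_equal(y$scans$hour, x$scans$hour)
  expect_setequal(y$individuals$id, x$individuals$id)
  # second round trip is byte-stable
  path2 <- file.path(withr::local_tempdir(), "again.csv")
  write_scans(y, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("read_scans enforces the closed behavior vocabulary", {
  path <- tiny_csv()
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  raw$behavior[3] <- "grazing"
  bad <- file.path(withr::local_tempdir(), "bad.csv")
  utils::write.csv(raw, bad, row.names = FALSE, na = "")
  err <- expect_error(read_scans(bad), "grazing")
  for (lbl in behavior_levels()) expect_match(conditionMessage(err), lbl)
  # case-insensitive matching of valid labels
  raw2 <- utils::read.csv(path, stringsAsFactors = FALSE)
  raw2$behavior <- toupper(raw2$behavior)
  up <- file.path(withr::local_tempdir(), "upper.csv")
  utils::write.csv(raw2, up, row.names = FALSE, na = "")
  expect_s3_class(read_scans(up), "herd_data")
})

test_that("read_scans rejects duplicates and out-of-range nn_rank", {
  path <- tiny_csv()
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  dir <- withr::local_tempdir()
  dup <- rbind(raw, raw[7, ])
  f1 <- file.path(dir, "dup.csv")
  utils::write.csv(dup, f1, row.names = FALSE, na = "")
  expect_error(read_scans(f1), "duplicate record")
  raw$nn_rank[2] <- 4
  f2 <- file.path(dir, "nn.csv")
  utils::write.csv(raw, f2, row.names = FALSE, na = "")
  expect_error(read_scans(f2), "nn_rank")
})

test_that("validate_scans reports the spec'd violation kinds", {
  x <- tiny_data()
  expect_true(validate_scans(x)$ok)

  # remove the focal row of one scan
  y <- x
  y$scans <- y$scans[!(y$scans$session_id == "S1" & y$scans$scan_index == 1 &
                         y$scans$animal_id == "A"), ]
  v <- validate_scans(y)
  expect_false(v$ok)
  expect_equal(v$violations$kind, "missing_focal")

  # duplicate nn_rank
  z <- x
  z$scans$nn_rank[z$scans$session_id == "S1" & z$scans$scan_index == 2 &
                    z$scans$animal_id == "C"] <- 1L
  v2 <- validate_scans(z)
  expect_true("duplicate_nn" %in% v2$violations$kind)

  # focal carrying a distance
  w <- x
  w$scans$distance_to_focal[w$scans$session_id == "S1" &
                              w$scans$scan_index == 3 &
                              w$scans$animal_id == "A"] <- "within_1BL"
  expect_true("focal_nonnull_distance" %in% validate_scans(w)$violations$kind)
})

test_that("group_size_summary computes per-scan distinct-animal counts", {
  x <- tiny_data()
  gs <- group_size_summary(x)
  expect_equal(gs$mean, 5)
  expect_equal(gs$sd, 0)
  expect_equal(gs$n_scans, 8L)

  # drop two animals from one scan -> sizes {3, 5 x7}
  y <- x
  y$scans <- y$scans[!(y$scans$session_id == "S2" & y$scans$scan_index == 4 &
                         y$scans$animal_id %in% c("D", "E")), ]
  gs2 <- group_size_summary(y)
  expect_equal(gs2$min, 3L)
  expect_equal(gs2$max, 5L)
  expect_equal(gs2$mean, mean(c(rep(5, 7), 3)))

  empty <- x
  empty$scans <- empty$scans[0, ]
  expect_error(group_size_summary(empty), "no scans")
})

test_that("behavior_budget rows sum to 1 and match hand counts", {
  x <- tiny_data()
  b <- behavior_budget(x)
  expect_equal(nrow(b), 5L)
  sums <- rowSums(b[, behavior_levels()])
  expect_true(all(abs(sums - 1) < 1e-12))
  # animal A over 8 scans: F,F,L,W | F,S,F,F -> 5 foraging, 1 lying, 1 standing, 1 walking
  a <- b[b$id == "A", ]
  expect_equal(a$foraging, 5 / 8)
  expect_equal(a$lying, 1 / 8)
  # scan-level conservation: behavior counts sum to group size
  tab <- table(x$scans$session_id, x$scans$scan_index)
  expect_true(all(tab == 5))
})

test_that("unobserved roster individuals are excluded with a warning", {
  x <- tiny_data()
  x$individuals <- rbind(x$individuals,
                         data.frame(id = "Z", sex = "female"))
  expect_warning(b <- behavior_budget(x), "Z")
  expect_false("Z" %in% b$id)
})

test_that("herd_data rejects unknown ids and bad rosters", {
  x <- tiny_data()
  bad <- x$scans
  bad$animal_id[1] <- "QQ"
  expect_error(herd_data(x$individuals, bad), "QQ")
  roster <- x$individuals
  roster$id[2] <- roster$id[1]
  expect_error(herd_data(roster, x$scans), "duplicate")
})

test_that("incomplete sessions are flagged and droppable", {
  x <- tiny_data()
  x$scans$behavior[x$scans$session_id == "S2" & x$scans$scan_index == 2 &
                     x$scans$animal_id == "E"] <- NA
  v <- validate_scans(x)
  expect_true("incomplete_behavior" %in% v$violations$kind)
  expect_message(y <- drop_incomplete_sessions(x), "1 session")
  expect_setequal(unique(y$scans$session_id), "S1")
})
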