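test_that("random conspecific excludes focal and NN1-3, is uniform and seeded", {
  x <- tiny_data()
  # add two extra eligible animals to one scan
  roster <- rbind(x$individuals, data.frame(id = c("F", "G"),
                                            sex = c("female", "male")))
  extra <- x$scans[x$scans$session_id == "S1" & x$scans$scan_index == 1, ][1:2, ]
  extra$animal_id <- c("F", "G")
  extra$behavior <- factor("lying", behavior_levels())
  extra$distance_to_focal <- factor("over_3BL", distance_levels())
  extra$nn_rank <- NA_integer_
  y <- herd_data(roster, rbind(x$scans, extra))
  scan <- y$scans[y$scans$session_id == "S1" & y$scans$scan_index == 1, ]
  # eligible = {E, F, G}: focal A and NN1-3 (B, C, D) excluded
  set.seed(1)
  draws <- replicate(9000, select_random_conspecific(scan))
  expect_setequal(unique(draws), c("E", "F", "G"))
  tab <- table(draws)
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)         # uniform over eligible
  expect_true(all(abs(tab / 9000 - 1 / 3) < 0.02))
  # determinism under a seed
  set.seed(99); a <- select_random_conspecific(scan)
  set.seed(99); b <- select_random_conspecific(scan)
  expect_identical(a, b)
  # four-animal scan: focal + 3 neighbours leaves nobody
  s4 <- x$scans[x$scans$session_id == "S1" & x$scans$scan_index == 1 &
                  x$scans$animal_id != "E", ]
  expect_warning(rc <- select_random_conspecific(s4), "no eligible")
  expect_true(is.na(rc))
})

test_that("session neighbour synchrony proportions match hand counts", {
  x <- tiny_data()
  nt <- session_neighbor_synchrony(x, seed = 4)
  # S1 focal A, NN1 = B: behaviors A: F,F,L,W vs B: F,F,L,S -> 3/4
  s1 <- nt[nt$session_id == "S1", ]
  expect_equal(s1$prop[s1$type == "NN1"], 3 / 4)
  # S1 NN2 = C: A vs C: F/F, F/F, L/S, W/S -> 2/4
  expect_equal(s1$prop[s1$type == "NN2"], 2 / 4)
  # S1 NN3 = D: F/F, F/L, L/L, W/W -> 3/4
  expect_equal(s1$prop[s1$type == "NN3"], 3 / 4)
  # random conspecific in the 5-animal scans is always E
  # S1 focal A vs E: F/F, F/L, L/L, W/F -> 2/4
  expect_equal(s1$prop[s1$type == "random_conspecific"], 2 / 4)
  expect_true(all(nt$n_valid == 4L))
  expect_true(all(nt$prop %in% c(0, .25, .5, .75, 1)))
})

test_that("nn_scan_table produces one record per usable scan with covariates", {
  x <- tiny_data()
  aff <- build_affiliation(tiny_interactions(), x$individuals$id)
  ranks <- stats::setNames(1:5, c("A", "B", "C", "D", "E"))
  tab <- nn_scan_table(x, aff, ranks)
  expect_equal(nrow(tab), 8L)
  expect_equal(attr(tab, "n_skipped"), 0L)
  # S1: focal A (female), NN1 B (female) -> same sex, affiliated, rank_diff 1
  r <- tab[tab$session_id == "S1" & tab$scan_index == 1, ]
  expect_equal(r$sex_combo, "same")
  expect_equal(r$affiliation, 1L)
  expect_equal(r$rank_diff, 1)
  expect_equal(r$distance, "within_1BL")
  # S2: focal B, NN1 A -> synchronized flags: F/F, S/S, F/F, L/F -> 1,1,1,0
  s2 <- tab[tab$session_id == "S2", ]
  expect_equal(s2$synchronized[order(s2$scan_index)], c(1L, 1L, 1L, 0L))
  # scan without NN1 is skipped and counted
  y <- x
  y$scans$nn_rank[y$scans$session_id == "S1" & y$scans$scan_index == 1] <- NA
  tab2 <- nn_scan_table(y, aff, ranks)
  expect_equal(nrow(tab2), 7L)
  expect_equal(attr(tab2, "n_skipped"), 1L)
})

test_that("proximity likelihood counts nested distance categories", {
  x <- tiny_data()
  pt <- proximity_likelihood_table(x)
  # A-B: S1 B is NN1 within_1BL (4 scans), S2 A within_1BL (4 scans) -> 8/8
  ab <- pt[pt$id_a == "A" & pt$id_b == "B", ]
  expect_equal(ab$n_focal_scans, 8L)
  expect_equal(ab$proximity, 1.0)
  # A-E / B-E: E always over_3BL -> 0
  ae <- pt[pt$id_a == "A" & pt$id_b == "E", ]
  expect_equal(ae$proximity, 0.0)
  # within_1BL nests inside the 3-BL definition
  expect_equal(dyadic_proximity_likelihood(x, c("B", "A")), 1.0)
  # C-D are never focal with each other present-as-focal pairing? they are:
  # C and D both present in all scans but neither is ever focal -> no rows
  expect_false(any(pt$id_a == "C" & pt$id_b == "D"))
  expect_error(dyadic_proximity_likelihood(x, c("C", "D")), "undefined")
})

test_that("proximity coupling produces the NN gradient in the simulator", {
  sim <- simulate_herd(sim_config(seed = 21, w_sex = 0, w_aff = 0,
                                  beta_rank = 0, n_sessions = 200))
  nt <- session_neighbor_synchrony(sim$data, seed = 21)
  m <- tapply(nt$prop, nt$type, mean)
  expect_gt(m[["NN1"]], m[["NN2"]])
  expect_gt(m[["NN2"]], m[["NN3"]] - 0.02)   # adjacent gap within MC error
  expect_gt(m[["NN3"]], m[["random_conspecific"]])
  expect_gt(m[["NN1"]], m[["random_conspecific"]] + 0.05)
})
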