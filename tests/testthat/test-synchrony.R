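test_that("group synchrony degree is the modal-behavior percentage", {
  mk <- function(beh) data.frame(
    session_id = "S", scan_index = 1L, focal_id = "a1", animal_id = paste0("a", seq_along(beh)),
    behavior = factor(beh, behavior_levels()), stringsAsFactors = FALSE)
  expect_equal(group_synchrony_degree(mk(c(rep("foraging", 6), "lying", "standing"))), 75)
  expect_equal(group_synchrony_degree(mk(rep("lying", 12))), 100)
  expect_equal(group_synchrony_degree(mk(behavior_levels())), 25)
  expect_error(group_synchrony_degree(mk("lying")[0, ]), "empty")
})

test_that("group synchrony summary has cumulative, non-increasing thresholds", {
  x <- tiny_data()
  # per-scan degrees: S1: 100, 60, 80, 40 ; S2: 80, 100, 80, 40
  g <- group_synchrony_summary(x)
  expect_equal(sort(unname(g$degrees)),
               sort(c(100, 60, 80, 40, 80, 100, 80, 40)))
  expect_equal(g$mean, mean(c(100, 60, 80, 40, 80, 100, 80, 40)))
  expect_equal(unname(g$threshold_props),
               c(mean(g$degrees >= 70), mean(g$degrees >= 90), mean(g$degrees == 100)))
  expect_true(all(diff(g$threshold_props) <= 0))
  # >=70 includes the >=90 and 100 scans by construction
  expect_gte(g$threshold_props[[">=70"]], g$threshold_props[[">=90"]])
})

test_that("degree lower bound: >= 100 * ceil(n/4) / n", {
  sim <- simulate_herd(small_config(seed = 2))
  g <- group_synchrony_summary(sim$data)
  sizes <- group_size_summary(sim$data)$sizes
  expect_true(all(g$degrees >= 100 * ceiling(sizes / 4) / sizes - 1e-9))
})

test_that("Fleiss kappa matches the hand-computed 3x3 table exactly", {
  counts <- rbind(c(3, 0), c(2, 1), c(0, 3))  # (F,F,F), (F,F,L), (L,L,L)
  k <- fleiss_kappa_counts(counts)
  expect_equal(k$P_bar, 7 / 9)
  expect_equal(k$Pe_bar, 41 / 81)
  expect_equal(k$K, 22 / 40)                  # = 0.55
})

test_that("Fleiss kappa equals pairwise brute force on random tables", {
  set.seed(42)
  for (rep in 1:20) {
    m <- 5
    counts <- t(replicate(5, tabulate(sample.int(4, m, replace = TRUE), 4)))
    if (length(unique(apply(counts, 1, which.max))) == 1 &&
        all(counts[cbind(1:5, apply(counts, 1, which.max))] == m)) next
    expect_equal(fleiss_kappa_counts(counts)$K, brute_fleiss(counts),
                 tolerance = 1e-12)
  }
})

test_that("fleiss_kappa on datasets: complete-scan selection and errors", {
  x <- tiny_data()
  k <- fleiss_kappa(x)           # every scan complete in the tiny data
  expect_equal(k$n_subjects, 8L)
  expect_equal(k$n_raters, 5L)
  # perfect agreement -> K = 1
  y <- x
  y$scans$behavior <- factor(ifelse(
    paste(y$scans$session_id, y$scans$scan_index) %in%
      c("S1 1", "S1 2", "S2 1", "S2 2"), "foraging", "lying"),
    behavior_levels())
  expect_equal(fleiss_kappa(y)$K, 1.0)
  # all one category -> undefined
  z <- x
  z$scans$behavior <- factor("foraging", behavior_levels())
  expect_error(fleiss_kappa(z), "undefined")
  # fewer than 2 complete scans -> error naming the count
  w <- x
  w$scans <- w$scans[!(w$scans$animal_id == "E" & w$scans$session_id == "S1"), ]
  w$scans <- w$scans[!(w$scans$animal_id == "D" & w$scans$session_id == "S2" &
                         w$scans$scan_index > 1), ]
  expect_error(fleiss_kappa(w), "got 1")
})

test_that("expected synchrony is the profile dot product, symmetric, bounded", {
  u <- rep(.25, 4)
  expect_equal(expected_synchrony(u, u), 0.25)
  expect_equal(expected_synchrony(c(1, 0, 0, 0), c(0, 1, 0, 0)), 0)
  expect_equal(expected_synchrony(c(.5, .5, 0, 0), c(.5, .5, 0, 0)), 0.5)
  set.seed(9)
  for (i in 1:25) {
    a <- as.vector(stats::rgamma(4, 1)); a <- a / sum(a)
    b <- as.vector(stats::rgamma(4, 1)); b <- b / sum(b)
    expect_equal(expected_synchrony(a, b), expected_synchrony(b, a))
    expect_lte(expected_synchrony(a, b), 1)
    expect_gte(expected_synchrony(a, b), 0)
  }
})

test_that("behavior_profiles rows are budgets in canonical order", {
  p <- behavior_profiles(tiny_data())
  expect_equal(colnames(p), behavior_levels())
  expect_equal(unname(rowSums(p)), rep(1, 5))
  expect_equal(unname(p["A", "foraging"]), 5 / 8)
})

test_that("dyadic observed synchrony counts matches over co-presence", {
  x <- tiny_data()
  # A and B co-present in all 8 scans; matches by hand:
  # S1: F/F, F/F, L/L, W/S ; S2: F/F, S/S, F/F, F/L -> 6 of 8
  d <- dyadic_observed_synchrony(x, c("A", "B"))
  expect_equal(d$n_co_present, 8L)
  expect_equal(d$observed, 6 / 8)
  # identical streams -> 1
  y <- x
  y$scans$behavior[y$scans$animal_id == "B"] <-
    y$scans$behavior[y$scans$animal_id == "A"]
  expect_equal(dyadic_observed_synchrony(y, c("A", "B"))$observed, 1.0)
  # never co-present -> error
  z <- x
  z$scans <- z$scans[!(z$scans$animal_id == "E" & z$scans$session_id == "S1"), ]
  z$scans <- z$scans[!(z$scans$animal_id == "D" & z$scans$session_id == "S2"), ]
  expect_error(dyadic_observed_synchrony(z, c("D", "E")), "never co-present")
})

test_that("dyad table enumerates all observed pairs", {
  sim <- simulate_herd(small_config(seed = 3))
  dy <- dyad_synchrony_table(sim$data)
  expect_equal(nrow(dy), choose(17, 2))    # 136 dyads for 17 animals
  expect_true(all(dy$observed >= 0 & dy$observed <= 1))
  expect_true(all(dy$expected >= 0 & dy$expected <= 1))
  expect_true(all(dy$n_co_present >= 1))
})

test_that("paired t-test matches hand computation", {
  d <- data.frame(observed = c(0.5, 0.6, 0.7, 0.9),
                  expected = c(0.4, 0.5, 0.6, 0.7))
  # differences 0.1, 0.1, 0.1, 0.2 -> t = 0.125 / (0.05/2) = 5, df = 3
  tt <- observed_vs_expected_test(d)
  expect_equal(tt$t, 5.0)
  expect_equal(tt$df, 3)
  expect_equal(tt$p, 2 * stats::pt(-5, 3))
  const <- data.frame(observed = c(.5, .6), expected = c(.4, .5))
  expect_error(observed_vs_expected_test(const), "zero variance")
})

test_that("permutation oracle: independence null is recovered exactly where valid", {
  # Within-scan label permutation preserves each scan's behavior
  # composition. For independently behaving animals the permuted match
  # probability E[n_b (n_b - 1) / (k (k - 1))] equals p_b^2, so mean
  # observed minus expected stays at 0 under permutation; for coupled data
  # the composition itself is overdispersed, which permutation cannot
  # remove, so the excess persists (and synchrony is a group-level, not a
  # labelling, phenomenon).
  permute_scans <- function(x) {
    key <- paste(x$scans$session_id, x$scans$scan_index)
    for (k in unique(key)) {
      i <- which(key == k)
      x$scans$behavior[i] <- x$scans$behavior[sample(i)]
    }
    x
  }
  gap <- function(x) {
    dy <- dyad_synchrony_table(x)
    mean(dy$observed - dy$expected)
  }
  sim0 <- simulate_herd(small_config(seed = 6, n_sessions = 40,
                                     copy_prob = 0, beta_rank = 0))
  set.seed(11)
  perm0 <- mean(replicate(10, gap(permute_scans(sim0$data))))
  expect_lt(abs(gap(sim0$data)), 0.02)
  expect_lt(abs(perm0), 0.02)
  sim1 <- simulate_herd(small_config(seed = 5, n_sessions = 40))
  set.seed(12)
  perm1 <- mean(replicate(5, gap(permute_scans(sim1$data))))
  expect_gt(gap(sim1$data), 0.02)   # coupled herd exceeds the null ...
  expect_gt(perm1, 0.02)            # ... through composition, which permutation keeps
})
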