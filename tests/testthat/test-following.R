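mk_events <- function(id, time, from, to, flag = "normal", trial = "t") {
  data.frame(trial_id = trial, individual_id = id, time = time,
             from_zone = from, to_zone = to, flag = flag,
             stringsAsFactors = FALSE)
}

test_that("a same-gate transition while the leader is present is a following", {
  ev <- rbind(mk_events("L", 10, 1, 2), mk_events("F", 12, 1, 2))
  occ <- build_occupancy(ev, c("L", "F"))
  ints <- detect_followings(filter_events(ev), occ)
  expect_equal(nrow(ints), 1)
  expect_equal(ints$leader_id, "L")
  expect_equal(ints$follower_id, "F")
  expect_equal(ints$delta_t, 2)
})

test_that("no following when the leader has left the destination zone", {
  ev <- rbind(mk_events("L", 10, 1, 2), mk_events("L", 11, 2, 3),
              mk_events("F", 12, 1, 2))
  occ <- build_occupancy(ev, c("L", "F"))
  ints <- detect_followings(filter_events(ev), occ)
  expect_equal(nrow(ints), 0)
})

test_that("attribution picks the most recent eligible uncredited leader", {
  ev <- rbind(mk_events("A", 10, 1, 2), mk_events("B", 11, 1, 2),
              mk_events("C", 12, 1, 2), mk_events("D", 13, 1, 2))
  occ <- build_occupancy(ev, c("A", "B", "C", "D"))
  ints <- detect_followings(filter_events(ev), occ)
  # C follows B (most recent); a follower's transition is itself a leader
  # event, so D follows C
  expect_equal(ints$leader_id[ints$follower_id == "C"], "B")
  expect_equal(ints$leader_id[ints$follower_id == "D"], "C")
})

test_that("attribution falls back past a credited leader, ties by file order", {
  # X and Y transit simultaneously (neither follows the other); F1 follows Y
  # (equal leader times resolve to the later-listed event) and then leaves,
  # so F2 falls back past the credited Y to the still-open X
  ev <- rbind(mk_events("X", 10, 1, 2), mk_events("Y", 10, 1, 2),
              mk_events("F1", 12, 1, 2), mk_events("F1", 12.5, 2, 3),
              mk_events("F2", 13, 1, 2))
  occ <- build_occupancy(ev, c("X", "Y", "F1", "F2"))
  ints <- detect_followings(filter_events(ev), occ)
  expect_equal(ints$leader_id[ints$follower_id == "F1"], "Y")
  expect_equal(ints$leader_id[ints$follower_id == "F2"], "X")
})

test_that("startle transits are ineligible on both sides but keep moving the animal", {
  ev <- rbind(mk_events("L", 10, 1, 2, flag = "startle"),
              mk_events("F", 12, 1, 2))
  filt <- filter_events(ev)
  occ <- build_occupancy(filt, c("L", "F"))
  expect_equal(nrow(detect_followings(filt, occ)), 0)
  expect_equal(zone_at(occ, "L", 11), 2)
  ev2 <- rbind(mk_events("L", 10, 1, 2),
               mk_events("F", 12, 1, 2, flag = "startle"))
  filt2 <- filter_events(ev2)
  occ2 <- build_occupancy(filt2, c("L", "F"))
  expect_equal(nrow(detect_followings(filt2, occ2)), 0)
})

test_that("tie strength follows the reciprocal-latency 10-minute rate", {
  expect_equal(tie_strength(c(2, 5), 600), 0.7)
  expect_equal(tie_strength(1, 600), 1)
  expect_equal(tie_strength(numeric(0), 600), 0)
  expect_error(tie_strength(c(2, -1), 600), "positive")
  expect_error(tie_strength(2, 0), "positive")
  # additive over disjoint interaction sets; scales as 1/t_focal
  expect_equal(tie_strength(c(2, 5, 3, 7), 600),
               tie_strength(c(2, 5), 600) + tie_strength(c(3, 7), 600))
  expect_equal(tie_strength(c(2, 5), 1200), tie_strength(c(2, 5), 600) / 2)
})

test_that("hand-checkable trial produces the worked network and rates", {
  ht <- hand_trial()
  ev <- filter_events(ht$events)
  occ <- build_occupancy(ev, ht$meta$individual_id)
  disc <- discovery_times(occ)
  ints <- detect_followings(ev, occ)
  nets <- build_individual_networks(ints, disc, ht$meta$individual_id)
  expect_equal(nets$weights["B", "A"], 0.7)
  expect_equal(sum(nets$weights != 0), 1)
  expect_equal(exploration_rate(ev, ints, disc, "B"), 1)
  expect_equal(exploration_rate(ev, ints, disc, "A"), 0.5)
  summ <- summarize_following(ev, ints)
  expect_equal(summ$n_transitions, 6)
  expect_equal(summ$n_followings, 2)
  expect_equal(summ$prop_following, 1 / 3)
})

test_that("only the focal's pre-discovery window feeds its network", {
  # F follows L at t=12 (before F's discovery at 300) and at t=395 (after)
  ev <- rbind(mk_events("L", 10, 1, 2), mk_events("F", 12, 1, 2),
              mk_events("F", 100, 2, 5), mk_events("F", 200, 5, 8),
              mk_events("F", 300, 8, 9),
              mk_events("F", 320, 9, 8), mk_events("F", 340, 8, 5),
              mk_events("F", 360, 5, 2),
              mk_events("L", 390, 2, 5), mk_events("F", 395, 2, 5))
  occ <- build_occupancy(ev, c("L", "F"))
  disc <- discovery_times(occ)
  ints <- detect_followings(filter_events(ev), occ)
  expect_equal(nrow(ints), 2)
  nets <- build_individual_networks(ints, disc, c("L", "F"))
  expect_equal(nets$weights["F", "L"], tie_strength(2, 300))
  # censored focals standardize by the trial duration
  expect_equal(unname(nets$t_focal["L"]), 2400)
})

test_that("homogeneous networks set every possible tie to one", {
  W <- homogeneous_networks(letters[1:8])
  expect_equal(rowSums(W), rep(7, 8), ignore_attr = TRUE)
  expect_equal(diag(W), rep(0, 8), ignore_attr = TRUE)
  expect_equal(W, t(W))
  expect_equal(sum(homogeneous_networks(c("a", "b"))), 2)
  expect_error(homogeneous_networks("a"), "at least 2")
})

test_that("exploration rate counts pre-discovery non-following transitions", {
  # 6 own transitions before discovery at 1200, none of them followings
  ev <- do.call(rbind, lapply(1:6, function(k)
    mk_events("a", k * 100, c(1, 2, 1, 2, 1, 2)[k], c(2, 1, 2, 1, 2, 1)[k])))
  disc <- data.frame(individual_id = "a", t_discovery = 1200,
                     censored = FALSE, stringsAsFactors = FALSE)
  no_ints <- detect_followings(filter_events(ev[0, ]),
                               build_occupancy(ev[0, ], "a"))
  expect_equal(exploration_rate(ev, no_ints, disc, "a"), 3)
  # all transitions are followings -> rate 0
  ints <- data.frame(trial_id = "t", leader_id = "b", follower_id = "a",
                     from_zone = 1, to_zone = 2, leader_time = ev$time - 1,
                     follower_time = ev$time, delta_t = 1,
                     stringsAsFactors = FALSE)
  expect_equal(exploration_rate(ev, ints, disc, "a"), 0)
  expect_equal(exploration_rate(ev[0, ], no_ints, disc, "a"), 0)
})

test_that("streaming detector matches the brute-force oracle with ties and startles", {
  cfg <- arena_sim_config(trial_duration = 600, following_bias = 6,
                          startle_prob = 0.05)
  for (seed in 1:10) {
    sim <- simulate_arena_trial(cfg, seed = seed)
    filt <- filter_events(sim$events)
    occ <- build_occupancy(filt, sim$meta$individual_id, trial_duration = 600)
    a <- detect_followings(filt, occ)
    b <- bf_followings(filt)
    expect_equal(a, b)
    # every interaction satisfies the invariants
    if (nrow(a)) {
      expect_true(all(a$delta_t > 0))
      expect_true(all(a$leader_id != a$follower_id))
      for (r in seq_len(nrow(a)))
        expect_equal(zone_at(occ, a$leader_id[r], a$follower_time[r]),
                     a$to_zone[r])
    }
  }
})
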