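# helpers to build tiny engineered datasets --------------------------------

blank_angles <- function(model, n) {
  dofs <- dof_names(model)
  matrix(0, n, length(dofs), dimnames = list(NULL, dofs))
}

mk_take <- function(model, n, activity, session, set = list()) {
  ang <- blank_angles(model, n)
  for (nm in names(set)) ang[, nm] <- set[[nm]]
  joint_angle_motion((1:n) / 30, ang, activity = activity, session = session)
}

test_that("Pearson correlation matches hand-computed values", {
  expect_identical(pearson_r(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_identical(pearson_r(c(1, 2, 3), c(6, 4, 2)), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_identical(pearson_r(c(5, 5, 5), c(1, 2, 3)), 0)
  expect_error(pearson_r(1:3, 1:4), "equal length")
  expect_error(pearson_r(1, 1), "at least 2")
})

test_that("inter-joint independence collapses for correlated joints and cancels across activities", {
  m <- hand_model_default()
  x <- sin(1:20)
  # identical joints: G = 0
  ds1 <- motion_dataset(list(
    mk_take(m, 20, "a", "s1", list(INDEX_PIP = x, INDEX_DIP = x))))
  expect_equal(inter_joint_independence(ds1, "index", "DIP", "PIP"), 0)
  # anti-correlated joints: absolute value also gives G = 0
  ds2 <- motion_dataset(list(
    mk_take(m, 20, "a", "s1", list(INDEX_PIP = x, INDEX_DIP = -x))))
  expect_equal(inter_joint_independence(ds2, "index", "DIP", "PIP"), 0)
  # +1 in one activity, -1 in another: the signed averages cancel to G = 1
  ds3 <- motion_dataset(list(
    mk_take(m, 20, "a", "s1", list(INDEX_PIP = x, INDEX_DIP = x)),
    mk_take(m, 20, "b", "s1", list(INDEX_PIP = x, INDEX_DIP = -x))))
  expect_equal(inter_joint_independence(ds3, "index", "DIP", "PIP"), 1)
  expect_error(inter_joint_independence(ds1, "index", "DIP", "NOPE"),
               "unknown role")
})

test_that("finger redundancy is 1 for a duplicated finger and 0 against still fingers", {
  m <- hand_model_default()
  n <- 25
  set.seed(30)
  idx_series <- list(INDEX_MCP_FLEXION = rnorm(n), INDEX_ABDUCTION = rnorm(n),
                     INDEX_PIP = rnorm(n), INDEX_DIP = rnorm(n))
  # middle duplicates index in all four role-paired joints
  dup <- idx_series
  names(dup) <- c("MIDDLE_MCP_FLEXION", "MIDDLE_ABDUCTION", "MIDDLE_PIP",
                  "MIDDLE_DIP")
  ds <- motion_dataset(list(mk_take(m, n, "a", "s1", c(idx_series, dup))))
  expect_equal(finger_redundancy(ds, "index", "a"), 1, tolerance = 1e-12)
  # all other fingers constant: r = 0 by convention, D = 0
  ds0 <- motion_dataset(list(mk_take(m, n, "a", "s1", idx_series)))
  expect_equal(finger_redundancy(ds0, "index", "a"), 0)
  expect_identical(inter_finger_independence(ds0, "index"), 1)
  expect_identical(inter_finger_independence(ds, "index"), 0)
})

test_that("scores match a brute-force nested-loop evaluation to 1e-12", {
  m <- hand_model_default()
  set.seed(31)
  for (rep in 1:3) {
    ds <- random_motion_dataset(m)
    sc <- importance_scores(ds, m)
    oracle <- oracle_placement(ds)
    expect_equal(sc$H, oracle$H, tolerance = 1e-12)
    expect_equal(sc$D_fa, oracle$D, tolerance = 1e-12)
    expect_equal(sc$I[names(oracle$I)], oracle$I, tolerance = 1e-12)
    # all scores within [0, 1] and the ranking is a permutation of the sites
    expect_true(all(sc$I >= 0 & sc$I <= 1))
    expect_true(all(sc$H >= 0 & sc$H <= 1))
    expect_true(all(sc$D_fa >= 0 & sc$D_fa <= 1))
    expect_setequal(sc$ranking, m$sensor_sites$name)
  }
})

test_that("scores are invariant to session duplication and sign flips", {
  m <- hand_model_default()
  set.seed(32)
  ds <- random_motion_dataset(m, n_activities = 2, n_sessions = 2)
  sc <- importance_scores(ds, m)
  # duplicating every session of one activity (imbalance) changes nothing
  dup_takes <- c(ds$takes, ds$takes[ds$activity == "act1"],
                 ds$takes[ds$activity == "act1"])
  sc_dup <- importance_scores(motion_dataset(dup_takes), m)
  expect_equal(sc_dup$I, sc$I, tolerance = 1e-12)
  expect_identical(sc_dup$ranking, sc$ranking)
  # negating every column of a finger changes nothing: the correlation
  # signs flip coherently inside each absolute value (a single-column flip
  # is *not* invariant for the redundancy score, whose joint average sits
  # inside the norm)
  flipped <- ds$takes
  ring_cols <- grep("^RING_", colnames(flipped[[1]]$angles), value = TRUE)
  for (i in seq_along(flipped)) {
    flipped[[i]]$angles[, ring_cols] <- -flipped[[i]]$angles[, ring_cols]
  }
  sc_flip <- importance_scores(motion_dataset(flipped), m)
  expect_equal(sc_flip$I, sc$I, tolerance = 1e-12)
})

test_that("an all-identical dataset degenerates to tie-break ranking", {
  m <- hand_model_default()
  x <- sin(1:30)
  cols <- finger_joint_names(m)
  ang <- blank_angles(m, 30)
  for (cn in cols) ang[, cn] <- x
  ds <- motion_dataset(list(
    joint_angle_motion((1:30) / 30, ang, "a", "s1")))
  sc <- importance_scores(ds, m)
  expect_true(sc$degenerate)
  expect_true(all(sc$I == 0))
  expect_identical(sc$ranking, gloveforge:::.anatomical_order())
})

test_that("the engineered pinch vocabulary puts only thumb/index sites on top", {
  set.seed(33)
  bb <- build_benchmark(pinch_vocabulary(), n_subjects = 2,
                        takes_per_gesture = 4, rate = 30, duration = 2)
  sc <- importance_scores(bb$dataset)
  top3_fingers <- sub("_.*$", "", sc$ranking[1:3])
  expect_true(all(top3_fingers %in% c("thumb", "index")))
})

test_that("candidate sets are nested with complementary worst sets", {
  m <- hand_model_default()
  set.seed(34)
  sc <- importance_scores(random_motion_dataset(m), m)
  cs <- candidate_sets(sc, 15)
  expect_identical(cs$best[[1]], sc$ranking[1])
  expect_length(cs$best[[15]], 15L)
  for (i in 1:14) {
    expect_true(all(cs$best[[i]] %in% cs$best[[i + 1]]))
    expect_true(all(cs$worst[[i]] %in% cs$worst[[i + 1]]))
  }
  expect_identical(sort(cs$worst[[15]]), sort(sc$ranking))
  expect_error(candidate_sets(sc, 0), "between 1 and 15")
  expect_error(candidate_sets(sc, 16), "between 1 and 15")
})

test_that("placement reports serialize to JSON", {
  m <- hand_model_default()
  set.seed(35)
  sc <- importance_scores(random_motion_dataset(m), m)
  path <- withr::local_tempfile(fileext = ".json")
  write_placement_report(sc, path, k = 3)
  doc <- jsonlite::read_json(path)
  expect_length(doc$ranking, 15)
  expect_length(doc$candidate_sets$best, 3)
  expect_equal(doc$importance[[doc$ranking[[1]]]],
               max(unlist(doc$importance)))
})
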