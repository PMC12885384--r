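make_pop_dataset <- function(counts, n_ctrl = 50, m = 6, seed = 3) {
  m <- max(m, length(counts))
  with_seed_local(seed, {
    total <- sum(counts) + n_ctrl
    vals <- matrix(rnorm(total * m), total, m)
    colnames(vals) <- paste0("g", seq_len(m))
    ann <- c(rep("non-targeting", n_ctrl),
             rep(paste0("g", seq_along(counts)), counts))
    expression_dataset(vals, ann)
  })
}

test_that("in-distribution splits give 70/10/20 with floor rounding", {
  d <- make_pop_dataset(counts = c(10, 25))
  s <- make_split(d, "in_distribution", seed = 1)
  r <- s$roles[s$roles$perturbation == "g1", ]
  expect_equal(sum(r$role == "train"), 7)
  expect_equal(sum(r$role == "val"), 1)
  expect_equal(sum(r$role == "test"), 2)
  # every cell gets exactly one role
  expect_false(any(is.na(s$roles$role)))
  expect_equal(nrow(s$roles), nrow(d$values))
})

test_that("the OOD rotation holds out every perturbation exactly once", {
  d <- make_pop_dataset(counts = rep(20, 10))
  held <- lapply(0:4, function(i)
    make_split(d, "out_of_distribution", split_index = i, seed = 4)$held_out_perturbations)
  all_held <- unlist(held)
  expect_setequal(all_held, perturbations(d))
  expect_equal(length(all_held), length(unique(all_held)))
  for (i in 0:4) {
    s <- make_split(d, "out_of_distribution", split_index = i, seed = 4)
    tr_perts <- unique(s$roles$perturbation[s$roles$role == "train"])
    expect_length(intersect(tr_perts, s$held_out_perturbations), 0)
    # held-out cells are all test cells
    ho <- s$roles[s$roles$perturbation %in% s$held_out_perturbations, ]
    expect_true(all(ho$role == "test"))
    # controls never held out, split 85/15
    ctrl <- s$roles[s$roles$perturbation == "non-targeting", ]
    expect_equal(sum(ctrl$role == "val"), floor(0.15 * nrow(ctrl)))
    expect_equal(sum(ctrl$role == "train"), nrow(ctrl) - floor(0.15 * nrow(ctrl)))
  }
})

test_that("splits are deterministic given the seed", {
  d <- make_pop_dataset(counts = rep(15, 6))
  s1 <- make_split(d, "out_of_distribution", split_index = 2, seed = 9)
  s2 <- make_split(d, "out_of_distribution", split_index = 2, seed = 9)
  expect_identical(s1$roles, s2$roles)
  s3 <- make_split(d, "out_of_distribution", split_index = 2, seed = 10)
  expect_false(identical(s1$held_out_perturbations, s3$held_out_perturbations))
})

test_that("invalid OOD configurations are rejected", {
  d <- make_pop_dataset(counts = rep(10, 3))
  expect_error(make_split(d, "out_of_distribution", split_index = 0, seed = 1),
               class = "perturbscm_invalid_configuration")
  d2 <- make_pop_dataset(counts = rep(10, 6))
  expect_error(make_split(d2, "out_of_distribution", split_index = 7, seed = 1),
               class = "perturbscm_invalid_configuration")
})

test_that("explicit held-out sets override the rotation", {
  d <- make_pop_dataset(counts = rep(10, 6))
  s <- make_split(d, "out_of_distribution", held_out = c("g2", "g5"), seed = 1)
  expect_setequal(s$held_out_perturbations, c("g2", "g5"))
  expect_true(all(s$roles$role[s$roles$perturbation %in% c("g2", "g5")] == "test"))
})
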