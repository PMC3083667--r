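test_that("default weight tables match the canonical influence and transfer schemes", {
  w <- default_weights()
  wp <- function(cls, ty) w$w_p$weight[w$w_p$age_class == cls & w$w_p$type == ty]
  expect_equal(wp("O", "alpha"), 1.0)
  expect_equal(wp("Y", "gamma"), 0.0)
  expect_equal(wp("M", "beta"), 0.4)
  expect_equal(knowledge_transfer_weight("alpha", "alpha"), 1.0)
  expect_equal(knowledge_transfer_weight("alpha", "gamma"), 0.5)
  expect_equal(knowledge_transfer_weight(rep("gamma", 3), c("alpha", "beta", "gamma")),
               c(0, 0, 0))
  pop <- make_population(c(70, 45, 20), type = c("alpha", "beta", "gamma"))
  expect_equal(perception_weight(pop), c(1.0, 0.4, 0.0))
})

test_that("known history admits all years at full engagement and none at zero", {
  pop <- make_population(c(60, 60), t_tru = c(1, 0))
  out <- withr::with_seed(1, build_known_history(pop, 2010, 1990))
  expect_equal(out$known_history[[1]], 1990:2009)
  expect_equal(out$known_history[[2]], integer(0))
  # candidate window respects the age limit: a 25-year-old reaches back 7 years
  young <- make_population(25, t_tru = 1)
  out2 <- withr::with_seed(1, build_known_history(young, 2010, 1990))
  expect_equal(out2$known_history[[1]], 2003:2009)
})

test_that("history admission is binomial in the engagement fraction", {
  pop <- make_population(60, t_tru = 0.5)  # 40 candidate years
  counts <- vapply(1:60, function(s) {
    out <- withr::with_seed(s, build_known_history(pop, 2010, 1970))
    length(out$known_history[[1]])
  }, numeric(1))
  expect_equal(mean(counts), 20, tolerance = 0.1)  # se ~ 0.41 over 60 seeds
  expect_true(all(counts >= 5 & counts <= 35))
})

test_that("annual extension tests only the newly completed year and is sticky", {
  pop <- make_population(c(30, 18), t_tru = 1,
                         known_history = list(c(2000L, 2005L), integer(0)))
  out <- withr::with_seed(1, extend_known_history(pop, 2010))
  expect_equal(out$known_history[[1]], c(2000L, 2005L, 2009L))
  expect_equal(out$known_history[[2]], integer(0))  # 18-year-olds not yet eligible
})

test_that("individual perception is current value minus known-history mean", {
  lin <- trend_series(2000:2010, intercept = 1, slope = 1)  # month-invariant
  pop <- make_population(c(70, 70, 70),
                         known_history = list(2000:2009, 2010L, integer(0)))
  rec <- individual_perception(pop, lin, "temperature", 6, 2010)
  expect_equal(rec$p[1], 11 - 5.5)  # values 1..10 over the history, current 11
  expect_equal(rec$p[2], 0)         # history mean equals current value
  expect_false(rec$defined[3])
  expect_true(is.na(rec$p[3]))
  expect_equal(rec$variable, rep("temperature", 3))
})

test_that("provider selection maximizes age-weighted engagement among longer histories", {
  pop <- make_population(c(80, 60, 40), t_tru = c(1, 0.5, 1),
                         known_history = list(1990:2009, 1985:2009, 2005:2009))
  # all three have longer histories than an empty-history newcomer;
  # scores are 1.0, 0.375, 0.5 -> the 80-year-old wins
  newcomer <- make_population(20)
  newcomer$id <- 4L
  pop2 <- dplyr::bind_rows(pop, newcomer)
  sel <- select_lk_provider(pop2)
  expect_equal(sel$provider_id[4], 1L)
  # an agent whose history is unsurpassed gets none
  expect_true(is.na(sel$provider_id[2]))
  # ties break to the smallest id
  twins <- make_population(c(50, 50, 30), t_tru = 1,
                           known_history = list(1995:2009, 1995:2009, integer(0)))
  expect_equal(select_lk_provider(twins)$provider_id[3], 1L)
})

test_that("provider selection matches brute force on random populations", {
  withr::with_seed(99, {
    for (k in 1:40) {
      n <- sample(2:20, 1)
      pop <- make_population(sample(18:90, n, replace = TRUE),
                             type = sample(c("alpha", "beta", "gamma"), n, TRUE),
                             t_tru = round(runif(n), 2),
                             known_history = lapply(seq_len(n), function(i) {
                               len <- sample(0:15, 1)
                               if (len == 0) integer(0) else
                                 sort(sample(1960:2009, len))
                             }))
      for (elig in c("cardinality", "span")) {
        expect_identical(select_lk_provider(pop, elig)$provider_id,
                         brute_lk_provider(pop, elig)$provider_id)
      }
    }
  })
})

test_that("perception blending is convex in the transfer weight", {
  expect_equal(apply_knowledge_transfer(2, 5, 0)$p, 2)
  expect_equal(apply_knowledge_transfer(2, 5, 1)$p, 5)
  expect_equal(apply_knowledge_transfer(2, 4, 0.5)$p, 3)
  out <- apply_knowledge_transfer(NA_real_, 4, 0.8)
  expect_equal(out$p, 3.2)
  expect_true(out$defined)
  out0 <- apply_knowledge_transfer(NA_real_, 4, 0)
  expect_false(out0$defined)
  expect_error(apply_knowledge_transfer(2, NA_real_, 0.5), "defined")
})

test_that("knowledge acquisition copies missing years with w_k probability", {
  pop <- make_population(c(80, 20, 20), type = c("alpha", "alpha", "gamma"),
                         known_history = list(1990:2009, integer(0), integer(0)))
  sel <- select_lk_provider(pop)
  out <- withr::with_seed(5, acquire_knowledge(pop, sel))
  # alpha recipient from alpha provider: w_k = 1, full adoption
  expect_setequal(out$known_history[[2]], 1990:2009)
  # gamma recipient acquires nothing
  expect_equal(out$known_history[[3]], integer(0))
  # provider untouched
  expect_equal(out$known_history[[1]], 1990:2009)
})

test_that("acquisition reads pre-transfer histories (simultaneous update)", {
  # 2 knows {2000}; 1 knows {2000, 2001} and provides to 2; 3 is empty and
  # has provider 1; whatever 2 acquires this round must not leak to 3
  pop <- make_population(c(50, 40, 30), type = "alpha",
                         known_history = list(c(2000L, 2001L), c(2000L), integer(0)))
  sel <- tibble::tibble(id = 1:3, provider_id = c(NA, 1L, 2L))
  out <- withr::with_seed(1, acquire_knowledge(pop, sel))
  expect_setequal(out$known_history[[2]], c(2000L, 2001L))
  expect_equal(out$known_history[[3]], c(2000L))  # only 2's snapshot
})

test_that("community perception is the normalized weighted mean with guards", {
  expect_equal(as.numeric(community_perception(c(2, 4), c(1, 1))), 3)
  expect_equal(as.numeric(community_perception(c(2, 4), c(1, 0))), 2)
  expect_equal(as.numeric(community_perception(c(1, 2, 3), c(1.0, 0.4, 0.0))),
               1.8 / 1.4)
  # all-zero weights fall back to the unweighted mean of defined perceptions
  expect_equal(as.numeric(community_perception(c(1, 5, NA), c(0, 0, 0))), 3)
  deg <- community_perception(c(NA_real_, NA_real_), c(1, 1))
  expect_equal(as.numeric(deg), 0)
  expect_true(attr(deg, "degenerate"))
  expect_error(community_perception(1:3, 1:2), "align")
})

test_that("community perception matches brute force and stays within the convex hull", {
  withr::with_seed(123, {
    for (k in 1:40) {
      n <- sample(1:20, 1)
      p <- rnorm(n)
      p[runif(n) < 0.2] <- NA
      w <- round(runif(n), 2)
      got <- as.numeric(community_perception(p, w))
      expect_equal(got, brute_community_perception(p, w), tolerance = 1e-12)
      if (any(!is.na(p))) {
        expect_gte(got, min(p, na.rm = TRUE) - 1e-12)
        expect_lte(got, max(p, na.rm = TRUE) + 1e-12)
      }
    }
  })
})

test_that("vulnerability is the signed gap between recorded and perceived change", {
  out <- vulnerability(c(5, 3, 2), c(3, 5, 2))
  expect_equal(out$v, c(2, -2, 0))
  expect_equal(out$v_abs, c(2, 2, 0))
})
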