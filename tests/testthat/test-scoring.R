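test_that("additive composition sums componentwise with degeneracy flags", {
  cv <- compose_additive(list(c(1, 2), c(3, 0.5)))
  expect_equal(cv$vector, c(4, 2.5))
  expect_equal(cv$n_tokens_used, 2L)
  expect_false(cv$degenerate)

  one <- compose_additive(list(c(1, 1)))
  expect_equal(one$vector, c(1, 1))

  z <- compose_additive(list(c(1, 0), c(-1, 0)))
  expect_true(z$degenerate)
  expect_null(z$vector)

  empty <- compose_additive(list())
  expect_null(empty$vector)
  expect_false(empty$degenerate)
  expect_equal(empty$n_tokens_used, 0L)

  expect_error(compose_additive(list(c(1, 2), c(1, 2, 3))), "mismatch")
})

test_that("multiplicative composition preserves product direction", {
  cv <- compose_multiplicative(list(c(1, 2), c(3, 0.5)))
  # positive multiple of (3, 1)
  expect_equal(cv$vector / cv$vector[2], c(3, 1), tolerance = 1e-12)

  z <- compose_multiplicative(list(c(1, 0), c(0, 1)))
  expect_true(z$degenerate)

  # long product: unit renormalization must agree with the exact product
  # direction computed in log space (a raw product of 40 copies of
  # (0.1, 0.2) underflows to ~1e-40 and ~1e-28)
  vecs <- rep(list(c(0.1, 0.2)), 40)
  cv40 <- compose_multiplicative(vecs)
  expect_false(cv40$degenerate)
  expect_equal(cv40$vector, oracle_product_direction(vecs),
               tolerance = 1e-9)

  # a genuinely underflowing mixed-sign case in higher dimension
  set.seed(5)
  vlist <- replicate(35, runif(6, 0.05, 0.4) * sample(c(-1, 1), 6, TRUE),
                     simplify = FALSE)
  cvl <- compose_multiplicative(vlist)
  ora <- oracle_product_direction(vlist)
  # same direction up to sign convention of the oracle (none): compare as is
  expect_equal(cvl$vector, ora, tolerance = 1e-9)
})

test_that("cosine matches analytic values and rejects zero vectors", {
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2), c(2, 4)), 1)
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)), sqrt(2) / 2,
               tolerance = 1e-12)
  expect_error(cosine_similarity(c(0, 0), c(1, 0)), "zero-norm")
  expect_error(cosine_similarity(c(1, 0), c(1, 0, 0)), "dimension")
})

test_that("semantic distance: self-distance zero, orthogonal one, oracle", {
  M <- rbind(a = c(1, 0), b = c(0, 1), box = c(0.3, 0.8),
             store = c(-0.2, 0.5), old = c(0.7, 0.1), hats = c(0.4, -0.6))
  sp <- semantic_space(M, "toy")
  for (m in c("additive", "multiplicative")) {
    expect_lt(abs(semantic_distance(sp, "box", "box", method = m)), 1e-12)
    expect_equal(semantic_distance(sp, "a", "b", method = m), 1)
    got <- semantic_distance(sp, "box", c("store", "old", "hats"),
                             method = m)
    expect_equal(got, oracle_distance(M, "box", c("store", "old", "hats"),
                                      m), tolerance = 1e-12)
  }
  # OOV-only and empty responses are missing, not errors
  expect_true(is.na(semantic_distance(sp, "box", c("zz", "qq"))))
  expect_true(is.na(semantic_distance(sp, "box", character())))
})

test_that("pipeline distance equals the brute-force oracle on random cases", {
  set.seed(99)
  n_cases <- 250
  for (case in seq_len(n_cases)) {
    d <- sample(2:10, 1)
    words <- unique(replicate(sample(5:12, 1), random_word()))
    M <- matrix(rnorm(length(words) * d), length(words), d)
    rownames(M) <- words
    sp <- semantic_space(M, "rand")
    cue <- sample(words, 1)
    resp <- sample(words, sample(1:6, 1), replace = TRUE)
    method <- sample(c("additive", "multiplicative"), 1)
    got <- semantic_distance(sp, cue, resp, method = method)
    want <- oracle_distance(M, cue, resp, method)
    if (is.na(want)) expect_true(is.na(got))
    else expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("distances lie in [0,2], are scale-invariant and permutation-invariant", {
  set.seed(123)
  for (case in 1:40) {
    d <- sample(3:8, 1)
    words <- unique(replicate(10, random_word()))
    M <- matrix(rnorm(length(words) * d), length(words), d)
    rownames(M) <- words
    sp <- semantic_space(M, "rand")
    cue <- sample(words, 1)
    resp <- sample(words, sample(2:6, 1), replace = TRUE)
    scale <- runif(1, 0.01, 100)
    sp_scaled <- semantic_space(M * scale, "scaled")
    for (m in c("additive", "multiplicative")) {
      d0 <- semantic_distance(sp, cue, resp, method = m)
      expect_gte(d0, 0)
      expect_lte(d0, 2)
      expect_equal(semantic_distance(sp_scaled, cue, resp, method = m),
                   d0, tolerance = 1e-10)
      expect_equal(semantic_distance(sp, cue, sample(resp), method = m),
                   d0, tolerance = 1e-9)
    }
    # singleton equivalence
    single <- sample(words, 1)
    expect_equal(semantic_distance(sp, cue, single, method = "additive"),
                 semantic_distance(sp, cue, single,
                                   method = "multiplicative"),
                 tolerance = 1e-12)
  }
})

test_that("score_table fills every space column and is deterministic", {
  spaces <- list(s1 = semantic_space(toy_matrix(c("box", "use", "hat"), 4,
                                                seed = 1), "s1"),
                 s2 = semantic_space(toy_matrix(c("box", "use", "hat"), 4,
                                                seed = 2), "s2"),
                 s3 = semantic_space(toy_matrix(c("box", "use", "hat"), 4,
                                                seed = 3), "s3"))
  records <- tibble::tibble(
    id = c("p1", "p2", "p3"),
    item = "box",
    response = c("use as a hat", "", "zzxq unknown words"))
  out <- score_table(records, spaces, method = "multiplicative",
                     config = cleaning_config("basic"))
  expect_identical(distance_columns(out), c("s1_dis", "s2_dis", "s3_dis"))
  expect_equal(nrow(out), 3L)
  # empty and all-OOV responses are missing in every space
  expect_true(all(is.na(out[2, distance_columns(out)])))
  expect_true(all(is.na(out[3, distance_columns(out)])))
  expect_false(anyNA(out[1, distance_columns(out)]))
  expect_equal(out$word_count, c(4L, 0L, 3L))
  # OOV ledger records the dropped tokens per space
  oov <- attr(out, "oov")
  expect_setequal(unique(oov$token[oov$id == "p3"]),
                  c("zzxq", "unknown", "words"))
  # determinism: identical reruns bit-identical
  out2 <- score_table(records, spaces, method = "multiplicative",
                      config = cleaning_config("basic"))
  expect_identical(as.data.frame(out), as.data.frame(out2))
  # malformed record
  expect_error(score_table(tibble::tibble(id = "p", item = "",
                                          response = "x"), spaces),
               "row 1")
})

test_that("cue removal changes word_count but cue cleaning stays basic", {
  sp <- semantic_space(toy_matrix(c("box", "hat", "things"), 4), "s")
  rec <- tibble::tibble(id = "p1", item = "box",
                        response = "box of things")
  plain <- score_table(rec, list(s = sp), config = cleaning_config("basic"))
  cuerm <- score_table(rec, list(s = sp),
                       config = cleaning_config("basic", remove_cue = TRUE))
  expect_equal(plain$word_count, 3L)
  expect_equal(cuerm$word_count, 2L)  # "box" deleted, "of" OOV-dropped later
  expect_false(identical(plain$s_dis, cuerm$s_dis))
})
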