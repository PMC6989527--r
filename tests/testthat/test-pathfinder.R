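rand_cm <- function(p = 0.4, nr = 4, nl = 3) matrix(runif(nr * nl) < p, nr, nl)

test_that("contact dissimilarity is the Jaccard distance", {
  a <- rand_cm(); set.seed(1)
  expect_equal(contact_dissimilarity(a, a), 0)
  empty <- matrix(FALSE, 4, 3)
  expect_equal(contact_dissimilarity(empty, empty), 0)
  b <- matrix(FALSE, 4, 3); b[1, 1] <- TRUE
  c2 <- matrix(FALSE, 4, 3); c2[2, 2] <- TRUE
  expect_equal(contact_dissimilarity(b, c2), 1)
  sub <- matrix(FALSE, 4, 3); sub[1:2, 1] <- TRUE
  sup <- sub; sup[3:4, 2] <- TRUE
  expect_equal(contact_dissimilarity(sub, sup), 0.5)
  expect_error(contact_dissimilarity(b, b[1:3, ]), "shape")
})

test_that("window assignment uses nearest centers with the lower-index tie rule", {
  ws <- window_spec(4, 0, 6, 0.3)   # centers 0, 2, 4, 6
  lamp <- c(0.4, 1.0, 2.1, 3.0, 4.9, 5.9, 8.5, -1.5)
  pools <- assign_windows(lamp, ws)
  expect_equal(pools[[1]], c(1, 2))     # 1.0 is the exact midpoint -> lower
  expect_equal(pools[[2]], c(3, 4))     # 3.0 midpoint -> window 2
  expect_equal(pools[[3]], 5)
  expect_equal(pools[[4]], 6)
  expect_equal(attr(pools, "unassigned"), c(7, 8))
  expect_equal(sum(lengths(pools)) + 2, length(lamp))
  expect_error(assign_windows(c(0.1, 6.0), ws), "window")
})

test_that("single-candidate pools give the forced chain and its summed score", {
  set.seed(21)
  cms <- replicate(4, rand_cm(), simplify = FALSE)
  sel <- pick_path(as.list(1:4), cms, n_seeds = 1)
  expect_equal(sel$chain, 1:4)
  expect_equal(sel$score,
               sum(vapply(1:3, function(i)
                 contact_dissimilarity(cms[[i]], cms[[i + 1]]), numeric(1))))
})

test_that("identical candidate contacts give a zero-score chain", {
  cm <- rand_cm()
  cms <- replicate(9, cm, simplify = FALSE)
  sel <- pick_path(split(1:9, rep(1:3, each = 3)), cms, n_seeds = 3)
  expect_equal(sel$score, 0)
  expect_equal(lengths(sel$seeds), rep(3L, 3))
})

test_that("dynamic programming equals exhaustive enumeration on small instances", {
  set.seed(22)
  for (trial in 1:12) {
    n_w <- sample(2:5, 1)
    sizes <- sample(1:4, n_w, replace = TRUE)
    ids <- seq_len(sum(sizes))
    pools <- split(ids, rep(seq_len(n_w), sizes))
    cms <- replicate(length(ids), rand_cm(), simplify = FALSE)
    sel <- pick_path(pools, cms, n_seeds = 1)
    combos <- do.call(expand.grid, pools)
    brute <- min(apply(combos, 1, function(ch) {
      sum(vapply(seq_len(n_w - 1), function(i)
        contact_dissimilarity(cms[[ch[i]]], cms[[ch[i + 1]]]), numeric(1)))
    }))
    expect_equal(sel$score, brute, tolerance = 1e-12)
  }
})

test_that("selected chains traverse monotonically increasing window centers", {
  ws <- window_spec(5, 0, 8, 0.3)
  set.seed(23)
  lamp <- runif(60, -0.5, 8.5)
  pools <- assign_windows(lamp, ws)
  cms <- replicate(60, rand_cm(), simplify = FALSE)
  sel <- pick_path(pools, cms, n_seeds = 2)
  centers_of <- vapply(seq_along(sel$chain), function(w)
    ws$center[w], numeric(1))
  expect_true(all(diff(centers_of) > 0))
  for (w in seq_along(pools)) expect_true(all(sel$seeds[[w]] %in% pools[[w]]))
})
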