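test_that("template building averages renditions on a common length", {
  r <- sin(seq(0, 3, length.out = 100))
  tpl <- build_template(list(r, r, r), n = 3)
  expect_equal(tpl$feature, r)
  expect_equal(tpl$n_source, 3)

  a <- seq(0, 1, length.out = 50)
  b <- rev(a)
  tpl2 <- build_template(list(a, b), n = 2)
  expect_equal(tpl2$feature, (a + b) / 2)

  expect_error(build_template(list()), "empty")
})

test_that("alignment of a sequence to itself is the zero-cost diagonal", {
  set.seed(4)
  x <- rnorm(40)
  p <- dtw_align(x, x)
  expect_equal(p$cost, 0)
  expect_equal(p$pairs[, 1], p$pairs[, 2])
  expect_equal(nrow(p$pairs), 40)
})

test_that("dynamic program matches exhaustive path enumeration", {
  set.seed(11)
  for (rep in 1:30) {
    m <- sample(2:6, 1)
    n <- sample(2:6, 1)
    x <- rnorm(m)
    y <- rnorm(n)
    band <- max(m, n)  # unconstrained, as in the enumeration
    p <- dtw_align(x, y, band = 1, normalize = FALSE)
    expect_equal(p$cost, dtw_enumerate(sq_cost(x, y)))
    # path is a valid warping path
    steps <- diff(p$pairs)
    expect_true(all(steps >= 0 & steps <= 1))
    expect_true(all(rowSums(steps) >= 1))
    expect_equal(p$pairs[1, ], c(query = 1, template = 1))
    expect_equal(unname(p$pairs[nrow(p$pairs), ]), c(m, n))
  }
})

test_that("alignment cost is symmetric and zero only for identical input", {
  set.seed(5)
  x <- rnorm(30)
  y <- rnorm(30)
  expect_equal(dtw_align(x, y, normalize = FALSE)$cost,
               dtw_align(y, x, normalize = FALSE)$cost)
  expect_gt(dtw_align(x, y, normalize = FALSE)$cost, 0)
  expect_error(dtw_align(rnorm(50), rnorm(10), band = 0.2), "infeasible")
  expect_error(dtw_align(numeric(0), rnorm(5)), "non-empty")
})

test_that("warp application averages many-to-one bins and inverts identity", {
  idp <- structure(list(pairs = cbind(query = 1:5, template = 1:5),
                        cost = 0, m = 5, n = 5), class = "warp_path")
  env <- c(1, 4, 9, 16, 25)
  expect_equal(apply_warp(env, idp), env)

  two2one <- structure(
    list(pairs = cbind(query = c(1, 2, 3), template = c(1, 1, 2)),
         cost = 0, m = 3, n = 2),
    class = "warp_path"
  )
  expect_equal(apply_warp(c(2, 4, 10), two2one), c(3, 10))
  expect_error(apply_warp(c(1, 2), idp), "does not match")
})

test_that("simulator warps are recovered within 3 ms median error", {
  errs <- c()
  for (s in 1:3) {
    sc <- chronic_scenario(n_channels = 2, motif_len = 600,
                           renditions_per_day = 5, warp_jitter = 0.1,
                           fs = 16000, template_seed = s,
                           noise = noise_preset(1, c(300, 6000)))
    ses <- gen_chronic_session(sc, day = 1, seed = s)
    rnd <- motif_renditions(ses)
    for (r in seq_along(rnd)) {
      feat <- rnd[[r]]$feature
      k <- min(length(feat), sc$motif_len - 10)
      tpl <- sc$shared_envelope[seq(11, length.out = k)]
      p <- dtw_align(feat[1:k], tpl)
      rec_t <- tapply(p$pairs[, 2], p$pairs[, 1], mean)
      u <- as.numeric(names(rec_t))
      w <- ses$truth$renditions[[r]]$warp
      true_t <- stats::approx(w$rendition_knots, w$template_knots,
                              xout = u + 10, rule = 2)$y - 10
      errs <- c(errs, stats::median(abs(rec_t - true_t)))
    }
  }
  expect_lte(stats::median(errs), 3)
})

# valid warp_path from a monotone rendition-time -> template-index map:
# advance the template index with (0,1) steps until it reaches the mapped
# target, then take the next rendition bin
path_from_map <- function(jstar, n) {
  m <- length(jstar)
  jstar[1] <- 1L
  ii <- 1L; jj <- 1L
  pi_ <- 1L; pj_ <- 1L
  while (ii < m || jj < n) {
    if (ii == m) {                      # finish the template with (0,1)
      jj <- jj + 1L
    } else {
      tgt <- min(jstar[ii + 1L], n)
      if (jj < tgt - 1L) {              # catch up with (0,1)
        jj <- jj + 1L
      } else if (jj < tgt) {            # diagonal
        ii <- ii + 1L; jj <- jj + 1L
      } else {                          # (1,0)
        ii <- ii + 1L
      }
    }
    pi_ <- c(pi_, ii); pj_ <- c(pj_, jj)
  }
  pairs <- cbind(query = pi_, template = pj_)
  structure(list(pairs = pairs, cost = NA_real_, m = m, n = n),
            class = "warp_path")
}

test_that("inverting the ground-truth warp restores the template envelope", {
  sc <- chronic_scenario(n_channels = 2, motif_len = 600,
                         renditions_per_day = 4, warp_jitter = 0.1,
                         fs = 16000, noise = noise_preset(0, c(300, 6000)))
  ses <- gen_chronic_session(sc, day = 1, seed = 7)
  for (r in seq_len(2)) {
    tru <- ses$truth$renditions[[r]]
    m <- length(tru$feature)
    u <- seq_len(m) - 0.5
    w <- tru$warp
    jstar <- round(stats::approx(w$rendition_knots, w$template_knots,
                                 xout = u, rule = 2)$y + 0.5)
    jstar <- cummax(pmin(pmax(jstar, 1L), sc$motif_len))
    p <- path_from_map(as.integer(jstar), sc$motif_len)
    back <- apply_warp(tru$envelope[, 1], p)
    expect_gte(stats::cor(back, ses$truth$template_envelopes[, 1]), 0.99)
  }
})

test_that("alignment improves pairwise envelope correlation under jitter", {
  sc <- chronic_scenario(n_channels = 2, motif_len = 500,
                         renditions_per_day = 8, warp_jitter = 0.1,
                         fs = 16000, noise = noise_preset(2, c(300, 6000)))
  ses <- gen_chronic_session(sc, day = 1, seed = 9)
  rnd <- motif_renditions(ses)
  tpl <- build_template(lapply(rnd, `[[`, "feature"), n = 8)
  L <- length(tpl$feature)
  aligned <- vapply(rnd, function(r) {
    apply_warp(r$neural[, 1], dtw_align(r$feature, tpl))
  }, numeric(L))
  L2 <- min(vapply(rnd, function(r) nrow(r$neural), numeric(1)))
  crop <- vapply(rnd, function(r) r$neural[seq_len(L2), 1], numeric(L2))
  mean_cor <- function(m) {
    cc <- stats::cor(m)
    mean(cc[upper.tri(cc)])
  }
  expect_gt(mean_cor(aligned), mean_cor(crop))
})
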