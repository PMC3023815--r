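test_that("single-method configuration yields a one-row gauged report", {
  p <- independent_panel(50, seed = 201)
  g <- simulate_genotypes(p, 300, seed = 202)
  g <- assign_phenotypes(g, "null", seed = 203)
  cmp <- compare_methods(g, methods = "bonferroni", B = 200, seed = 204)
  expect_equal(nrow(cmp), 1L)
  expect_equal(cmp$method, "bonferroni")
  expect_equal(cmp$threshold, 0.05 / 50)
  expect_true(is.finite(cmp$corresponding_alpha))
})

test_that("independent SNPs: every correction is near nominal, blocks reduce to Bonferroni", {
  p <- independent_panel(150, seed = 211)
  g <- simulate_genotypes(p, 500, seed = 212)
  g <- assign_phenotypes(g, "null", seed = 213)
  cmp <- compare_methods(g, B = 1500, n_iter = 1500, window = 5,
                         ld_window = 20, target_region_size = 50,
                         seed = 214)
  tb <- tibble::as_tibble(cmp)
  blocks <- tb[tb$method %in% c("gabriel", "spine", "fourgamete"), ]
  expect_true(all(blocks$n_tests == 150L))
  expect_true(all(blocks$threshold == 0.05 / 150))
  expect_true(all(abs(tb$corresponding_alpha - 0.05) < 0.035))
})

test_that("blocky data reproduces the reference threshold ordering", {
  p <- blocky_panel(60, seed = 221)
  g <- simulate_genotypes(p, 600, seed = 222)
  g <- assign_phenotypes(g, "null", seed = 223)
  cmp <- compare_methods(g, B = 2000, n_iter = 2000, window = 12,
                         ld_window = 25, target_region_size = 60,
                         seed = 224)
  tb <- tibble::as_tibble(cmp)
  thr <- function(m) tb$threshold[tb$method == m]
  ca <- function(m) tb$corresponding_alpha[tb$method == m]
  # Bonferroni is the smallest threshold; LD-block corrections the largest
  expect_true(thr("bonferroni") <= thr("permutation"))
  expect_true(all(thr("permutation") <= c(thr("gabriel"), thr("spine"),
                                          thr("fourgamete"))))
  # block-count corrections are anti-conservative against the shared gauge
  expect_true(all(c(ca("gabriel"), ca("spine"), ca("fourgamete")) >
                    ca("permutation")))
  expect_lte(ca("bonferroni"), 0.05 + 2 * sqrt(0.05 * 0.95 / 2000))
  # permutation row is self-consistent
  expect_gte(ca("permutation"), 0.05)
})

test_that("reports are reproducible under a fixed seed", {
  p <- blocky_panel(20, seed = 231)
  g <- simulate_genotypes(p, 300, seed = 232)
  g <- assign_phenotypes(g, "null", seed = 233)
  a <- compare_methods(g, B = 300, n_iter = 300, window = 8, ld_window = 15,
                       seed = 7)
  b <- compare_methods(g, B = 300, n_iter = 300, window = 8, ld_window = 15,
                       seed = 7)
  expect_equal(tibble::as_tibble(a), tibble::as_tibble(b))
})

test_that("subset equal to the full data gives zero deltas; seeds reproduce", {
  p <- blocky_panel(20, seed = 241)
  g <- simulate_genotypes(p, 400, seed = 242)
  g <- assign_phenotypes(g, "null", seed = 243)
  n_cases <- sum(g$labels)
  d0 <- subset_delta(g, n_cases = n_cases, seed = 5, B = 300, n_iter = 300,
                     window = 8, ld_window = 15)
  expect_true(all(d0$delta == 0))
  d1 <- subset_delta(g, n_cases = n_cases %/% 2, seed = 6, B = 300,
                     n_iter = 300, window = 8, ld_window = 15)
  d2 <- subset_delta(g, n_cases = n_cases %/% 2, seed = 6, B = 300,
                     n_iter = 300, window = 8, ld_window = 15)
  expect_equal(d1, d2)
  expect_error(
    subset_delta(g, n_cases = nrow(g$dosages) + 1, seed = 1), "available"
  )
})

test_that("tidiers and plots expose the fitted objects", {
  p <- blocky_panel(10, seed = 251)
  g <- simulate_genotypes(p, 200, seed = 252)
  g <- assign_phenotypes(g, "null", seed = 253)
  mp <- permute_minp(g, B = 100, seed = 254)
  td <- tidy(mp)
  expect_equal(nrow(td), 100L)
  expect_true(all(diff(td$min_p) >= 0))
  gl <- glance(mp)
  expect_equal(gl$B, 100L)
  expect_equal(gl$threshold_0.05, null_threshold(mp, 0.05))

  part <- solid_spine_blocks(g, window = 10)
  expect_equal(glance(part)$n_tests, block_test_count(part))
  expect_equal(nrow(tidy(part)), nrow(part$blocks))

  me <- simplem_meff(g)
  expect_equal(glance(me)$m_eff_total, me$total)
  expect_s3_class(autoplot(mp), "ggplot")
  expect_s3_class(autoplot(part), "ggplot")
  cmp <- compare_methods(g, methods = c("bonferroni", "permutation"),
                         B = 100, seed = 255, minp = mp)
  expect_s3_class(autoplot(cmp), "ggplot")
  expect_equal(glance(cmp)$B, 100L)
})
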