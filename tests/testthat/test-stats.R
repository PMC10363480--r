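test_that("t-test wrapper matches its definitions", {
  a <- c(1.1, 2.2, 3.3, 4.4, 5.5)
  expect_equal(groupTTest(a, a)$p_value, 1, tolerance = 1e-9)

  jitter <- c(1e-3, -1e-3, 5e-4, -5e-4, 2e-4)
  res <- groupTTest(rep(0, 5), 10 + jitter)
  expect_lt(res$p_value, 1e-6)

  b <- c(2.0, 3.1, 4.5, 5.2, 6.3)
  two <- groupTTest(b, a)$p_value
  one <- groupTTest(b, a, sided = "one", direction = "greater")$p_value
  expect_equal(one, two / 2, tolerance = 1e-12)

  expect_error(groupTTest(rep(1, 5), rep(1, 5)), "zero variance")
  # pooled-variance flag reproduces the classical test
  expect_equal(groupTTest(a, b, pooled = TRUE)$p_value,
               stats::t.test(a, b, var.equal = TRUE)$p.value)
})

test_that("Dunn post hoc z and p values match an independent oracle", {
  # expected values computed with an independent rank-based implementation
  # (scipy) on this frozen three-group dataset, which includes a cross-
  # group tie (5.0)
  g <- list(a = c(1.2, 3.4, 2.2, 5.0, 4.1, 3.3, 2.8, 4.4, 3.9, 2.5),
            b = c(4.8, 5.9, 6.1, 5.5, 7.2, 6.6, 5.0, 6.9, 5.8, 6.3),
            c = c(2.9, 3.1, 4.0, 3.8, 2.7, 3.5, 4.2, 3.0, 3.6, 2.6))
  res <- kruskalDunn(g, correction = "none")
  expect_equal(res$omnibus$statistic, 18.78288829550512, tolerance = 1e-9)
  expect_equal(res$omnibus$p_value, 8.343487690116377e-05, tolerance = 1e-9)
  pw <- res$pairwise
  expect_identical(paste(pw$group1, pw$group2), c("a b", "a c", "b c"))
  expect_equal(pw$z, c(-3.759621982910, -0.012701425618, 3.746920557293),
               tolerance = 1e-9)
  expect_equal(pw$p_value,
               c(1.701702896654e-04, 9.898660010799e-01, 1.790187504501e-04),
               tolerance = 1e-9)
  # correction never decreases any p-value
  holm <- kruskalDunn(g, correction = "holm")$pairwise
  expect_true(all(holm$p_adjusted >= holm$p_value - 1e-15))
})

test_that("degenerate group structures are reported, not errored", {
  same <- list(a = 1:10, b = 1:10, c = 1:10)
  res <- kruskalDunn(same)
  expect_gt(res$omnibus$p_value, 0.99)
  tied <- list(a = rep(1, 5), b = rep(1, 5), c = rep(1, 5))
  res2 <- kruskalDunn(tied)
  expect_true(is.na(res2$omnibus$p_value))
  expect_match(res2$omnibus$note, "tied")
})

test_that("composition contrasts reach significance at n = 50 per group", {
  d <- generateLabeledDataset(list(
    generatorSpec("HARAMP_LIKE", n = 50, seed = 91),   # K-rich
    generatorSpec("MTP_LIKE", n = 50, seed = 92),      # R-rich
    generatorSpec("RANDOM", n = 50, seed = 93)))
  tab <- aaFrequencyTable(list(krich = d$peptides$HARAMP_LIKE,
                               rrich = d$peptides$MTP_LIKE,
                               random = d$peptides$RANDOM))
  groups <- split(tab$freq_K, tab$set)
  res <- kruskalDunn(groups)
  expect_lt(res$omnibus$p_value, 1e-6)
  vs_k <- res$pairwise[res$pairwise$group1 == "krich" |
                         res$pairwise$group2 == "krich", ]
  expect_true(all(vs_k$p_adjusted < 0.001))
})

test_that("property tables recover the designed class contrasts", {
  d <- generateLabeledDataset(list(
    generatorSpec("MTP_LIKE", n = 30, seed = 94),
    generatorSpec("CTP_LIKE", n = 30, seed = 95)))
  all_p <- do.call(c, unname(d$peptides))
  metrics <- helixMetrics(findAmphipathicHelices(all_p, limitCleavage = FALSE))
  freq <- aaFrequencyTable(all_p)
  features <- data.frame(peptide_id = freq$peptide_id,
                         freq_K = freq$freq_K, freq_R = freq$freq_R,
                         boman = unname(bomanIndex(all_p)))
  sets <- data.frame(peptide_id = d$truth$peptide_id, set = d$truth$class)
  out <- tpPropertyTable(metrics, features, sets)
  expect_true(all(c("mean", "median") %in% names(out$table)))

  get_test <- function(prop) out$tests[out$tests$property == prop, ]
  len <- get_test("length")
  m_len <- out$table$mean[out$table$property == "length"]
  names(m_len) <- out$table$set[out$table$property == "length"]
  expect_gt(m_len[["CTP_LIKE"]], m_len[["MTP_LIKE"]])
  expect_lt(len$p_value, 0.01)

  hf <- out$table$mean[out$table$property == "helix_fraction"]
  names(hf) <- out$table$set[out$table$property == "helix_fraction"]
  expect_gt(hf[["MTP_LIKE"]], hf[["CTP_LIKE"]])
  expect_lt(get_test("helix_fraction")$p_value, 0.01)

  up <- out$table$mean[out$table$property == "upstream_length"]
  names(up) <- out$table$set[out$table$property == "upstream_length"]
  expect_gt(up[["CTP_LIKE"]], up[["MTP_LIKE"]])

  # one-sided direction carried from a reference pair
  out1 <- tpPropertyTable(metrics, features, sets,
                          reference_pair = c("CTP_LIKE", "MTP_LIKE"),
                          one_sided_pair = c("CTP_LIKE", "MTP_LIKE"))
  len1 <- out1$tests[out1$tests$property == "length", ]
  expect_identical(len1$test, "T_ONE_SIDED")
  expect_identical(len1$direction, "greater")

  # single-set input: table only, no tests, no error
  single <- tpPropertyTable(metrics, features,
                            sets[sets$set == "MTP_LIKE", ])
  expect_null(single$tests)
})
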