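# Independent double-loop ACC oracle.
oracle_acc <- function(seq, z = zScaleTable(), max_lag = 4) {
  res <- strsplit(seq, "")[[1]]
  N <- length(res)
  out <- c()
  for (j in 1:3) for (k in 1:3) for (d in 1:max_lag) {
    s <- 0
    for (i in 1:(N - d)) s <- s + z[res[i], j] * z[res[i + d], k]
    out <- c(out, s / (N - d))
  }
  out
}

test_that("ACC terms: closed form, count and oracle agreement", {
  z <- zScaleTable()
  # homopolymer closed form: value(j,k,d) = z_j(A) * z_k(A)
  v <- accVector("AAAAAA")
  for (j in 1:3) for (k in 1:3) for (d in 1:4)
    expect_equal(v[[paste("acc", j, k, d, sep = "_")]],
                 z["A", j] * z["A", k], tolerance = 1e-12)
  expect_identical(length(v), 36L)
  expect_identical(names(v)[1:5],
                   c("acc_1_1_1", "acc_1_1_2", "acc_1_1_3", "acc_1_1_4",
                     "acc_1_2_1"))
  # random 12-mer against the double-loop oracle
  chimeraTP:::withSeed(31, {
    for (k in 1:25) {
      s <- random_seq(12)
      expect_equal(unname(accVector(s)), oracle_acc(s), tolerance = 1e-12)
    }
  })
  expect_error(accVector("ACDE"), "at least max_lag \\+ 1")
  # centered variant subtracts within-sequence scale means
  s <- "ACDKLMNPQRST"
  res <- strsplit(s, "")[[1]]
  zc <- sweep(z[res, ], 2, colMeans(z[res, ]))
  manual <- sum(zc[1:11, 1] * zc[2:12, 1]) / 11
  expect_equal(unname(accVector(s, centered = TRUE)["acc_1_1_1"]), manual,
               tolerance = 1e-12)
})

test_that("ACC is order-sensitive for cross terms", {
  fwd <- accVector("KKKKAAAALLLL")
  rev <- accVector("LLLLAAAAKKKK")
  expect_gt(max(abs(fwd - rev)), 1e-6)
})

test_that("barycenter distances follow the Euclidean definition", {
  p <- PeptideSet(c(a = "GIGKFLKSAKKF"))
  ref <- PeptideSet(c(r1 = "GIGKFLKSAKKF", r2 = "GIGKFLKSAKKF"))
  d <- tpBarycenterDistance(p, ref)
  expect_equal(d$tp_distance, 0)

  ref2 <- random_peptides(2, min_len = 12, max_len = 20, seed = 33)
  q <- random_peptides(3, min_len = 12, max_len = 20, seed = 34)
  d2 <- tpBarycenterDistance(q, ref2)
  bary <- colMeans(accMatrix(ref2))
  manual <- sqrt(rowSums(sweep(accMatrix(q), 2, bary)^2))
  expect_equal(d2$tp_distance, unname(manual), tolerance = 1e-12)
  expect_true(all(d2$tp_distance >= 0))
  expect_error(tpBarycenterDistance(q, ref2[0]), "empty")
})

test_that("matched composition classes sit closer to their own barycenter", {
  d <- generateLabeledDataset(list(
    generatorSpec("HARAMP_LIKE", n = 20, seed = 41),   # K-rich
    generatorSpec("MTP_LIKE", n = 20, seed = 42),      # R-rich
    generatorSpec("HARAMP_LIKE", n = 20, seed = 43),
    generatorSpec("MTP_LIKE", n = 20, seed = 44)))
  k_ref <- d$peptides$HARAMP_LIKE[1:20]
  r_ref <- d$peptides$MTP_LIKE[1:20]
  k_query <- d$peptides$HARAMP_LIKE[21:40]
  r_query <- d$peptides$MTP_LIKE[21:40]
  expect_lt(mean(tpBarycenterDistance(k_query, k_ref)$tp_distance),
            mean(tpBarycenterDistance(k_query, r_ref)$tp_distance))
  expect_lt(mean(tpBarycenterDistance(r_query, r_ref)$tp_distance),
            mean(tpBarycenterDistance(r_query, k_ref)$tp_distance))
})

test_that("Boman index is the per-residue mean of the scale", {
  sc <- bomanScale()
  expect_equal(unname(bomanIndex("R")), sc[["R"]])
  p <- "GIGKFLKS"
  expect_equal(unname(bomanIndex(paste0(p, p))), unname(bomanIndex(p)),
               tolerance = 1e-12)
  chimeraTP:::withSeed(35, {
    for (k in 1:20) {
      s <- random_seq(10)
      expect_equal(unname(bomanIndex(s)),
                   sum(sc[strsplit(s, "")[[1]]]) / 10, tolerance = 1e-12)
    }
  })
})

test_that("charge profiles and net charge follow the charge rules", {
  cp <- chargeProfile("KKKK", window = 4)
  expect_identical(nrow(cp$profile), 1L)
  expect_equal(cp$profile$charge, 4)
  expect_equal(cp$net_charge, 4)
  expect_equal(chargeProfile("KDKD")$net_charge, 0)
  expect_equal(chargeProfile("HHHH", his_charge = 1)$net_charge, 4)
  # truncated C-terminal windows are dropped
  expect_identical(nrow(chargeProfile("KRDEKRDEKR", window = 4)$profile), 7L)
  # K -> R substitution preserves net charge
  set <- random_peptides(20, seed = 36)
  for (i in seq_len(length(set))) {
    p <- set[i]
    expect_equal(chargeProfile(substituteBasic(p, "K_TO_R"))$net_charge,
                 chargeProfile(p)$net_charge)
  }
})

test_that("amino-acid frequencies partition to one and recover contrasts", {
  f <- aaFrequencyTable(PeptideSet(c(p = "KKRR")))
  expect_equal(f$freq_K, 0.5)
  expect_equal(f$freq_R, 0.5)

  set <- random_peptides(30, seed = 37)
  tab <- aaFrequencyTable(list(fuzz = set))
  expect_equal(rowSums(tab[, paste0("freq_", AA20)]),
               rep(1, 30), tolerance = 1e-12, ignore_attr = TRUE)

  d <- generateLabeledDataset(list(
    generatorSpec("HARAMP_LIKE", n = 30, seed = 45),
    generatorSpec("MTP_LIKE", n = 30, seed = 46)))
  tab2 <- aaFrequencyTable(list(haramp = d$peptides$HARAMP_LIKE,
                                tp = d$peptides$MTP_LIKE),
                           baseline = c(freq_K = 0.052, freq_R = 0.057))
  med <- function(set, col) median(tab2[tab2$set == set, col])
  expect_gt(med("haramp", "freq_K"), med("tp", "freq_K"))
  expect_gt(med("tp", "freq_R"), med("haramp", "freq_R"))
  expect_named(attr(tab2, "baseline"), c("freq_K", "freq_R"))
})
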