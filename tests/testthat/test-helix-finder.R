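# Brute-force hydrophobic-moment oracle: direct complex summation.
oracle_moment <- function(window, scale = helixHydrophobicityScale(),
                          delta = 100) {
  res <- strsplit(window, "")[[1]]
  z <- sum(scale[res] * exp(1i * (seq_along(res) - 1) * delta * pi / 180))
  Mod(z) / length(res)
}

test_that("hydrophobic moment matches the complex-sum oracle", {
  # zero-weight window
  expect_equal(hydrophobicMoment(strrep("G", 12))$mu, 0)
  # single repeated residue, N = 18: mu = |h| * |sum e^{i n delta}| / 18
  h <- helixHydrophobicityScale()[["L"]]
  geo <- Mod(sum(exp(1i * (0:17) * 100 * pi / 180)))
  expect_equal(hydrophobicMoment(strrep("L", 18))$mu, abs(h) * geo / 18,
               tolerance = 1e-12)
  # random windows
  chimeraTP:::withSeed(11, {
    for (k in 1:100) {
      w <- random_seq(sample(2:30, 1))
      expect_equal(hydrophobicMoment(w)$mu, oracle_moment(w),
                   tolerance = 1e-12)
    }
  })
  expect_error(hydrophobicMoment("AXA"), "not in scale")
  expect_error(hydrophobicMoment("A"), "at least 2")
})

test_that("moment is not shift-invariant unless the wheel sum vanishes", {
  scale <- helixHydrophobicityScale()
  shifted <- scale + 1
  chimeraTP:::withSeed(12, {
    # N = 18 spans exactly five turns, so sum(e^{i n delta}) = 0 and a
    # constant shift cannot change the moment
    w18 <- random_seq(18)
    expect_equal(hydrophobicMoment(w18, shifted)$mu,
                 hydrophobicMoment(w18, scale)$mu, tolerance = 1e-12)
    # at other lengths the shift generically changes the moment, and the
    # shifted value still matches the oracle
    changed <- 0
    for (k in 1:100) {
      w <- random_seq(sample(c(5:17, 19:25), 1))
      m0 <- hydrophobicMoment(w, scale)$mu
      m1 <- hydrophobicMoment(w, shifted)$mu
      expect_equal(m1, oracle_moment(w, shifted), tolerance = 1e-12)
      if (abs(m1 - m0) > 1e-9) changed <- changed + 1
    }
    expect_gt(changed, 90)
  })
})

test_that("poly-serine has no amphipathic helix (exhaustive window scan)", {
  seq <- strrep("S", 30)
  cfg <- helixConfig()
  # oracle: every window of length >= 9 is below the moment threshold
  mus <- unlist(lapply(9:30, function(len)
    vapply(1:(30 - len + 1), function(s)
      oracle_moment(substr(seq, s, s + len - 1)), numeric(1))))
  expect_true(all(mus < cfg$mu_min))
  prof <- findAmphipathicHelices(seq)
  expect_identical(nrow(helixAnnotations(prof)), 0L)
  expect_equal(helixFraction(prof), 0)
  expect_true(prof@helix_free)
  expect_equal(upstreamLength(prof), 30)
})

test_that("designed amphipathic peptides are recovered", {
  p <- makeAmphipathicPeptide(18, arc = 180, seed = 3)
  prof <- findAmphipathicHelices(p)[[1]]
  ann <- helixAnnotations(prof)
  expect_identical(nrow(ann), 1L)
  expect_gte(ann$end - ann$start + 1L, 0.9 * 18)

  # two designed segments separated by a 10-residue poly-S spacer
  a <- aaSequences(makeAmphipathicPeptide(18, seed = 4))[[1]]
  b <- aaSequences(makeAmphipathicPeptide(18, seed = 5))[[1]]
  two <- paste0(a, strrep("S", 10), b)
  prof2 <- findAmphipathicHelices(two)
  ann2 <- helixAnnotations(prof2)
  expect_gte(nrow(ann2), 2L)
  midpoint <- 18 + 5
  expect_true(all(ann2$end < midpoint | ann2$start > midpoint))
})

test_that("annotations never overlap nor exceed bounds on fuzzed peptides", {
  set <- random_peptides(300, min_len = 9, max_len = 60, seed = 7)
  profs <- findAmphipathicHelices(set)
  for (p in profs) {
    a <- helixAnnotations(p)
    if (!nrow(a)) next
    expect_true(all(a$start >= 1 & a$end <= p@evaluation_limit))
    if (nrow(a) > 1)
      expect_true(all(a$start[-1] > a$end[-nrow(a)]))
  }
})

test_that("masking annotated spans removes all annotations inside them", {
  set <- random_peptides(120, min_len = 15, max_len = 50, seed = 8)
  profs <- findAmphipathicHelices(set)
  seqs <- aaSequences(set)
  for (id in names(profs)) {
    a <- helixAnnotations(profs[[id]])
    if (!nrow(a)) next
    masked <- seqs[[id]]
    for (i in seq_len(nrow(a)))
      substr(masked, a$start[i], a$end[i]) <-
        strrep("S", a$end[i] - a$start[i] + 1L)
    again <- helixAnnotations(findAmphipathicHelices(masked))
    if (!nrow(again)) next
    # no re-annotation lies inside a masked span
    for (i in seq_len(nrow(a)))
      expect_false(any(again$start >= a$start[i] & again$end <= a$end[i]))
  }
})

test_that("raising the moment threshold never annotates more residues", {
  set <- random_peptides(150, min_len = 12, max_len = 55, seed = 9)
  totals <- vapply(c(0.35, 0.45, 0.55), function(thr) {
    profs <- findAmphipathicHelices(set, helixConfig(mu_min = thr))
    sum(vapply(profs, function(p) {
      a <- helixAnnotations(p)
      if (nrow(a)) sum(a$end - a$start + 1L) else 0L
    }, integer(1)))
  }, numeric(1))
  expect_true(all(diff(totals) <= 0))
})

test_that("helix metrics follow the stated conventions", {
  full <- makeAmphipathicPeptide(20, seed = 10, id = "full")
  m <- helixMetrics(findAmphipathicHelices(full))
  expect_equal(m$helix_fraction, 1)
  expect_equal(m$upstream_length, 0)

  none <- helixMetrics(findAmphipathicHelices(strrep("S", 25)))
  expect_equal(none$helix_fraction, 0)
  expect_equal(none$upstream_length, 25)
  expect_true(none$helix_free)

  # cleavage limit restricts the evaluated region for TP roles
  tp <- PeptideSet(c(tp = paste0(aaSequences(full)[[1]], strrep("S", 30))),
                   role = "mTP", cleavage = 20)
  mt <- helixMetrics(findAmphipathicHelices(tp))
  expect_identical(mt$length, 20L)
  expect_equal(mt$helix_fraction, 1)
})

test_that("upstream stretches are longer in cTP-like than mTP-like sets", {
  d <- generateLabeledDataset(list(
    generatorSpec("MTP_LIKE", n = 25, seed = 21),
    generatorSpec("CTP_LIKE", n = 25, seed = 22)))
  met_m <- helixMetrics(findAmphipathicHelices(d$peptides$MTP_LIKE))
  met_c <- helixMetrics(findAmphipathicHelices(d$peptides$CTP_LIKE))
  expect_gt(mean(met_c$upstream_length), mean(met_m$upstream_length))
})

test_that("external annotations override prediction and are labelled", {
  p <- PeptideSet(c(tp = strrep("S", 40)), role = "cTP", cleavage = 35)
  ext <- data.frame(peptide_id = "tp", start = 10, end = 25)
  prof <- findAmphipathicHelices(p, external = ext)[["tp"]]
  a <- helixAnnotations(prof)
  expect_identical(a$source, "EXTERNAL")
  expect_identical(c(a$start, a$end), c(10, 25))
  expect_equal(helixFraction(prof), 16 / 35)
})
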