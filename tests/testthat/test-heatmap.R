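# a ContactMap built by hand: one chromosome, explicit triples
mkContacts <- function(bin_i, bin_j, count, res = 1000L, chrom = "chr1") {
  new("ContactMap",
      contacts = data.frame(chrom = chrom, bin_i = as.integer(pmin(bin_i, bin_j)),
                            bin_j = as.integer(pmax(bin_i, bin_j)),
                            count = count, stringsAsFactors = FALSE),
      resolution = res)
}

test_that("distance score is the midrank percentile within a stratum-distance", {
  # one TAD of 4 bins: distance-1 population is (0,1),(1,2),(2,3)
  tads <- toyTads(0, 4000)
  cm <- mkContacts(c(0, 1, 2), c(1, 2, 3), c(10, 5, 1))
  sc <- contactTable(scoreContacts(cm, tads = tads))
  expect_equal(sc$dscore[sc$count == 10], 0)
  expect_equal(sc$dscore[sc$count == 5], 1 / 3)
  expect_equal(sc$dscore[sc$count == 1], 2 / 3, tolerance = 1e-12)
  # all counts equal at a distance -> symmetric midrank 0.5*(N-1)/N
  cmEq <- mkContacts(c(0, 1, 2), c(1, 2, 3), c(4, 4, 4))
  scEq <- contactTable(scoreContacts(cmEq, tads = tads))
  expect_true(all(scEq$dscore == 0.5 * 2 / 3))
  # no tie-heavy contact can reach an interaction call at theta = 0.15
  expect_true(all(contactTable(classifyContacts(
    scoreContacts(cmEq, tads = tads), 0.15))$state == "no_class"))
})

test_that("unrecorded bin pairs enter the population as zero counts", {
  # TAD of 5 bins: distance 1 has 4 pairs but only 2 recorded
  tads <- toyTads(0, 5000)
  cm <- mkContacts(c(0, 2), c(1, 3), c(7, 3))
  sc <- contactTable(scoreContacts(cm, tads = tads))
  # population at distance 1: {7, 3, 0, 0}
  expect_equal(sc$dscore[sc$count == 7], bruteDscore(7, c(7, 3, 0, 0)))
  expect_equal(sc$dscore[sc$count == 3], bruteDscore(3, c(7, 3, 0, 0)))
})

test_that("distance score matches the brute-force oracle on random small maps", {
  set.seed(31)
  for (trial in 1:6) {
    n <- sample(4:10, 1)   # up to 10x10 per-TAD matrix
    tads <- toyTads(0, n * 1000)
    ii <- c(); jj <- c()
    for (d in 1:(n - 1)) {
      pick <- which(runif(n - d) < 0.7)
      ii <- c(ii, pick - 1L); jj <- c(jj, pick - 1L + d)
    }
    if (!length(ii)) next
    cm <- mkContacts(ii, jj, rpois(length(ii), 6))
    sc <- contactTable(scoreContacts(cm, tads = tads))
    for (r in seq_len(nrow(sc))) {
      d <- sc$bin_j[r] - sc$bin_i[r]
      rec <- sc$count[sc$bin_j - sc$bin_i == d]
      pop <- c(rec, rep(0, (n - d) - length(rec)))
      expect_equal(sc$dscore[r], bruteDscore(sc$count[r], pop),
                   info = paste("trial", trial, "row", r))
    }
    # rank scores are invariant under rescaling all counts
    cm2 <- mkContacts(ii, jj, contactTable(cm)$count * 17)
    expect_equal(contactTable(scoreContacts(cm2, tads = tads))$dscore, sc$dscore)
    # monotone: within a distance, larger count never scores higher
    for (d in unique(sc$bin_j - sc$bin_i)) {
      sub <- sc[sc$bin_j - sc$bin_i == d, ]
      o <- order(sub$count, decreasing = TRUE)
      expect_true(all(diff(sub$dscore[o]) >= 0))
    }
  }
})

test_that("three-class thresholding follows the theta / 1 - theta rule", {
  tads <- toyTads(0, 30000)
  cm <- mkContacts(0:28, 1:29, 29:1)  # distinct counts at distance 1
  sc <- scoreContacts(cm, tads = tads)
  cl <- contactTable(classifyContacts(sc, 0.15))
  expect_equal(cl$state[cl$dscore <= 0.15][1], "interaction")
  expect_equal(cl$state[cl$dscore >= 0.85][1], "non_interaction")
  expect_equal(cl$state[abs(cl$dscore - 0.5) < 0.1][1], "no_class")
  # theta = 0.5 cancels the no-class band
  cl5 <- contactTable(classifyContacts(sc, 0.5))
  expect_false(any(cl5$state == "no_class"))
  expect_error(classifyContacts(sc, 0), "theta")
  expect_error(classifyContacts(sc, 0.6), "theta")
})

test_that("interaction fraction per stratum tracks theta with distinct counts", {
  # fully recorded distances with all-distinct counts
  tads <- toyTads(0, 40000)
  n <- 40
  set.seed(5)
  ii <- c(); jj <- c(); cc <- c()
  for (d in 1:3) {
    ii <- c(ii, 0:(n - 1 - d)); jj <- c(jj, d:(n - 1))
    cc <- c(cc, sample.int(1000, n - d))
  }
  cm <- mkContacts(ii, jj, cc)
  cl <- contactTable(classifyContacts(scoreContacts(cm, tads = tads), 0.15))
  for (d in 1:3) {
    sub <- cl[cl$bin_j - cl$bin_i == d, ]
    frac <- mean(sub$state == "interaction")
    expect_lte(abs(frac - 0.15), 1 / nrow(sub))
  }
})

test_that("classified contacts convert to labeled pairs, dropping no-class", {
  tads <- toyTads(0, 10000)
  sft <- toySft(list(A = 1:10))
  cm <- mkContacts(c(0, 1, 2, 0, 3), c(1, 2, 3, 5, 7), c(50, 40, 30, 20, 10))
  sc <- scoreContacts(cm, tads = tads)
  # force a mix of states by hand-picking theta after inspecting scores
  cl <- classifyContacts(sc, 0.25)
  states <- contactTable(cl)$state
  pairs <- contactsToPairs(cl, sft, tads)
  expect_equal(nrow(pairs), sum(states != "no_class"))
  expect_equal(sum(pairs$label == "positive"), sum(states == "interaction"))
  expect_equal(sum(pairs$label == "negative"), sum(states == "non_interaction"))
  expect_true(all(c("max_A_height", "min_A_height", "genomic_distance")
                  %in% names(pairs)))
  # theta = 0.5: every in-TAD off-diagonal contact becomes a labeled pair
  cl5 <- classifyContacts(sc, 0.5)
  expect_equal(nrow(contactsToPairs(cl5, sft, tads)), nrow(contactTable(cm)))
  # resolution mismatch is an integrity error
  sft5k <- toySft(list(A = 1:10), res = 5000L)
  expect_error(contactsToPairs(cl, sft5k, tads), "resolution")
})

test_that("chromosome-level strata use the whole-chromosome bin population", {
  cs <- c(chr1 = 10000)
  cm <- mkContacts(c(0, 3), c(1, 4), c(9, 2))
  sc <- contactTable(scoreContacts(cm, chromSizes = cs, stratum = "chromosome"))
  # distance-1 population over a 10-bin chromosome: {9, 2, 0 x7}
  expect_equal(sc$dscore[sc$count == 9], bruteDscore(9, c(9, 2, rep(0, 7))))
  expect_error(scoreContacts(mkContacts(0, 12, 5), chromSizes = cs,
                             stratum = "chromosome"), "beyond")
})
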