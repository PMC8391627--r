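test_that("score summary uses the population variance", {
  expect_equal(score_summary(c(2, 2, 2, 2)), list(EX = 2, VX = 0))
  expect_equal(score_summary(c(1, 3)), list(EX = 2, VX = 1))
  expect_equal(score_summary(c(5, 3, 2, 1)), list(EX = 2.75, VX = 2.1875))
  expect_error(score_summary(numeric(0)), "empty")
})

test_that("the enrichment statistic contrasts hit and non-hit scores", {
  scores <- c(gA = 5, gB = 3, gC = 2, gD = 1, gE = 10, gF = 4)
  flags <- c(gA = 1, gB = 0, gC = 1, gD = 0, gE = 1, gF = 0)
  G <- c("gA", "gB", "gC", "gD")
  expect_equal(sdgq(G, flags, scores), (5 + 2) - (3 + 1))
  # every gene in G hit: the statistic is the full score sum
  all_hit <- c(gA = 1, gB = 1, gC = 1, gD = 1, gE = 0, gF = 0)
  expect_equal(sdgq(G, all_hit, scores), 5 + 3 + 2 + 1)
  # constant scores collapse to c * (2 NGQ - n)
  const <- setNames(rep(2.5, 6), names(scores))
  expect_equal(sdgq(G, flags, const), 2.5 * (2 * 2 - 4))
  # literal form contrasts hits in G against hits in the complement
  expect_equal(sdgq(G, flags, scores, form = "literal"), (5 + 2) - 10)
  expect_error(sdgq(names(scores), flags, scores, form = "literal"),
               "complement")
})

test_that("analytic null moments substitute correctly and reject degeneracies", {
  # E(NGQ) = 2 at N=100, V=20, n=10
  expect_equal(e_sdgq(EX = 1, N = 100, V = 20, n = 10), 2 * 2 - 10)
  expect_equal(e_sdgq(EX = 2, N = 100, V = 20, n = 10), -12)
  # balanced coverage: E(NGQ) = n/2 makes the expectation vanish
  expect_equal(e_sdgq(EX = 1.7, N = 100, V = 50, n = 10), 0)
  vn <- ngq_var(100, 20, 10)
  expect_equal(v_sdgq(EX = 1, VX = 2, N = 100, V = 20, n = 10),
               4 * (2 / 9 * (2 * 8 - vn) + vn), tolerance = 1e-12)
  # constant scores: only the hit-count variance term survives
  expect_equal(v_sdgq(EX = 3, VX = 0, N = 100, V = 20, n = 10),
               4 * 9 * vn, tolerance = 1e-12)
  expect_error(v_sdgq(EX = 1, VX = 1, N = 100, V = 20, n = 1), "at least 2")
  expect_error(v_sdgq(EX = 0, VX = 0, N = 100, V = 20, n = 10), "degenerate")
})

test_that("Z and p behave as a one-sided upper-tail normal test", {
  expect_equal(z_statistic(5, 5, 2), 0)
  expect_equal(z_statistic(13 + sqrt(13), 13, 13), 1)
  expect_error(z_statistic(1, 0, 0), "positive")
  expect_equal(z_pvalue(0), 0.5)
  expect_lt(abs(z_pvalue(1.6449) - 0.05), 1e-4)
  expect_equal(z_pvalue(50), 0)
})

test_that("Monte-Carlo null moments reproduce the analytic moments", {
  # The null of the derivation: the hit count of a random gene set is
  # hypergeometric and hit status falls uniformly within the set. The
  # analytic moments condition on the set's scores, so the oracle fixes
  # the score values of G and randomises the hits.
  set.seed(77)
  N <- 200; V <- 60; n <- 20
  d_G <- abs(rnorm(n))
  sm <- score_summary(d_G)
  draws <- vapply(seq_len(1e5), function(b) {
    v <- rhyper(1, V, N - V, n)
    hit <- seq_len(n) %in% sample.int(n, v)
    sum(d_G[hit]) - sum(d_G[!hit])
  }, numeric(1))
  E_an <- e_sdgq(sm$EX, N, V, n)
  V_an <- v_sdgq(sm$EX, sm$VX, N, V, n)
  expect_lt(abs(mean(draws) - E_an) / abs(E_an), 0.01)
  expect_lt(abs(var(draws) - V_an) / V_an, 0.02)

  # marginally over random sets (scores redrawn per set) the expectation
  # with the population score mean still holds
  set.seed(2024)
  scores <- abs(rnorm(N))
  draws2 <- vapply(seq_len(5e4), function(b) {
    d <- scores[sample.int(N, n)]
    v <- rhyper(1, V, N - V, n)
    hit <- seq_len(n) %in% sample.int(n, v)
    sum(d[hit]) - sum(d[!hit])
  }, numeric(1))
  E_pop <- e_sdgq(mean(scores), N, V, n)
  expect_lt(abs(mean(draws2) - E_pop) / abs(E_pop), 0.02)
})

test_that("the fitted test is scale-equivariant and reduces to the hypergeometric count", {
  fix <- covered_universe(300, 90)
  set.seed(13)
  scores <- random_scores(fix$universe)
  f1 <- qtl_gse(fix$universe, fix$qtls, scores, sizes = c(30, 60))
  f2 <- qtl_gse(fix$universe, fix$qtls, 7 * scores, sizes = c(30, 60))
  expect_equal(f2$results$SDGQ, 7 * f1$results$SDGQ, tolerance = 1e-12)
  expect_equal(f2$results$E_SDGQ, 7 * f1$results$E_SDGQ, tolerance = 1e-12)
  expect_equal(f2$results$V_SDGQ, 49 * f1$results$V_SDGQ, tolerance = 1e-12)
  expect_equal(f2$results$Z, f1$results$Z, tolerance = 1e-12)
  expect_equal(f2$results$p_value, f1$results$p_value, tolerance = 1e-12)
  # normalization flag changes nothing statistically
  f3 <- qtl_gse(fix$universe, fix$qtls, scores, sizes = c(30, 60),
                normalize_scores = TRUE)
  expect_equal(f3$results$Z, f1$results$Z, tolerance = 1e-12)

  # constant scores: Z must equal the standardised hypergeometric count
  const <- setNames(rep(4, 300), fix$universe$gene_id)
  fc <- qtl_gse(fix$universe, fix$qtls, const, sizes = c(30, 60))
  zh <- (fc$results$NGQ -
           vapply(fc$results$size, function(n) ngq_mean(300, 90, n), numeric(1))) /
    sqrt(vapply(fc$results$size, function(n) ngq_var(300, 90, n), numeric(1)))
  expect_equal(fc$results$Z, zh, tolerance = 1e-12)
})

test_that("adding a hit to a high-score gene never decreases the statistic", {
  set.seed(17)
  fix <- covered_universe(100, 30)
  scores <- random_scores(fix$universe)
  flags <- qtl_hit_flags(fix$universe, fix$qtls)
  G <- names(scores)[1:40]
  s0 <- sdgq(G, flags, scores)
  for (g in names(which(flags[G] == 0))[1:5]) {
    flags2 <- flags
    flags2[g] <- 1L
    expect_gte(sdgq(G, flags2, scores), s0)
  }
})

test_that("degenerate designs are refused with explanatory errors", {
  gu <- tiled_universe(50)
  empty <- qtl_set(data.frame(qtl_id = character(), trait = character(),
                              chrom = character(), start = integer(),
                              end = integer()))
  scores <- random_scores(gu)
  expect_error(suppressWarnings(qtl_gse(gu, empty, scores, sizes = 10)),
               "no gene in the universe")
  all_q <- span_qtl(gu, 1, 50)
  expect_error(qtl_gse(gu, all_q, scores, sizes = 10), "every gene")
  part <- span_qtl(gu, 1, 20)
  expect_error(qtl_gse(gu, part, scores, sizes = 50), "smaller than")
  expect_error(qtl_gse(gu, part, scores[-1], sizes = 10), "missing from scores")
  expect_error(qtl_gse(gu, part, c(scores, gX = 1), sizes = 10),
               "absent from the universe")
})

test_that("the fit is deterministic and its table internally consistent", {
  fix <- covered_universe(400, 100)
  set.seed(23)
  scores <- random_scores(fix$universe)
  f1 <- qtl_gse(fix$universe, fix$qtls, scores, sizes = c(40, 80, 120))
  f2 <- qtl_gse(fix$universe, fix$qtls, scores, sizes = c(40, 80, 120))
  expect_identical(f1$results, f2$results)
  r <- f1$results
  expect_true(all(r$NGQ <= pmin(r$size, r$V)))
  expect_true(all(r$NQHits >= r$NGQ))
  expect_true(all(r$p_value >= 0 & r$p_value <= 1))
  expect_true(all(r$adj_p >= r$p_value - 1e-15))
  expect_true(all(r$fdr >= r$p_value - 1e-15))
  expect_s3_class(f1, "qtl_gse")
  expect_output(print(f1), "nested gene set")
  expect_output(print(summary(f1)), "strongest enrichment")
  expect_identical(as.data.frame(f1), r)
})

test_that("literal-form moments come from permutation and give a calibrated Z", {
  set.seed(29)
  fix <- covered_universe(150, 45)
  scores <- random_scores(fix$universe)
  f <- qtl_gse(fix$universe, fix$qtls, scores, sizes = 30, form = "literal",
               B_perm = 3000, seed = 101)
  expect_true(is.finite(f$results$Z))
  # permutation moments should put a typical draw within a few SDs
  expect_lt(abs(f$results$Z), 5)
})
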