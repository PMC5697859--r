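toy_db <- function() {
  chains <- tibble::tibble(
    chain = c("ch1", "ch2", "ch3"),
    aa = c("ALAAAW", "ALAAA", "GGGGG"),
    pb = c("ZZmmZZ", "ZZdZZ", "ZZmZZ")
  )
  build_pentadb(chains, trivial_tier_table(chains$chain))
}

test_that("record extraction counts windows with defined central PBs", {
  # 10 residues, PBs defined at 3..8: every one of the 6 windows kept
  chains <- tibble::tibble(chain = "c", aa = strrep("A", 10),
                           pb = "ZZmmddmmZZ")
  db <- build_pentadb(chains, trivial_tier_table("c"))
  expect_equal(nrow(db$records), 6)
  expect_equal(db$records$position, 1:6)
  expect_identical(db$records$pb, c("m", "m", "d", "d", "m", "m"))
  # single window
  db1 <- build_pentadb(
    tibble::tibble(chain = "c", aa = "AAAAA", pb = "ZZmZZ"),
    trivial_tier_table("c")
  )
  expect_equal(nrow(db1$records), 1)
  # interior Z skips exactly that window
  dbz <- build_pentadb(
    tibble::tibble(chain = "c", aa = strrep("A", 10), pb = "ZZmZddmmZZ"),
    trivial_tier_table("c")
  )
  expect_equal(nrow(dbz$records), 5)
  expect_false(2L %in% dbz$records$position)
  # unknown chain in tier table
  expect_error(
    build_pentadb(tibble::tibble(chain = "nope", aa = "AAAAA", pb = "ZZmZZ"),
                  trivial_tier_table("c")),
    "nope"
  )
})

test_that("exact queries count central PBs over accessible chains", {
  db <- toy_db()
  # ALAAA occurs in ch1 (pos 1, pb m; pos 2 is AAAW-containing) and ch2
  p <- query_exact(db, "ALAAA")
  expect_identical(match_kind(p), "exact")
  expect_identical(p$pb, c("d", "m"))
  expect_identical(p$count, c(1L, 1L))
  # excluding one source chain
  p2 <- query_exact(db, "ALAAA", accessible = c("ch1", "ch3"))
  expect_identical(p2$pb, "m")
  # excluding all
  p3 <- query_exact(db, "ALAAA", accessible = character())
  expect_identical(match_kind(p3), "none")
  expect_equal(nrow(p3), 0)
})

test_that("wildcard queries match the 4-mer prefix with any fifth residue", {
  db <- toy_db()
  p <- query_wildcard(db, "ALAAQ")
  expect_identical(match_kind(p), "wildcard")
  expect_identical(p$pb, c("d", "m"))
  expect_identical(sum(p$count), 2L)
  p2 <- query_wildcard(db, "QQQQQ")
  expect_identical(match_kind(p2), "none")
})

test_that("profiles sum to the number of matching accessible records", {
  fx <- std_fixture()
  db <- fixture_pentadb(fx)
  recs <- tibble::as_tibble(db$records)
  set.seed(33)
  for (k in 1:15) {
    aa5 <- recs$aa5[sample(nrow(recs), 1)]
    acc <- sample(fx$chains$chain, 6)
    p <- query_exact(db, aa5, acc)
    # oracle: linear scan
    expect_equal(sum(p$count),
                 sum(recs$aa5 == aa5 & recs$chain %in% acc))
  }
})

test_that("tier predicates encode identity-below-threshold access", {
  # ch_a and ch_b near-identical; ch_c ~50% to both; ch_d unrelated
  tiers <- tibble::tibble(
    chain = c("ch_a", "ch_b", "ch_c", "ch_d"),
    cluster30 = c("g1", "g1", "g1", "ch_d"),
    cluster40 = c("g1", "g1", "g1", "ch_d"),
    cluster50 = c("g1", "g1", "g1", "ch_d"),
    cluster70 = c("g2", "g2", "ch_c", "ch_d"),
    cluster90 = c("g2", "g2", "ch_c", "ch_d"),
    cluster95 = c("g2", "g2", "ch_c", "ch_d"),
    cluster100 = c("ch_a", "ch_b", "ch_c", "ch_d")
  )
  # ch_b shares >= 95% identity with ch_a: inaccessible below 100
  expect_false("ch_b" %in% accessible_chains(tiers, "ch_a", 95))
  expect_true("ch_b" %in% accessible_chains(tiers, "ch_a", 100))
  # ch_c shares >= 30 but < 70: accessible at 70+, not at 30..50
  expect_false("ch_c" %in% accessible_chains(tiers, "ch_a", 50))
  expect_true("ch_c" %in% accessible_chains(tiers, "ch_a", 70))
  # the query itself is never accessible
  for (t in c(30, 95, "full")) {
    expect_false("ch_a" %in% accessible_chains(tiers, "ch_a", t))
  }
  expect_identical(sort(accessible_chains(tiers, "ch_a", "full")),
                   c("ch_b", "ch_c", "ch_d"))
  expect_error(accessible_chains(tiers, "ch_a", 60), "threshold")
  # co-clustering complement
  expect_identical(coclustered_chains(tiers, "ch_a", 95), "ch_b")
  expect_identical(sort(coclustered_chains(tiers, "ch_a", 30)),
                   c("ch_b", "ch_c"))
})

test_that("accessible sets grow monotonically with the threshold", {
  fx <- std_fixture()
  ths <- c(30, 40, 50, 70, 90, 95, 100)
  for (q in fx$chains$chain[c(1, 6, 12)]) {
    sets <- lapply(ths, accessible_chains, tiers = fx$tiers, query_chain = q)
    full <- accessible_chains(fx$tiers, q, "full")
    for (i in seq_along(sets)[-1]) {
      expect_true(all(sets[[i - 1]] %in% sets[[i]]))
    }
    expect_true(all(sets[[length(sets)]] %in% full))
  }
})

test_that("the store persists and reloads without loss", {
  fx <- std_fixture()
  db <- fixture_pentadb(fx)
  dir <- withr::local_tempdir()
  write_pentadb(db, dir)
  db2 <- read_pentadb(dir)
  expect_equal(pentadb_stats(db2), pentadb_stats(db))
  expect_equal(
    tibble::as_tibble(db$records)[order(db$records$chain,
                                        db$records$position), 1:4],
    tibble::as_tibble(db2$records)[order(db2$records$chain,
                                         db2$records$position), 1:4]
  )
  # queries behave identically after reload
  p1 <- query_exact(db, db$records$aa5[1])
  p2 <- query_exact(db2, db$records$aa5[1])
  expect_equal(p1, p2)
})

test_that("the toy clusterer recovers hand-computable cluster structures", {
  skip_if_not_installed("Biostrings")
  s <- c(a = "ACDEFGHIKL", b = "ACDEFGHIKL", c = "ACDEFWWWWW")
  tiers <- toy_identity_clusterer(s)
  # identical pair: together at every threshold
  for (col in paste0("cluster", c(30, 40, 50, 70, 90, 95, 100))) {
    expect_identical(tiers[[col]][1], tiers[[col]][2])
  }
  # c is 50% identical to a and b: merged at 30..50, separate at 70+
  expect_identical(tiers$cluster50[3], tiers$cluster50[1])
  expect_false(tiers$cluster70[3] == tiers$cluster70[1])
  # fully dissimilar sequences never cluster
  s2 <- c(x = "AAAAAAAAAA", y = "WWWWWWWWWW")
  t2 <- toy_identity_clusterer(s2)
  expect_false(t2$cluster30[1] == t2$cluster30[2])
  # empty input
  t0 <- toy_identity_clusterer(character())
  expect_equal(nrow(t0), 0)
})
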