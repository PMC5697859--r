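test_that("profile collection slides, prefers exact and falls back", {
  chains <- tibble::tibble(
    chain = c("s1", "s2"),
    aa = c("ALAAAW", "ALAACDE"),
    pb = c("ZZmmZZ", "ZZdddZZ")
  )
  db <- build_pentadb(chains, trivial_tier_table(chains$chain))
  profs <- collect_profiles("ALAAA", db)
  expect_equal(nrow(profs), 1)
  expect_identical(profs$match_kind, "exact")
  # exact hit exists: wildcard candidates (d from ALAAC) must not leak in
  expect_identical(profs$profile[[1]]$pb, "m")
  # wildcard fallback on a 5-mer absent from the store
  profs2 <- collect_profiles("ALAAQ", db)
  expect_identical(profs2$match_kind, "wildcard")
  expect_setequal(profs2$profile[[1]]$pb, c("m", "d"))
  # no match at all
  profs3 <- collect_profiles("WWWWW", db)
  expect_identical(profs3$match_kind, "none")
  expect_error(collect_profiles("ALA", db), "5 residues")
})

test_that("majority rule picks the top count and flags ties", {
  pr <- predict_majority(make_profiles(list(
    c(m = 3, d = 1),
    c(c = 2, d = 2),
    character(0)
  )))
  d <- tidy(pr)
  expect_identical(d$chosen, c("m", "c", "Z"))
  expect_identical(d$tie, c(FALSE, TRUE, FALSE))
  expect_identical(d$tied[[2]], c("c", "d"))
  # predicted string: ZZ + central positions 3..5 + ZZ over length 7
  expect_identical(pr$pb, "ZZmcZZZ")
})

test_that("S2 sums tri-PB odds over neighbour candidate combinations", {
  # single candidates each side: one-term sum
  odds <- c(amd = 0.7)
  expect_equal(s2_scores("m", "a", "d", odds), c(m = 0.7))
  # uniform table: |prev| x |next| terms
  u <- uniform_tripb(0.25)
  s2 <- s2_scores(c("m", "d"), c("a", "c"), c("e", "f", "h"), u)
  expect_equal(unname(s2), rep(0.25 * 6, 2))
  # absent neighbours widen to the full alphabet
  s2t <- s2_scores("m", NULL, "d", u)
  expect_equal(unname(s2t), 0.25 * 16)
  # brute-force oracle on random small tables
  set.seed(14)
  for (k in 1:20) {
    cand <- list(sample(letters[1:16], sample(1:4, 1)),
                 sample(letters[1:16], sample(1:4, 1)),
                 sample(letters[1:16], sample(1:4, 1)))
    tbl <- uniform_tripb(0)
    tbl[sample(length(tbl), 300)] <- runif(300)
    got <- s2_scores(cand[[2]], cand[[1]], cand[[3]], tbl)
    for (y in cand[[2]]) {
      acc <- 0
      for (x in cand[[1]]) for (z in cand[[3]]) {
        acc <- acc + tbl[[paste0(x, y, z)]]
      }
      expect_equal(got[[y]], acc)
    }
  }
})

test_that("hybrid selection equals exhaustive S1 x S2 enumeration", {
  set.seed(77)
  lets <- letters[1:16]
  for (case in 1:100) {
    n_win <- sample(3:6, 1)
    maps <- lapply(seq_len(n_win), function(i) {
      k <- sample(1:4, 1)
      stats::setNames(sample(1:9, k, replace = TRUE), sample(lets, k))
    })
    tbl <- uniform_tripb(0)
    tbl[] <- runif(length(tbl), 0.01, 2) # every motif observed
    profiles <- make_profiles(maps)
    got <- tidy(predict_hybrid(profiles, tbl))$chosen
    # oracle: enumerate every tri-PB product per window
    want <- vapply(seq_len(n_win), function(w) {
      cands <- sort(names(maps[[w]]))
      xs <- if (w > 1) names(maps[[w - 1]]) else lets
      zs <- if (w < n_win) names(maps[[w + 1]]) else lets
      score <- vapply(cands, function(y) {
        s2 <- 0
        for (x in xs) for (z in zs) s2 <- s2 + tbl[[paste0(x, y, z)]]
        maps[[w]][[y]] * s2
      }, numeric(1))
      cands[which.max(score)] # ties broken towards earlier (sorted) letter
    }, "")
    expect_identical(got, want)
  }
})

test_that("hybrid with a constant tri-PB table reduces to the majority rule", {
  set.seed(88)
  u <- uniform_tripb(0.5)
  for (case in 1:100) {
    n_win <- sample(2:7, 1)
    maps <- lapply(seq_len(n_win), function(i) {
      k <- sample(0:4, 1)
      if (k == 0) return(character(0))
      stats::setNames(sample(1:9, k, replace = TRUE),
                      sample(letters[1:16], k))
    })
    profiles <- make_profiles(maps)
    expect_identical(predict_hybrid(profiles, u)$pb,
                     predict_majority(profiles)$pb)
  }
})

test_that("hybrid arithmetic follows S1 x S2 and falls back when all zero", {
  # S1 {c:2, d:1}, S2 {c:0.1, d:0.5}: product favours d
  odds <- c(ace = 0.1, ade = 0.5) # only motifs through c resp. d
  profiles <- make_profiles(list(c(a = 1), c(c = 2, d = 1), c(e = 1)))
  pr <- predict_hybrid(profiles, odds)
  expect_identical(tidy(pr)$chosen[2], "d")
  expect_equal(tidy(pr)$s2[[2]], c(c = 0.1, d = 0.5))
  # no tri-PB observed through the candidates: fall back to majority (c)
  pr0 <- predict_hybrid(profiles, c(mmm = 1))
  expect_identical(tidy(pr0)$chosen[2], "c")
  expect_true(tidy(pr0)$s2_all_zero[2])
})

test_that("chosen letters always come from the candidate profile", {
  fx <- std_fixture()
  db <- fixture_pentadb(fx)
  tripb <- pb_frequency_table(fx$chains$pb, order = 3, mode = "odds")
  q <- fx$chains[5, ]
  for (m in c("majority", "hybrid")) {
    pr <- predict_pb(q$aa, db, method = m, query_chain = q$chain,
                     tripb = tripb)
    d <- tidy(pr)
    for (i in seq_len(nrow(d))) {
      if (d$chosen[i] == "Z") {
        expect_identical(d$match_kind[i], "none")
      } else {
        expect_true(d$chosen[i] %in% d$profile[[i]]$pb)
      }
    }
  }
})

test_that("the tier ladder short-circuits at the closest rung with a hit", {
  chains <- tibble::tibble(
    chain = c("near", "far1", "far2"),
    aa = c("AAAAA", "AAAAA", "CAAAA"),
    pb = c("ZZaZZ", "ZZbZZ", "ZZbZZ")
  )
  tiers <- tibble::tibble(
    chain = chains$chain,
    cluster30 = c("g", "g", "x2"), cluster40 = c("g", "g", "x2"),
    cluster50 = c("g", "g", "x2"), cluster70 = c("g", "g", "x2"),
    cluster90 = c("g", "g", "x2"), cluster95 = c("g", "g", "x2"),
    cluster100 = c("q", "f1", "x2")
  )
  # rung 1 (co-clustered at 100) holds only "near": its 'a' wins outright
  tiers2 <- rbind(tiers, tibble::tibble(
    chain = "query", cluster30 = "g", cluster40 = "g", cluster50 = "g",
    cluster70 = "g", cluster90 = "g", cluster95 = "g", cluster100 = "q"
  ))
  db2 <- build_pentadb(chains, tiers2)
  ladder2 <- tier_ladder(tiers2, "query", start = "100")
  profs <- collect_profiles("AAAAA", db2, ladder = ladder2)
  expect_identical(profs$tier_used, "co100")
  expect_identical(profs$profile[[1]]$pb, "a")
  # miss at rung 1 walks outwards and records the rung used
  profs2 <- collect_profiles("CAAAA", db2, ladder = ladder2)
  expect_identical(profs2$tier_used, "all")
  expect_identical(profs2$profile[[1]]$pb, "b")
})

test_that("a <30 ladder start equals the classic scheme at the 30% cut-off", {
  fx <- std_fixture()
  db <- fixture_pentadb(fx)
  tripb <- pb_frequency_table(fx$chains$pb, order = 3, mode = "odds")
  for (q_idx in c(1, 7)) {
    q <- fx$chains[q_idx, ]
    b8 <- predict_pb(q$aa, db, method = "hybrid", scheme = "noise-filter",
                     start = "<30", query_chain = q$chain, tripb = tripb)
    a8 <- predict_pb(q$aa, db, method = "hybrid", scheme = "classic",
                     threshold = 30, query_chain = q$chain, tripb = tripb)
    expect_identical(b8$pb, a8$pb)
  }
})

test_that("single-tier stores make the two querying schemes coincide", {
  # every chain mutually below 30% identity: the ladder has one effective rung
  fx <- std_fixture()
  keep <- fx$chains$identity == 100 # one chain per family, all unrelated
  chains <- fx$chains[keep, ]
  tiers <- fx$tiers[fx$tiers$chain %in% chains$chain, ]
  db <- build_pentadb(chains, tiers)
  tripb <- pb_frequency_table(chains$pb, order = 3, mode = "odds")
  q <- chains[1, ]
  nf <- predict_pb(q$aa, db, method = "hybrid", scheme = "noise-filter",
                   start = "100", query_chain = q$chain, tripb = tripb)
  cl <- predict_pb(q$aa, db, method = "hybrid", scheme = "classic",
                   threshold = "full", query_chain = q$chain, tripb = tripb)
  expect_identical(nf$pb, cl$pb)
})

test_that("prediction accessors summarise window outcomes", {
  fx <- std_fixture()
  db <- fixture_pentadb(fx)
  q <- fx$chains[2, ]
  pr <- predict_pb(q$aa, db, method = "majority", query_chain = q$chain)
  g <- glance(pr)
  expect_equal(g$n_windows, nchar(q$aa) - 4)
  expect_equal(g$n_exact + g$n_wildcard + g$n_none, g$n_windows)
  expect_equal(nchar(pr$pb), nchar(q$aa))
  expect_identical(substr(pr$pb, 1, 2), "ZZ")
})
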