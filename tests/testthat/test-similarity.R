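test_that("term-level Resnik is the (optionally normalized) MICA IC", {
  g <- chain_graph()
  # corpus: 2 of 4 pairs fall under a  ->  IC(a) = ln 2
  leafy <- mk_graph(c("X:r", "X:a", "X:b", "X:c"),
                    child = c("X:a", "X:b", "X:c"),
                    parent = c("X:r", "X:a", "X:r"))
  corp <- mk_corpus(tibble::tibble(resource = paste0("r", 1:4),
                                   term = c("X:b", "X:a", "X:c", "X:c")),
                    list(X = leafy))
  ic <- compute_ic_corpus(leafy, corp)
  expect_equal(unname(ic$ic[["X:a"]]), log(2))
  expect_equal(sim_term_resnik(leafy, ic, "X:a", "X:b", normalize = FALSE),
               log(2))
  expect_equal(sim_term_resnik(leafy, ic, "X:b", "X:b", normalize = FALSE),
               unname(ic$ic[["X:b"]]))
  expect_equal(sim_term_resnik(leafy, ic, "X:a", "X:b", normalize = TRUE),
               log(2) / ic$ic_max)
  # pair sharing only the root scores 0
  expect_equal(sim_term_resnik(leafy, ic, "X:b", "X:c"), 0)
})

test_that("term-level Lin follows 2*IC(mica) / (IC1 + IC2)", {
  g <- mk_graph(c("X:r", "X:m", "X:t1", "X:t2"),
                child = c("X:m", "X:t1", "X:t2"),
                parent = c("X:r", "X:m", "X:m"))
  ic <- ic_table(c("X:r" = 0, "X:m" = 0.5, "X:t1" = 1.0, "X:t2" = 1.5),
                 "intrinsic")
  expect_equal(sim_term_lin(g, ic, "X:t1", "X:t2"), 0.4)
  expect_equal(sim_term_lin(g, ic, "X:t1", "X:t1"), 1)
  expect_equal(sim_term_lin(g, ic, "X:r", "X:r"), 0)  # zero denominator
})

test_that("best-match-average matches hand values and the double-loop oracle", {
  g <- mk_graph(c("X:r", "X:x", "X:y"),
                child = c("X:x", "X:y"), parent = c("X:r", "X:x"))
  ic <- ic_table(c("X:r" = 0, "X:x" = 0.5, "X:y" = 4.5), "intrinsic")
  # lin(x,x) = 1, lin(x,y) = 2*0.5/5 = 0.2
  expect_equal(sim_group_bma(g, ic, "X:x", "X:x", term_sim = "lin"), 1)
  expect_equal(sim_group_bma(g, ic, "X:x", c("X:x", "X:y"), term_sim = "lin"),
               0.8)   # (1 + (1 + 0.2)/2) / 2
  expect_true(is.na(sim_group_bma(g, ic, character(), "X:x")))

  withr::local_seed(707)
  for (rep in 1:20) {
    gg <- rand_dag(sample(4:15, 1))
    icc <- rand_ic(gg)
    A <- sample_upto(names(gg$anc), 5)
    B <- sample_upto(names(gg$anc), 5)
    expect_equal(
      sim_group_bma(gg, icc, A, B, term_sim = "resnik"),
      oracle_bma(function(a, b) oracle_term_resnik(gg, icc, a, b), A, B),
      tolerance = 1e-12)
    expect_equal(
      sim_group_bma(gg, icc, A, B, term_sim = "lin"),
      oracle_bma(function(a, b) oracle_term_lin(gg, icc, a, b), A, B),
      tolerance = 1e-12)
  }
})

test_that("simUI is the Jaccard of ancestor closures", {
  g <- mk_graph(c("X:r", "X:a", "X:b"),
                child = c("X:a", "X:b"), parent = c("X:r", "X:r"))
  expect_equal(sim_group_simui(g, "X:a", "X:b"), 1 / 3)
  expect_equal(sim_group_simui(g, c("X:a", "X:b"), c("X:a", "X:b")), 1)
  expect_true(is.na(sim_group_simui(g, character(), "X:a")))
})

test_that("simGIC is the IC-weighted closure Jaccard with 0/0 conventions", {
  g <- mk_graph(c("X:r", "X:a", "X:b"),
                child = c("X:a", "X:b"), parent = c("X:r", "X:r"))
  ic <- ic_table(c("X:r" = 0.5, "X:a" = 1, "X:b" = 0.5), "intrinsic")
  # closures {a,r} vs {b,r}: intersection IC 0.5, union IC 2.0
  expect_equal(sim_group_simgic(g, ic, "X:a", "X:b"), 0.25)
  expect_equal(sim_group_simgic(g, ic, c("X:a", "X:b"), c("X:a", "X:b")), 1)
  # intersection only at a zero-IC root
  ic0 <- ic_table(c("X:r" = 0, "X:a" = 1, "X:b" = 0.5), "intrinsic")
  g2 <- mk_graph(c("X:r", "X:a", "X:b", "X:c"),
                 child = c("X:a", "X:b", "X:c"),
                 parent = c("X:r", "X:r", "X:r"))
  ic2 <- ic_table(c("X:r" = 0, "X:a" = 1, "X:b" = 1, "X:c" = 1), "intrinsic")
  expect_equal(sim_group_simgic(g2, ic2, "X:a", "X:b"), 0)
  # all-zero IC: 1 iff closures coincide
  icz <- ic_table(c("X:r" = 0, "X:a" = 0, "X:b" = 0, "X:c" = 0), "intrinsic")
  expect_equal(sim_group_simgic(g2, icz, "X:a", "X:a"), 1)
  expect_equal(sim_group_simgic(g2, icz, "X:a", "X:b"), 0)
})

test_that("set measures agree with the brute-force closure oracles", {
  withr::local_seed(808)
  for (rep in 1:25) {
    g <- rand_dag(sample(3:20, 1))
    ic <- rand_ic(g)
    A <- sample(names(g$anc), sample(1:8, 1), replace = TRUE)
    B <- sample(names(g$anc), sample(1:8, 1), replace = TRUE)
    expect_identical(sim_group_simui(g, A, B), oracle_simui(g, A, B))
    expect_equal(sim_group_simgic(g, ic, A, B), oracle_simgic(g, ic, A, B),
                 tolerance = 1e-12)
  }
})

test_that("all groupwise measures are symmetric, bounded and reflexive", {
  withr::local_seed(909)
  for (rep in 1:20) {
    g <- rand_dag(sample(4:15, 1))
    ic <- rand_ic(g)
    A <- sample_upto(names(g$anc), 6)
    B <- sample_upto(names(g$anc), 6)
    for (ms in c("resnik_bma", "lin_bma", "simui", "simgic")) {
      m <- measure_spec(ms)
      ab <- mdsemsim:::group_sim(g, ic, m, A, B)
      ba <- mdsemsim:::group_sim(g, ic, m, B, A)
      expect_equal(ab, ba, tolerance = 1e-12)
      expect_gte(ab, 0)
      expect_lte(ab, 1)
    }
    # identity on identical non-empty sets (needs some positive IC inside)
    pos <- names(ic$ic)[ic$ic > 0]
    if (length(pos) > 0) {
      S <- sample(pos, min(3, length(pos)))
      expect_equal(sim_group_bma(g, ic, S, S, term_sim = "lin"), 1)
      expect_equal(sim_group_simui(g, S, S), 1)
      expect_equal(sim_group_simgic(g, ic, S, S), 1)
    }
  }
})

# --- lifting fixtures ------------------------------------------------------

# d1: chain r<-p<-x plus p<-q<-y  =>  simUI({x},{y}) = 2/5
# d2: chain r<-s<-t<-u plus u<-v  =>  simUI({u},{u,v}) = 4/5
lifting_fixture <- function() {
  d1 <- mk_graph(c("D1:r", "D1:p", "D1:q", "D1:x", "D1:y"),
                 child = c("D1:p", "D1:q", "D1:x", "D1:y"),
                 parent = c("D1:r", "D1:p", "D1:p", "D1:q"), domain = "D1")
  d2 <- mk_graph(c("D2:r", "D2:s", "D2:t", "D2:u", "D2:v"),
                 child = c("D2:s", "D2:t", "D2:u", "D2:v"),
                 parent = c("D2:r", "D2:s", "D2:t", "D2:u"), domain = "D2")
  onts <- list(D1 = d1, D2 = d2)
  corp <- mk_corpus(tibble::tibble(
    resource = c("r1", "r1", "r2", "r2", "r2"),
    term = c("D1:x", "D2:u", "D1:y", "D2:u", "D2:v")), onts)
  ics <- lapply(onts, compute_ic_intrinsic)
  list(onts = onts, corp = corp, ics = ics)
}

test_that("aggregative settings average per-domain scores, raw and weighted", {
  fx <- lifting_fixture()
  ms <- measure_spec("simui")
  raw <- sim_resources(fx$corp, "r1", "r2", setting_spec("aggregative_raw"),
                       ms, fx$onts, fx$ics)
  expect_equal(raw, (2 / 5 + 4 / 5) / 2)             # = 0.6
  wtd <- sim_resources(fx$corp, "r1", "r2",
                       setting_spec("aggregative_weighted"), ms,
                       fx$onts, fx$ics)
  expect_equal(wtd, (0.4 * 2 + 0.8 * 3) / 5)         # = 0.64
  # baselines recover the per-domain scores themselves
  expect_equal(sim_resources(fx$corp, "r1", "r2",
                             setting_spec("baseline", "D1"), ms,
                             fx$onts, fx$ics), 2 / 5)
  # identity under any setting for simUI
  expect_equal(sim_resources(fx$corp, "r1", "r1",
                             setting_spec("aggregative_raw"), ms,
                             fx$onts, fx$ics), 1)
})

test_that("weighted aggregation collapses to raw under equal weights", {
  fx <- lifting_fixture()
  # make counts equal: r2 gets one annotation per domain
  corp <- mk_corpus(tibble::tibble(
    resource = c("r1", "r1", "r2", "r2"),
    term = c("D1:x", "D2:u", "D1:y", "D2:v")), fx$onts)
  for (msname in c("simui", "simgic", "resnik_bma", "lin_bma")) {
    ms <- measure_spec(msname)
    raw <- sim_resources(corp, "r1", "r2", setting_spec("aggregative_raw"),
                         ms, fx$onts, fx$ics)
    wtd <- sim_resources(corp, "r1", "r2",
                         setting_spec("aggregative_weighted"), ms,
                         fx$onts, fx$ics)
    expect_equal(raw, wtd, tolerance = 1e-12)
  }
})

test_that("domains missing from either resource are excluded, not zero-scored", {
  fx <- lifting_fixture()
  corp <- mk_corpus(tibble::tibble(
    resource = c("r1", "r1", "r2"),
    term = c("D1:x", "D2:u", "D1:x")), fx$onts)   # r2 lacks D2
  ms <- measure_spec("simui")
  raw <- sim_resources(corp, "r1", "r2", setting_spec("aggregative_raw"),
                       ms, fx$onts, fx$ics)
  expect_equal(raw, 1)   # only D1 contributes, and it matches exactly
})

test_that("resources sharing no domain score 0 aggregatively but > 0 integratively", {
  fx <- lifting_fixture()
  corp <- mk_corpus(tibble::tibble(
    resource = c("r1", "r2"), term = c("D1:x", "D2:u")), fx$onts)
  ms <- measure_spec("simui")
  expect_equal(sim_resources(corp, "r1", "r2",
                             setting_spec("aggregative_raw"), ms,
                             fx$onts, fx$ics), 0)
  merged <- merge_ontologies(fx$onts)
  mic <- compute_ic_corpus(merged, corp)
  integ <- sim_resources(corp, "r1", "r2", setting_spec("integrative"), ms,
                         fx$onts, fx$ics, merged = merged, merged_ic = mic)
  # closures only share the created root: 1 / |union| > 0
  expect_equal(integ, 1 / 8)
})

test_that("cross-domain Resnik under corpus IC is 0 through the merged root", {
  fx <- lifting_fixture()
  merged <- merge_ontologies(fx$onts)
  corp <- mk_corpus(tibble::tibble(
    resource = c("r1", "r2"), term = c("D1:x", "D2:u")), fx$onts)
  mic <- compute_ic_corpus(merged, corp)
  expect_equal(unname(mic$ic[[merged$merged_root_id]]), 0)
  out <- sim_resources(corp, "r1", "r2", setting_spec("integrative"),
                       measure_spec("resnik_bma"), fx$onts, fx$ics,
                       merged = merged, merged_ic = mic)
  expect_equal(out, 0)
})

test_that("similarity_matrix equals element-wise sim_resources", {
  ds <- generate_dataset(synthetic_spec(33, m = 12, terms_per_domain = 15,
                                        n_classes = 3))
  onts <- ds$ontologies
  corp <- ds$corpus
  ics <- lapply(onts, compute_ic_corpus, corpus = corp)
  merged <- merge_ontologies(onts)
  mic <- compute_ic_corpus(merged, corp)
  res <- corp$resources
  for (st in list(setting_spec("baseline", "SRCA"),
                  setting_spec("aggregative_raw"),
                  setting_spec("aggregative_weighted"),
                  setting_spec("integrative"))) {
    for (msname in c("resnik_bma", "simui", "simgic", "lin_bma")) {
      ms <- measure_spec(msname)
      mat <- similarity_matrix(corp, st, ms, onts, ics,
                               merged = merged, merged_ic = mic)
      expect_identical(mat$scores, t(mat$scores))
      expect_true(all(mat$scores >= 0 & mat$scores <= 1))
      pick <- cbind(c(1, 2, 5, nrow(mat$scores)), c(2, 7, 5, 1))
      for (row in seq_len(nrow(pick))) {
        i <- pick[row, 1]; j <- pick[row, 2]
        expect_equal(
          mat$scores[i, j],
          sim_resources(corp, res[[i]], res[[j]], st, ms, onts, ics,
                        merged = merged, merged_ic = mic),
          tolerance = 1e-12,
          info = paste(st$mode, msname))
      }
    }
  }
})

test_that("matrix diagonal is 1 for the normalized set measures", {
  ds <- generate_dataset(synthetic_spec(34, m = 8, terms_per_domain = 12,
                                        n_classes = 2))
  ics <- lapply(ds$ontologies, compute_ic_corpus, corpus = ds$corpus)
  merged <- merge_ontologies(ds$ontologies)
  mic <- compute_ic_corpus(merged, ds$corpus)
  for (msname in c("lin_bma", "simui", "simgic")) {
    mat <- similarity_matrix(ds$corpus, setting_spec("integrative"),
                             measure_spec(msname), ds$ontologies, ics,
                             merged = merged, merged_ic = mic)
    expect_equal(unname(diag(mat$scores)), rep(1, nrow(mat$scores)),
                 tolerance = 1e-12)
  }
})

test_that("tidy and TSV round trips preserve the scores", {
  ds <- generate_dataset(synthetic_spec(35, m = 6, terms_per_domain = 12,
                                        n_classes = 2))
  ics <- lapply(ds$ontologies, compute_ic_corpus, corpus = ds$corpus)
  mat <- similarity_matrix(ds$corpus, setting_spec("aggregative_raw"),
                           measure_spec("simui"), ds$ontologies, ics)
  td <- tidy(mat)
  expect_equal(nrow(td), choose(6, 2))
  expect_true(all(td$r1 < td$r2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_similarity_matrix(mat, path)
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(as.matrix(wide[, -1]), mat$scores, ignore_attr = TRUE)
})
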