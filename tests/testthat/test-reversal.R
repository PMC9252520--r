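test_that("KS statistics match direct evaluation on the worked cases", {
  rk <- make_ranking(10)
  top <- ks_enrichment(names(rk)[1:2], rk, min_overlap = 2)
  expect_equal(top$a, 0.8)
  expect_equal(top$b, 0.1)
  expect_equal(top$es, 0.8)

  bottom <- ks_enrichment(names(rk)[9:10], rk, min_overlap = 2)
  expect_equal(bottom$a, 0.0)
  expect_equal(bottom$b, 0.9)
  expect_equal(bottom$es, -0.9)

  # n = 2, single gene on top: exact tie resolves to +a
  tie <- ks_enrichment("G01", make_ranking(2), min_overlap = 1)
  expect_equal(tie$a, 0.5)
  expect_equal(tie$b, 0.5)
  expect_equal(tie$es, +0.5)
})

test_that("KS statistics equal the brute-force oracle exhaustively", {
  # every set of size <= 4 in every universe of size <= 8
  for (n in 2:8) {
    rk <- make_ranking(n)
    for (t in 1:min(4, n - 1)) {
      pos_sets <- utils::combn(n, t)
      for (col in seq_len(ncol(pos_sets))) {
        pos <- pos_sets[, col]
        got <- ks_enrichment(names(rk)[pos], rk, min_overlap = 1)
        want <- ks_brute(pos, n)
        expect_identical(got$a, want$a)
        expect_identical(got$b, want$b)
      }
    }
  }
})

test_that("reversing a ranking mirrors the KS statistics exactly", {
  set.seed(61)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    rk <- make_ranking(n)
    set <- sample(names(rk), sample(2:6, 1))
    fwd <- ks_enrichment(set, rk, min_overlap = 1)
    rev_rk <- setNames(n + 1L - rk, names(rk))
    bwd <- ks_enrichment(set, rev_rk, min_overlap = 1)
    expect_equal(bwd$a, fwd$b - 1 / n, tolerance = 1e-12)
    expect_equal(bwd$b, fwd$a + 1 / n, tolerance = 1e-12)
  }
})

test_that("insufficient overlap rejects the set with a message", {
  rk <- make_ranking(10)
  expect_message(res <- ks_enrichment(names(rk)[1:3], rk, min_overlap = 5),
                 "rejected")
  expect_null(res)
})

make_sig <- function(up, down) {
  structure(list(up = up, down = down,
                 log2fc = setNames(rep(c(2, -2), c(length(up), length(down))),
                                   c(up, down)),
                 provenance = list(patient_id = "PT1")),
            class = "disease_signature")
}

test_that("RGES sign contract: mimic positive, reverser negative, same-sign zero", {
  n <- 100
  rk <- make_ranking(n)
  up <- names(rk)[1:10]       # disease-up at the very top of the ranking
  down <- names(rk)[(n - 9):n]
  sig <- make_sig(up, down)
  rec <- list(drug = "d", cell_line = "c", dose_um = 10, time_h = 24,
              ranking = rk)
  mimic <- rges_score(sig, rec)
  expect_gt(mimic$rges, 0)

  # reverser: up genes at the bottom, down genes at the top
  rev_rec <- rec
  rev_rec$ranking <- setNames(n + 1L - rk, names(rk))
  reversal <- rges_score(sig, rev_rec)
  expect_lt(reversal$rges, 0)

  # both sets enriched at the top -> same-sign zeroing
  sig_same <- make_sig(names(rk)[1:10], names(rk)[11:20])
  same <- rges_score(sig_same, rec)
  expect_gt(same$es_up, 0)
  expect_gt(same$es_down, 0)
  expect_identical(same$rges, 0)

  # rges always within [-2, 2]
  for (r in list(mimic, reversal, same))
    expect_true(r$rges >= -2 && r$rges <= 2)
})

test_that("reward model offsets are paired mean differences to the reference", {
  mk_rges <- function(drug, dose, time, rges)
    data.frame(drug = drug, cell_line = "c", dose_um = dose, time_h = time,
               es_up = 0.1, es_down = -0.1, rges = rges)
  # one drug: reference -0.3, (low, long) -0.1 -> offset -0.2
  tab <- rbind(mk_rges("d1", 10, 24, -0.3), mk_rges("d1", 1, 24, -0.1))
  class(tab) <- c("rges_table", class(tab))
  m <- fit_reward_model(tab)
  expect_equal(m$offset[m$dose_class == "low" & m$time_class == "long"], -0.2)
  expect_equal(m$offset[m$dose_class == "high" & m$time_class == "long"], 0)

  # two drugs with paired differences -0.2 and -0.4 -> offset -0.3
  tab2 <- rbind(mk_rges("d1", 10, 24, -0.3), mk_rges("d1", 1, 24, -0.1),
                mk_rges("d2", 10, 24, -0.5), mk_rges("d2", 1, 24, -0.1))
  class(tab2) <- c("rges_table", class(tab2))
  m2 <- fit_reward_model(tab2)
  expect_equal(m2$offset[m2$dose_class == "low" & m2$time_class == "long"], -0.3)

  # reference-only library: all offsets zero
  tab3 <- rbind(mk_rges("d1", 10, 24, -0.3), mk_rges("d2", 10, 24, 0.2))
  class(tab3) <- c("rges_table", class(tab3))
  expect_true(all(fit_reward_model(tab3)$offset == 0))
})

test_that("sRGES identities: single reference record and plain means", {
  tab <- data.frame(drug = "d1", cell_line = "c", dose_um = 10, time_h = 24,
                    es_up = 0.2, es_down = -0.05, rges = -0.25)
  class(tab) <- c("rges_table", class(tab))
  s <- summarize_srges(tab)
  expect_equal(s$srges, -0.25)
  expect_identical(s$n_treatments, 1L)

  # two standardized values -0.2 and -0.4 average to -0.3
  tab2 <- rbind(tab, within(tab, { rges <- -0.35; cell_line <- "c2" }))
  tab2$rges <- c(-0.2, -0.4)
  class(tab2) <- c("rges_table", class(tab2))
  expect_equal(summarize_srges(tab2)$srges, -0.3)

  # all-reference drug: srges within [min rges, max rges]
  expect_gte(summarize_srges(tab2)$srges, min(tab2$rges))
  expect_lte(summarize_srges(tab2)$srges, max(tab2$rges))

  expect_error(summarize_srges(tab[0, ]), "no scored treatments")
})

test_that("perturbation library validates rankings and round-trips TSV", {
  cfg <- small_scenario(seed = 62)
  sim <- simulate_cohort(cfg)
  pert <- simulate_perturbation_library(cfg, sim$truth$sig_up, sim$truth$sig_down)
  lib <- pert$library
  # every record is a complete permutation (constructor enforces; re-check)
  for (r in lib$records)
    expect_setequal(r$ranking, seq_along(lib$universe))

  f <- tempfile(fileext = ".tsv")
  write_perturbation_library(lib, f)
  lib2 <- read_perturbation_library(f)
  expect_identical(length(lib2$records), length(lib$records))
  expect_setequal(lib2$universe, lib$universe)
  key <- function(l) vapply(l$records, function(r)
    paste(r$drug, r$cell_line, r$dose_um, r$time_h), character(1))
  m <- match(key(lib), key(lib2))
  for (i in seq_along(lib$records))
    expect_identical(lib$records[[i]]$ranking[order(names(lib$records[[i]]$ranking))],
                     lib2$records[[m[i]]]$ranking[order(names(lib2$records[[m[i]]]$ranking))])

  # broken permutation rejected
  bad <- lib$records
  bad[[1]]$ranking[1] <- bad[[1]]$ranking[2]
  expect_error(perturbation_library(bad, lib$universe), "permutation")
  # non-positive dose rejected
  bad2 <- lib$records
  bad2[[1]]$dose_um <- 0
  expect_error(perturbation_library(bad2, lib$universe), "positive")
})

test_that("planted reversers take the lowest sRGES ranks", {
  cfg <- small_scenario(seed = 63)
  sim <- simulate_cohort(cfg)
  pert <- simulate_perturbation_library(cfg, sim$truth$sig_up, sim$truth$sig_down)
  sig <- make_sig(sim$truth$sig_up, sim$truth$sig_down)
  out <- srges(sig, pert$library)
  expect_setequal(utils::head(out$drug, length(pert$reversers)),
                  pert$reversers)
  expect_true(all(diff(out$srges) >= 0))   # sorted ascending
  # reversers score negative, and stronger potency scores lower
  rev_scores <- out$srges[match(pert$reversers, out$drug)]
  expect_true(all(rev_scores < 0))
})
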