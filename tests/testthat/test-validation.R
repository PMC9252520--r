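test_that("cell-line matching finds an embedded copy of the patient", {
  set.seed(71)
  n <- 200
  genes <- sprintf("g%03d", 1:n)
  panel <- matrix(rnorm(n * 5, 8, 2), n, 5,
                  dimnames = list(genes, paste0("CL-", 1:5)))
  pat <- setNames(panel[, 3], genes)
  res <- match_cell_line(pat, expression_matrix(panel, "log2"), n_genes = 100)
  expect_identical(res$cell_line, "CL-3")
  expect_equal(res$rho, 1.0)
})

test_that("cell-line matching ties break to the smallest id", {
  set.seed(72)
  n <- 100
  genes <- sprintf("g%03d", 1:n)
  base <- rnorm(n, 8, 2)
  # panel of monotone transforms of one profile: all rho = 1
  panel <- cbind("CL-b" = exp(base / 4), "CL-a" = base * 3 + 1,
                 "CL-c" = base)
  rownames(panel) <- genes
  res <- match_cell_line(setNames(base, genes),
                         expression_matrix(panel, "log2"), n_genes = 50)
  expect_identical(res$cell_line, "CL-a")
  expect_error(match_cell_line(setNames(base[1], genes[1]),
                               expression_matrix(panel, "log2"), 50),
               "fewer than 2")
})

test_that("efficacy labelling applies the mean - 0.5 SD rule inclusively", {
  sens <- data.frame(drug = c("d1", "d2", "d3"), cell_line = "c",
                     auc = c(0.2, 0.5, 0.8))
  lab <- classify_drug_efficacy(sens, "c")
  expect_equal(attr(lab, "mean"), 0.5)
  expect_equal(attr(lab, "sd"), 0.3)
  expect_equal(attr(lab, "threshold"), 0.35)
  expect_identical(lab$drug[lab$effective], "d1")

  # boundary: AUC exactly at mean - 0.5 SD counts as effective
  sens2 <- data.frame(drug = c("a", "b", "c", "d"), cell_line = "c",
                      auc = c(1, 2, 3, 4))
  lab2 <- classify_drug_efficacy(sens2, "c")
  thr <- attr(lab2, "threshold")
  expect_true(all(lab2$effective == (lab2$auc <= thr)))

  # degenerate: identical AUCs -> SD 0, every drug effective
  sens3 <- data.frame(drug = c("a", "b", "c"), cell_line = "c", auc = 0.5)
  expect_true(all(classify_drug_efficacy(sens3, "c")$effective))

  # invariance to drug ordering
  perm <- sens[c(3, 1, 2), ]
  lab_perm <- classify_drug_efficacy(perm, "c")
  expect_identical(sort(lab_perm$drug[lab_perm$effective]), "d1")

  expect_error(classify_drug_efficacy(sens[1:2, ], "c"), ">= 3")
})

test_that("validation correlation is exact on a linear construction", {
  st <- data.frame(drug = sprintf("d%02d", 1:20),
                   srges = seq(-0.5, 0.5, length.out = 20),
                   n_treatments = 1L)
  class(st) <- c("srges_table", class(st))
  sens <- data.frame(drug = st$drug, cell_line = "c",
                     auc = 0.5 + 0.4 * st$srges)
  v <- validate_correlation(st, sens, "c")
  expect_equal(v$r, 1.0)
  expect_lt(v$p, 1e-10)
  expect_error(validate_correlation(st[1:2, ], sens[1:2, ], "c"), ">= 3")
})

test_that("independent scores give small correlations at the null rate", {
  set.seed(73)
  rejections <- 0L
  for (i in 1:100) {
    st <- data.frame(drug = sprintf("d%02d", 1:30), srges = rnorm(30),
                     n_treatments = 1L)
    class(st) <- c("srges_table", class(st))
    sens <- data.frame(drug = st$drug, cell_line = "c",
                       auc = runif(30, 0.2, 0.9))
    v <- suppressWarnings(validate_correlation(st, sens, "c"))
    if (v$p < 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections, 15L)   # ~5% expected under the null
})

test_that("effective/ineffective sRGES shift is detected by the t-test", {
  set.seed(74)
  n <- 100
  auc <- c(runif(n / 2, 0.1, 0.3), runif(n / 2, 0.6, 0.9))
  srges_vals <- c(rnorm(n / 2, -0.3, 0.1), rnorm(n / 2, 0, 0.1))
  st <- data.frame(drug = sprintf("d%03d", 1:n), srges = srges_vals,
                   n_treatments = 1L)
  class(st) <- c("srges_table", class(st))
  sens <- data.frame(drug = st$drug, cell_line = "c", auc = auc)
  v <- validate_correlation(st, sens, "c")
  expect_lt(v$t_p, 0.05)
  expect_lt(v$t_stat, 0)    # effective (low AUC) drugs have lower srges
})

test_that("permutation null flags a planted subgroup effect", {
  set.seed(75)
  drugs <- sprintf("d%02d", 1:20)
  sens <- data.frame(drug = drugs, cell_line = "c",
                     auc = seq(0.2, 0.9, length.out = 20))
  subtype <- sprintf("s%02d", 1:30)
  # pipeline: random subgroups give srges uncorrelated with auc
  null_pipeline <- function(ids) {
    st <- data.frame(drug = drugs, srges = rnorm(20), n_treatments = 1L)
    class(st) <- c("srges_table", class(st))
    st
  }
  pn <- permutation_null(observed_r = 0.6, subtype_samples = subtype,
                         pipeline = null_pipeline, sens = sens,
                         cell_line = "c", N = 5, n_perm = 100, seed = 75)
  expect_length(pn$null_r, 100)
  expect_lt(pn$p, 0.01)
  expect_error(permutation_null(0.5, subtype, null_pipeline, sens, "c",
                                N = 5, n_perm = 1), "n_perm")
  expect_error(permutation_null(0.5, subtype[1:4], null_pipeline, sens, "c",
                                N = 5, n_perm = 10), "more than N")
})

test_that("constant pipelines degrade to r = 0 with a warning, not a crash", {
  drugs <- sprintf("d%02d", 1:10)
  sens <- data.frame(drug = drugs, cell_line = "c",
                     auc = seq(0.2, 0.9, length.out = 10))
  const_pipeline <- function(ids) {
    st <- data.frame(drug = drugs, srges = 0, n_treatments = 1L)
    class(st) <- c("srges_table", class(st))
    st
  }
  expect_warning(
    pn <- permutation_null(0.3, sprintf("s%d", 1:10), const_pipeline, sens,
                           "c", N = 3, n_perm = 10, seed = 1),
    "constant|degenerate")
  expect_true(all(pn$null_r == 0))
  expect_equal(pn$p, 1)
})

test_that("permutation null mean is seed-stable at large n_perm", {
  set.seed(76)
  drugs <- sprintf("d%02d", 1:20)
  auc <- seq(0.2, 0.9, length.out = 20)
  sens <- data.frame(drug = drugs, cell_line = "c", auc = auc)
  # deterministic pipeline whose srges depends weakly on the drawn subgroup
  noise <- matrix(rnorm(20 * 97), 20, 97)
  pipe <- function(ids) {
    h <- sum(utf8ToInt(paste(sort(ids), collapse = ""))) %% 97L + 1L
    st <- data.frame(drug = drugs, srges = 0.2 * auc + noise[, h],
                     n_treatments = 1L)
    class(st) <- c("srges_table", class(st))
    st
  }
  p1 <- permutation_null(0.5, sprintf("s%02d", 1:40), pipe, sens, "c",
                         N = 5, n_perm = 500, seed = 10)
  p2 <- permutation_null(0.5, sprintf("s%02d", 1:40), pipe, sens, "c",
                         N = 5, n_perm = 500, seed = 20)
  se <- sqrt(var(p1$null_r) / 500 + var(p2$null_r) / 500)
  expect_lt(abs(mean(p1$null_r) - mean(p2$null_r)), 3 * se)
})

test_that("responder AUC follows the Mann-Whitney identity", {
  # perfect separation: all responders score lower
  sc <- setNames(c(-1, -0.5, -0.2, 0.3, 0.6, 1), sprintf("p%d", 1:6))
  lab <- setNames(rep(c("responder", "non-responder"), each = 3), names(sc))
  res <- responder_auc(sc, lab)
  expect_equal(res$auc, 1.0)

  # identical distributions: AUC 0.5
  sc2 <- setNames(rep(c(0.1, 0.2, 0.3), 2), sprintf("p%d", 1:6))
  res2 <- responder_auc(sc2, lab)
  expect_equal(res2$auc, 0.5)

  expect_error(responder_auc(sc, setNames(rep("responder", 6), names(sc))),
               "non-empty")
})

test_that("Mann-Whitney AUC equals the trapezoidal ROC integral exhaustively", {
  # all label splits of up to 10 patients with distinct scores
  trap_auc <- function(scores, resp) {
    ths <- c(-Inf, sort(unique(scores)), Inf)
    tpr <- sapply(ths, function(th) mean(scores[resp] <= th))
    fpr <- sapply(ths, function(th) mean(scores[!resp] <= th))
    sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  }
  set.seed(77)
  for (n in c(4, 6, 8, 10)) {
    scores <- setNames(sample(seq(0.1, 1, length.out = n)), sprintf("p%d", 1:n))
    for (k in 1:(n - 1)) {
      for (rep in 1:3) {
        resp <- rep(FALSE, n); resp[sample(n, k)] <- TRUE
        names(resp) <- names(scores)
        got <- responder_auc(scores, resp)$auc
        expect_equal(got, trap_auc(scores, resp), tolerance = 1e-12)
      }
    }
  }
  skip_if_not_installed("pROC")
  resp <- rep(c(TRUE, FALSE), 5); names(resp) <- sprintf("p%d", 1:10)
  scores <- setNames(rnorm(10), names(resp))
  got <- responder_auc(scores, resp)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = resp, predictor = scores,
                                        direction = ">", quiet = TRUE)))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("simulated response labels give the expected AUC band on average", {
  cfg <- scenario_config(seed = 78)
  aucs <- sapply(1:30, function(i) {
    cfg_i <- scenario_config(seed = 78 + i)
    strength <- setNames(c(rep(-0.8, 5), rep(0, 15)), sprintf("drug%02d", 1:20))
    sr <- simulate_sensitivity_and_response(cfg_i, strength)
    responder_auc(sr$scores, sr$labels)$auc
  })
  expect_gt(mean(aucs), 0.7)
  expect_lt(mean(aucs), 0.9)
})
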